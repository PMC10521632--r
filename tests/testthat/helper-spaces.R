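# Small deterministic fixtures used across test files.

make_space <- function(k = 6, dim = 4, seed = 1, metapath = "GEN-ppi-GEN",
                       ids = NULL) {
  if (is.null(ids)) ids <- sprintf("G%03d", seq_len(k))
  m <- withr::with_seed(seed, {
    matrix(rnorm(length(ids) * dim), length(ids), dim,
           dimnames = list(ids, NULL))
  })
  embedding_space(metapath, vectors = m)
}

make_hetero_space <- function(ks = 5, kd = 6, dim = 4, seed = 1,
                              metapath = "CPD-int-GEN") {
  withr::with_seed(seed, {
    ms <- matrix(rnorm(ks * dim), ks, dim,
                 dimnames = list(sprintf("C%03d", seq_len(ks)), NULL))
    md <- matrix(rnorm(kd * dim), kd, dim,
                 dimnames = list(sprintf("G%03d", seq_len(kd)), NULL))
    embedding_space(metapath, src_vectors = ms, dst_vectors = md)
  })
}

make_edges <- function(src, dst, src_type = "GEN", dst_type = src_type,
                       quiet = TRUE) {
  as_edges(tibble::tibble(src_id = src, src_type = src_type,
                          dst_id = dst, dst_type = dst_type),
           quiet = quiet)
}

# brute-force oracles -------------------------------------------------

brute_quantile_rank <- function(bg_distances, d) {
  vapply(d, function(x) sum(bg_distances <= x) / length(bg_distances), 0)
}

brute_auroc <- function(pos, neg) {
  # concordant (positive, negative) pairs, ties counted one half
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  sum(cmp) / (length(pos) * length(neg))
}

brute_cosine <- function(u, v) {
  1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
}

degree_multiset <- function(edges) {
  tbl <- tibble::as_tibble(edges)
  rel <- paste(tbl$src_type, tbl$dst_type, sep = "-")
  homo <- tbl$src_type == tbl$dst_type
  # undirected homogeneous edges: degree ignores which column a node
  # sits in; heterogeneous (bipartite) edges: per-role degrees
  nodes <- c(
    paste(rel, ifelse(homo, "any", "src"), tbl$src_id),
    paste(rel, ifelse(homo, "any", "dst"), tbl$dst_id)
  )
  deg <- table(nodes)
  deg[order(names(deg))]
}

ks_distance_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(abs(p - (seq_len(n) - 1) / n), abs(p - seq_len(n) / n))
}
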