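#' Cosine distance between two vectors
#'
#' `1 - (u . v) / (||u|| ||v||)`, the distance used for all pair
#' scoring.  Ranges over `[0, 2]`: 0 for parallel, 1 for orthogonal,
#' 2 for antiparallel vectors.
#'
#' @param u,v Numeric vectors of equal length and nonzero norm.
#' @return A single number in `[0, 2]`.
#' @examples
#' cosine_distance(c(1, 0), c(0, 1))  # 1
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) rlang::abort("vectors differ in dimension")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) rlang::abort("zero-norm vector in cosine distance")
  min(max(1 - sum(u * v) / (nu * nv), 0), 2)
}

#' Quantile rank of a distance against a background sample
#'
#' The support score: the fraction of background distances less than or
#' equal to the observed distance, found by binary search on the sorted
#' background.  Lower means the pair is unusually close in that
#' context, i.e. better supported.  Ties count as `<=`, so a pair is
#' never reported closer than the background warrants.
#'
#' @param bg A `background_sample`.
#' @param d Numeric vector of cosine distances.
#' @return Quantile ranks in `[0, 1]`, one per element of `d`.
#' @examples
#' bg <- structure(list(distances = c(.1, .2, .3, .4), n = 4L),
#'                 class = "background_sample")
#' quantile_rank(bg, 0.25)  # 0.5
#' @export
quantile_rank <- function(bg, d) {
  if (bg$n == 0) rlang::abort("empty background sample")
  findInterval(d, bg$distances) / bg$n
}

# role matrices + row indices for one applicable (space, type pair);
# returns covered-edge rows with distances
edge_distances_one <- function(edges, space, edge_src_type, edge_dst_type,
                               orientation) {
  sub <- dplyr::filter(
    tibble::as_tibble(edges),
    .data$src_type == edge_src_type, .data$dst_type == edge_dst_type
  )
  if (nrow(sub) == 0) return(sub[0, ])
  if (orientation == "forward") {
    A <- space$src; B <- space$dst
  } else {
    A <- space$dst; B <- space$src
  }
  ia <- match(sub$src_id, rownames(A))
  ib <- match(sub$dst_id, rownames(B))
  keep <- !is.na(ia) & !is.na(ib)
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) == 0) return(sub)
  d <- chunked_row_cosine(
    normalize_rows(A), normalize_rows(B), ia[keep], ib[keep]
  )
  sub$distance <- d
  sub
}

#' Score every edge in every applicable embedding space
#'
#' For each edge covered by a space (both endpoints in the relevant
#' role vocabularies), computes the cosine distance between the two
#' entity vectors and its quantile rank against the space's background.
#' Edges not covered by a space are simply absent from that space's
#' rows; coverage is reported by [support_coverage()] and respected by
#' [summarize_support()].
#'
#' @param edges An `assoc_edges` tibble.
#' @param spaces Named list of `embedding_space` objects.
#' @param backgrounds Named list of `background_sample`s keyed by
#'   metapath (see [sample_backgrounds()]).
#' @return A tibble of class `support_tbl`, one row per covered
#'   (edge, metapath) combination: `src_id`, `src_type`, `dst_id`,
#'   `dst_type`, `metapath`, `distance`, `quantile_rank`.  The scored
#'   edge set is kept in attribute `edges`.
#' @export
score_dataset <- function(edges, spaces, backgrounds) {
  app <- suppressWarnings(applicable_spaces(spaces, edges))
  by_name <- stats::setNames(spaces, vapply(spaces, `[[`, "", "metapath"))
  rows <- vector("list", nrow(app))
  for (k in seq_len(nrow(app))) {
    sp <- by_name[[app$metapath[k]]]
    bg <- backgrounds[[app$metapath[k]]]
    if (is.null(bg)) {
      rlang::abort(sprintf("no background sample for space %s", sp$metapath))
    }
    sub <- edge_distances_one(
      edges, sp, app$edge_src_type[k], app$edge_dst_type[k], app$orientation[k]
    )
    if (nrow(sub) == 0) next
    sub$metapath <- sp$metapath
    sub$quantile_rank <- quantile_rank(bg, sub$distance)
    rows[[k]] <- sub
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    src_id = character(), src_type = character(),
    dst_id = character(), dst_type = character(),
    metapath = character(), distance = double(), quantile_rank = double()
  )
  out <- dplyr::arrange(out, .data$metapath, .data$src_id, .data$dst_id)
  out <- out[, c("src_id", "src_type", "dst_id", "dst_type",
                 "metapath", "distance", "quantile_rank")]
  if (nrow(out) == 0) {
    rlang::inform("support table is empty: no edge is covered by any space")
  }
  structure(out,
            edges = tibble::as_tibble(edges),
            class = c("support_tbl", class(tibble::tibble())))
}

#' Per-metapath coverage of a support table
#'
#' Coverage is the fraction of input edges whose both endpoints carry a
#' vector in a given space's vocabulary.
#'
#' @param support A `support_tbl` from [score_dataset()].
#' @return A tibble with columns `metapath`, `n_covered`, `coverage`.
#' @export
support_coverage <- function(support) {
  n_edges <- nrow(attr(support, "edges"))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(support), .data$metapath),
    n_covered = dplyr::n(),
    coverage = dplyr::n() / n_edges,
    .groups = "drop"
  )
}

#' Aggregate a support table to edge- and dataset-level summaries
#'
#' The edge-level aggregate is the minimum quantile rank across the
#' metapaths covering that edge ("best context wins"): an association
#' counts as supported at a cutoff when at least one biomedical context
#' supports it.  Fractions are computed over covered edges only;
#' uncovered edges are reported via `dataset_coverage`, never imputed.
#'
#' @param support A `support_tbl` from [score_dataset()].
#' @param cutoffs Ascending quantile-rank thresholds in `(0, 1]`.  The
#'   default stratification is c(0.01, 0.05, 0.10, 0.25); 0.05 is the
#'   conventional headline threshold.
#' @return An object of class `support_summary`: list with
#' \describe{
#'   \item{cutoffs}{the threshold grid;}
#'   \item{supported_fraction}{tibble `cutoff`, `fraction`: share of
#'     covered edges whose best (minimum) quantile rank is <= cutoff;}
#'   \item{per_metapath}{tibble `metapath`, `cutoff`, `n_supported`,
#'     `fraction` (share of that metapath's covered edges), `n_covered`,
#'     `coverage`;}
#'   \item{edge_support}{tibble per covered edge with `min_qr` and one
#'     accumulated-count column `n_le_<cutoff>` per cutoff (number of
#'     metapaths supporting the edge at that cutoff);}
#'   \item{dataset_coverage}{fraction of input edges covered by >= 1
#'     metapath; plus `n_edges`, `n_covered`.}
#' }
#' @export
summarize_support <- function(support, cutoffs = c(0.01, 0.05, 0.10, 0.25)) {
  if (nrow(support) == 0) rlang::abort("nothing to summarize: empty support table")
  if (is.unsorted(cutoffs, strictly = TRUE) ||
      any(cutoffs <= 0) || any(cutoffs > 1)) {
    rlang::abort("cutoffs must be strictly ascending and in (0, 1]")
  }
  tbl <- tibble::as_tibble(support)
  n_edges <- nrow(attr(support, "edges"))

  edge_groups <- dplyr::group_by(
    tbl, .data$src_id, .data$src_type, .data$dst_id, .data$dst_type
  )
  edge_support <- dplyr::summarise(
    edge_groups,
    n_metapaths = dplyr::n(),
    min_qr = min(.data$quantile_rank),
    .groups = "drop"
  )
  for (c_ in cutoffs) {
    counts <- dplyr::summarise(
      edge_groups,
      n = sum(.data$quantile_rank <= c_), .groups = "drop"
    )$n
    edge_support[[sprintf("n_le_%g", c_)]] <- counts
  }

  supported_fraction <- tibble::tibble(
    cutoff = cutoffs,
    fraction = vapply(cutoffs, function(c_) mean(edge_support$min_qr <= c_), 0)
  )

  cov <- support_coverage(support)
  per_metapath <- tidyr::crossing(cov, cutoff = cutoffs)
  counts <- dplyr::summarise(
    dplyr::group_by(
      tidyr::crossing(tbl[, c("metapath", "quantile_rank")], cutoff = cutoffs),
      .data$metapath, .data$cutoff
    ),
    n_supported = sum(.data$quantile_rank <= .data$cutoff),
    .groups = "drop"
  )
  per_metapath <- dplyr::left_join(per_metapath, counts,
                                   by = c("metapath", "cutoff"))
  per_metapath <- dplyr::mutate(
    per_metapath,
    fraction = .data$n_supported / .data$n_covered
  )
  per_metapath <- dplyr::arrange(per_metapath, .data$metapath, .data$cutoff)
  per_metapath <- per_metapath[, c("metapath", "cutoff", "n_supported",
                                   "fraction", "n_covered", "coverage")]

  structure(
    list(
      cutoffs = cutoffs,
      supported_fraction = supported_fraction,
      per_metapath = per_metapath,
      edge_support = edge_support,
      n_edges = n_edges,
      n_covered = nrow(edge_support),
      dataset_coverage = nrow(edge_support) / n_edges
    ),
    class = "support_summary"
  )
}

#' @export
print.support_summary <- function(x, ...) {
  cat(sprintf(
    "# Support summary: %d/%d edges covered (%.1f%%)\n",
    x$n_covered, x$n_edges, 100 * x$dataset_coverage
  ))
  for (i in seq_along(x$cutoffs)) {
    cat(sprintf(
      "#   quantile rank <= %-5g: %5.1f%% of covered edges supported\n",
      x$cutoffs[i], 100 * x$supported_fraction$fraction[i]
    ))
  }
  invisible(x)
}

#' Tidy a support summary into a per-metapath tibble
#'
#' @param x A `support_summary`.
#' @param ... Unused.
#' @return The per-metapath stratification: one row per
#'   (metapath, cutoff) with supported counts, fractions and coverage.
#' @exportS3Method generics::tidy
tidy.support_summary <- function(x, ...) {
  x$per_metapath
}

#' One-row overview of a support summary
#'
#' @param x A `support_summary`.
#' @param headline_cutoff Which cutoff to report as the headline
#'   supported fraction (default 0.05).
#' @param ... Unused.
#' @return A one-row tibble: `n_edges`, `n_covered`, `dataset_coverage`,
#'   `n_metapaths`, `supported_fraction` at the headline cutoff.
#' @exportS3Method generics::glance
glance.support_summary <- function(x, headline_cutoff = 0.05, ...) {
  i <- which(x$cutoffs == headline_cutoff)
  frac <- if (length(i)) x$supported_fraction$fraction[i] else NA_real_
  tibble::tibble(
    n_edges = x$n_edges,
    n_covered = x$n_covered,
    dataset_coverage = x$dataset_coverage,
    n_metapaths = length(unique(x$per_metapath$metapath)),
    headline_cutoff = headline_cutoff,
    supported_fraction = frac
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
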