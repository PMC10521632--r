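# Degree-preserving randomization via repeated double-edge swaps,
# performed independently within each (src_type, dst_type) relation.
# Homogeneous relations are undirected; heterogeneous relations are
# bipartite, so only target-role endpoints are exchanged, which keeps
# both role-specific degree sequences intact.  Swaps creating
# duplicates or self-pairs are rejected and retried.

swap_relation <- function(src, dst, undirected, n_attempts) {
  n <- length(src)
  if (n < 2) return(list(src = src, dst = dst, swapped = FALSE))
  canon <- function(a, b) {
    if (undirected && a > b) c(b, a) else c(a, b)
  }
  used <- new.env(parent = emptyenv(), size = 2L * n)
  for (k in seq_len(n)) {
    assign(paste0(src[k], "\r", dst[k]), TRUE, envir = used)
  }
  e1s <- sample.int(n, n_attempts, replace = TRUE)
  e2s <- sample.int(n, n_attempts, replace = TRUE)
  coins <- if (undirected) stats::runif(n_attempts) < 0.5 else logical(n_attempts)
  for (t in seq_len(n_attempts)) {
    i <- e1s[t]; j <- e2s[t]
    if (i == j) next
    a1 <- src[i]; b1 <- dst[i]
    a2 <- src[j]; b2 <- dst[j]
    if (coins[t]) {
      # undirected alternative pairing: heads join (a1,a2) and (b1,b2)
      p1 <- canon(a1, a2); p2 <- canon(b1, b2)
    } else {
      p1 <- canon(a1, b2); p2 <- canon(a2, b1)
    }
    if (undirected && (p1[1] == p1[2] || p2[1] == p2[2])) next
    k1 <- paste0(p1[1], "\r", p1[2])
    k2 <- paste0(p2[1], "\r", p2[2])
    if (k1 == k2) next
    if (exists(k1, envir = used, inherits = FALSE) ||
        exists(k2, envir = used, inherits = FALSE)) next
    rm(list = c(paste0(a1, "\r", b1), paste0(a2, "\r", b2)), envir = used)
    assign(k1, TRUE, envir = used)
    assign(k2, TRUE, envir = used)
    src[i] <- p1[1]; dst[i] <- p1[2]
    src[j] <- p2[1]; dst[j] <- p2[2]
  }
  list(src = src, dst = dst, swapped = TRUE)
}

#' Degree-preserving permutation of an edge set
#'
#' Randomizes the dataset while preserving every node's degree within
#' each (src_type, dst_type) relation, using repeated double-edge swaps
#' (`swap_factor * n_edges` attempted swaps per relation).  This is the
#' null model behind the expected-support curve and the enrichment
#' scores: it keeps hubness fixed so that any excess support must come
#' from embedding proximity, not from degree.
#'
#' @param edges An `assoc_edges` tibble.
#' @param seed Integer seed; the permutation is deterministic given it.
#' @param swap_factor Attempted swaps per edge (default 10).
#' @return A permuted `assoc_edges` tibble with the same number of
#'   edges, the same per-relation degree sequences, and no duplicate or
#'   self edges.  Relations with a single edge are returned unpermuted
#'   with a warning.
#' @export
permute_edges <- function(edges, seed = 1L, swap_factor = 10) {
  tbl <- tibble::as_tibble(edges)[, c("src_id", "src_type", "dst_id", "dst_type")]
  withr::with_seed(seed, {
    parts <- split(
      tbl, paste(tbl$src_type, tbl$dst_type, sep = "\r"), drop = TRUE
    )
    parts <- parts[order(names(parts))]
    out <- lapply(parts, function(p) {
      undirected <- p$src_type[1] == p$dst_type[1]
      if (nrow(p) < 2) {
        rlang::warn(sprintf(
          "relation %s-%s has a single edge; returned unpermuted",
          p$src_type[1], p$dst_type[1]
        ))
        return(p)
      }
      r <- swap_relation(p$src_id, p$dst_id, undirected,
                         n_attempts = ceiling(swap_factor * nrow(p)))
      p$src_id <- r$src
      p$dst_id <- r$dst
      p
    })
    res <- dplyr::bind_rows(out)
  })
  new_edges(res)
}

#' Generate an ensemble of permuted edge sets
#'
#' Child seeds are derived from the master seed by fixed arithmetic
#' (`seed + index`), so the ensemble is reproducible while each
#' permutation uses an independent stream.
#'
#' @param edges An `assoc_edges` tibble.
#' @param n_perm Number of permuted networks (>= 2; default 25).
#' @param seed Master seed.
#' @param swap_factor Passed to [permute_edges()].
#' @return A list of permuted `assoc_edges`, of class
#'   `permutation_ensemble`, with attributes `n_perm`, `seed` and
#'   `scheme = "degree_preserving_swap"`.
#' @export
permutation_ensemble <- function(edges, n_perm = 25, seed = 1L,
                                 swap_factor = 10) {
  if (n_perm < 2) rlang::abort("n_perm must be >= 2")
  sets <- lapply(seq_len(n_perm), function(i) {
    permute_edges(edges, seed = seed + i, swap_factor = swap_factor)
  })
  structure(sets,
            n_perm = n_perm, seed = seed,
            scheme = "degree_preserving_swap",
            class = "permutation_ensemble")
}

#' Score every permuted edge set of an ensemble
#'
#' @param ensemble A `permutation_ensemble`.
#' @param spaces,backgrounds As in [score_dataset()]; the same
#'   backgrounds as the observed run, so observed and null quantile
#'   ranks are comparable.
#' @return List of `support_tbl`s, one per permuted set.
#' @export
score_ensemble <- function(ensemble, spaces, backgrounds) {
  lapply(ensemble, function(e) {
    suppressMessages(score_dataset(e, spaces, backgrounds))
  })
}

#' Observed versus expected support across the cutoff grid
#'
#' Runs the full scoring on `n_perm` degree-preserving permutations of
#' the dataset and summarises, per cutoff, the mean and standard
#' deviation of the null supported fraction, next to the observed one.
#' An observed curve well above the expected one indicates the dataset
#' is more backed up by the embedding contexts than chance predicts.
#'
#' @param edges An `assoc_edges` tibble.
#' @param spaces,backgrounds As in [score_dataset()].
#' @param cutoffs Quantile-rank threshold grid.
#' @param n_perm,seed,swap_factor Passed to [permutation_ensemble()].
#' @param support Optional pre-computed observed `support_tbl` (skips
#'   rescoring the observed edges).
#' @return Object of class `expected_support`: list with `curve`
#'   (tibble `cutoff`, `observed`, `expected_mean`, `expected_sd`),
#'   `observed_summary`, `ensemble_tables`, `ensemble`, `n_perm`,
#'   `seed`, `scheme`.
#' @export
expected_support <- function(edges, spaces, backgrounds,
                             cutoffs = c(0.01, 0.05, 0.10, 0.25),
                             n_perm = 25, seed = 1L, swap_factor = 10,
                             support = NULL) {
  app <- suppressWarnings(applicable_spaces(spaces, edges))
  if (nrow(app) == 0) rlang::abort("zero applicable spaces; nothing to permute against")
  if (is.null(support)) {
    support <- score_dataset(edges, spaces, backgrounds)
  }
  obs_summary <- summarize_support(support, cutoffs)
  ensemble <- permutation_ensemble(edges, n_perm = n_perm, seed = seed,
                                   swap_factor = swap_factor)
  tables <- score_ensemble(ensemble, spaces, backgrounds)
  frac <- vapply(tables, function(tb) {
    if (nrow(tb) == 0) return(rep(NA_real_, length(cutoffs)))
    summarize_support(tb, cutoffs)$supported_fraction$fraction
  }, numeric(length(cutoffs)))
  frac <- matrix(frac, nrow = length(cutoffs))
  curve <- tibble::tibble(
    cutoff = cutoffs,
    observed = obs_summary$supported_fraction$fraction,
    expected_mean = apply(frac, 1, mean, na.rm = TRUE),
    expected_sd = apply(frac, 1, stats::sd, na.rm = TRUE)
  )
  structure(
    list(
      curve = curve,
      observed_summary = obs_summary,
      ensemble_tables = tables,
      ensemble = ensemble,
      n_perm = n_perm, seed = seed,
      scheme = "degree_preserving_swap"
    ),
    class = "expected_support"
  )
}

#' @export
print.expected_support <- function(x, ...) {
  cat(sprintf("# Expected support over %d degree-preserving permutations\n",
              x$n_perm))
  print(x$curve)
  invisible(x)
}

#' Tidy the observed-versus-expected support curve
#'
#' @param x An `expected_support` object.
#' @param ... Unused.
#' @return The `curve` tibble.
#' @exportS3Method generics::tidy
tidy.expected_support <- function(x, ...) x$curve

#' Empirical enrichment scores per (edge, metapath)
#'
#' For each scored (edge, metapath) combination, the observed quantile
#' rank is compared with the pool of quantile ranks that the same
#' metapath assigned to the permuted networks.  The empirical p-value
#' uses the standard +1 pseudocount,
#' `p = (1 + #\{pooled <= observed\}) / (1 + pool size)`, so it is never
#' zero and never smaller than `1 / (pool + 1)`; the enrichment score
#' is `-log10(p)`.  Pairs significantly close in one biomedical context
#' get high scores.
#'
#' @param support Observed `support_tbl`.
#' @param ensemble_tables List of permuted `support_tbl`s computed on
#'   the same spaces (see [score_ensemble()]).
#' @return A tibble: the support rows plus `p_emp`, `enrichment_score`
#'   and `pool_size`.  Metapaths with an empty null pool get `NA` with
#'   a warning.
#' @export
enrichment_scores <- function(support, ensemble_tables) {
  pooled <- dplyr::bind_rows(lapply(ensemble_tables, tibble::as_tibble))
  pools <- split(pooled$quantile_rank, pooled$metapath)
  pools <- lapply(pools, sort)
  out <- tibble::as_tibble(support)
  p <- rep(NA_real_, nrow(out))
  psize <- rep(NA_integer_, nrow(out))
  for (m in unique(out$metapath)) {
    rows <- which(out$metapath == m)
    pool <- pools[[m]]
    if (is.null(pool) || length(pool) == 0) {
      rlang::warn(sprintf(
        "metapath %s: empty permutation pool; enrichment unavailable", m
      ))
      next
    }
    cnt <- findInterval(out$quantile_rank[rows], pool)
    p[rows] <- (1 + cnt) / (1 + length(pool))
    psize[rows] <- length(pool)
  }
  out$p_emp <- p
  out$enrichment_score <- -log10(p)
  out$pool_size <- psize
  out
}
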