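# The analytical canvas: six panels summarising a full run.
# (a) edge x metapath heatmap of quantile ranks (top 10 most
#     supportive metapaths; warm = low rank = strong support)
# (b) supported fraction per cutoff, with dataset coverage
# (c) observed vs expected support across the cutoff grid
# (d) metapath AUROC bars (top edge-task metapaths highlighted,
#     profile task in a second colour)
# (e) top edges by accumulated support across cutoffs
# (f) per-metapath supported percentage stratified by cutoff

placeholder_panel <- function(label, msg) {
  ggplot2::ggplot() +
    ggplot2::annotate("text", x = 0, y = 0, label = msg, size = 3.2) +
    ggplot2::theme_void() +
    ggplot2::labs(title = label)
}

panel_heatmap <- function(summary, support, n_top = 10) {
  if (is.null(support) || nrow(support) == 0) {
    return(placeholder_panel("(a) support heatmap", "no covered edges"))
  }
  headline <- summary$cutoffs[min(2, length(summary$cutoffs))]
  top <- dplyr::filter(summary$per_metapath, .data$cutoff == headline)
  top <- dplyr::arrange(top, dplyr::desc(.data$fraction), .data$metapath)
  top <- utils::head(top$metapath, n_top)
  tbl <- dplyr::filter(tibble::as_tibble(support), .data$metapath %in% top)
  tbl$edge <- paste(tbl$src_id, tbl$dst_id, sep = "–")
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = .data$edge, y = factor(.data$metapath, levels = rev(top)),
    fill = .data$quantile_rank
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#b2182b", high = "#2166ac",
                                 limits = c(0, 1), name = "quantile\nrank") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(title = "(a) support per edge and metapath",
                  x = "input edges", y = NULL)
}

panel_stratified <- function(summary) {
  df <- summary$supported_fraction
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cutoff), y = .data$fraction)) +
    ggplot2::geom_col(fill = "#b2182b") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::labs(
      title = "(b) supported fraction by cutoff",
      subtitle = sprintf("dataset coverage: %d/%d edges (%.0f%%)",
                         summary$n_covered, summary$n_edges,
                         100 * summary$dataset_coverage),
      x = "quantile-rank cutoff", y = "fraction of covered edges"
    )
}

panel_expected <- function(expected) {
  if (is.null(expected)) {
    return(placeholder_panel("(c) observed vs expected", "no permutation run"))
  }
  df <- tidyr::pivot_longer(expected$curve, c("observed", "expected_mean"),
                            names_to = "series", values_to = "fraction")
  ggplot2::ggplot(df, ggplot2::aes(.data$cutoff, .data$fraction,
                                   colour = .data$series)) +
    ggplot2::geom_ribbon(
      data = expected$curve,
      ggplot2::aes(x = .data$cutoff,
                   ymin = pmax(.data$expected_mean - .data$expected_sd, 0),
                   ymax = pmin(.data$expected_mean + .data$expected_sd, 1)),
      inherit.aes = FALSE, alpha = 0.2
    ) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(
      values = c(observed = "#b2182b", expected_mean = "grey40"), name = NULL
    ) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(legend.position = "bottom") +
    ggplot2::labs(title = "(c) observed vs expected support",
                  x = "quantile-rank cutoff", y = "supported fraction")
}

panel_auroc <- function(ranking) {
  if (is.null(ranking) || nrow(ranking) == 0) {
    return(placeholder_panel("(d) metapath AUROC", "no applicable metapaths"))
  }
  df <- tidyr::pivot_longer(
    tibble::as_tibble(ranking), c("auroc_edges", "auroc_profile"),
    names_to = "task", values_to = "auroc"
  )
  df <- df[!is.na(df$auroc), ]
  df$task <- ifelse(df$task == "auroc_edges", "edges vs permuted",
                    "profile similarity")
  df$highlight <- df$is_top & df$task == "edges vs permuted"
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$auroc,
    y = factor(.data$metapath, levels = rev(ranking$metapath)),
    fill = .data$task, alpha = .data$highlight
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c("edges vs permuted" = "black",
                 "profile similarity" = "#2166ac"), name = NULL
    ) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.45),
                                guide = "none") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, linewidth = 0.3) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(legend.position = "bottom") +
    ggplot2::labs(title = "(d) metapath predictive AUROC",
                  x = "AUROC", y = NULL)
}

panel_accumulated <- function(summary, n_top = 15) {
  es <- summary$edge_support
  acc_cols <- grep("^n_le_", names(es), value = TRUE)
  if (length(acc_cols) == 0 || nrow(es) == 0) {
    return(placeholder_panel("(e) accumulated support", "no covered edges"))
  }
  # order by accumulated count at the strictest cutoff, descending
  es <- dplyr::arrange(es, dplyr::desc(.data[[acc_cols[1]]]),
                       dplyr::desc(.data$n_metapaths))
  es <- utils::head(es, n_top)
  es$edge <- paste(es$src_id, es$dst_id, sep = "–")
  df <- tidyr::pivot_longer(
    es[, c("edge", acc_cols)], dplyr::all_of(acc_cols),
    names_to = "cutoff", values_to = "n_metapaths"
  )
  df$cutoff <- sub("^n_le_", "", df$cutoff)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$n_metapaths, y = factor(.data$edge, levels = rev(es$edge)),
    fill = .data$cutoff
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_brewer(palette = "Reds", direction = -1,
                               name = "cutoff") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::labs(title = "(e) top edges by accumulated support",
                  x = "metapaths supporting the edge", y = NULL)
}

panel_metapath_fractions <- function(summary, n_top = 15) {
  df <- summary$per_metapath
  headline <- summary$cutoffs[min(2, length(summary$cutoffs))]
  ord <- dplyr::arrange(
    dplyr::filter(df, .data$cutoff == headline),
    dplyr::desc(.data$fraction), .data$metapath
  )$metapath
  df <- df[df$metapath %in% utils::head(ord, n_top), ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$fraction,
    y = factor(.data$metapath, levels = rev(utils::head(ord, n_top))),
    fill = factor(.data$cutoff)
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_brewer(palette = "Reds", direction = -1,
                               name = "cutoff") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::labs(title = "(f) supported share per metapath",
                  x = "fraction of covered edges supported", y = NULL)
}

#' Render the six-panel analytical canvas
#'
#' Panels with unavailable data degrade to annotated placeholder axes
#' rather than aborting, so the canvas is useful on sparse inputs.
#'
#' @param summary A `support_summary` (required).
#' @param expected Optional `expected_support`.
#' @param enrichment Optional enrichment tibble (annotates panel (a)).
#' @param ranking Optional `metapath_ranking`.
#' @param support Optional `support_tbl` backing panel (a).
#' @param path Optional output file; written via [ggplot2::ggsave()]
#'   with the device chosen by the file extension.
#' @return The assembled patchwork object, invisibly when `path` is
#'   given.
#' @export
render_canvas <- function(summary, expected = NULL, enrichment = NULL,
                          ranking = NULL, support = NULL, path = NULL) {
  panels <- list(
    panel_heatmap(summary, support),
    panel_stratified(summary),
    panel_expected(expected),
    panel_auroc(ranking),
    panel_accumulated(summary),
    panel_metapath_fractions(summary)
  )
  canvas <- patchwork::wrap_plots(panels, ncol = 2)
  if (!is.null(path)) {
    ggplot2::ggsave(path, canvas, width = 11, height = 12, dpi = 150)
    return(invisible(canvas))
  }
  canvas
}

#' Number of panels in an assembled canvas
#'
#' @param canvas A patchwork object from [render_canvas()].
#' @return Integer panel count.
#' @export
n_panels <- function(canvas) {
  length(canvas$patches$plots) + 1L
}

#' Run the full support-assessment pipeline
#'
#' Scores every edge in every applicable embedding space, aggregates to
#' a dataset-level support estimate, calibrates against a
#' degree-preserving permutation null (expected support + per-pair
#' enrichment), ranks metapaths by predictive AUROC, and (when
#' `out_dir` is given) writes the three result tables, a metadata file
#' and the analytical canvas.
#'
#' @param edges An `assoc_edges` tibble (see [read_edges()]).
#' @param spaces Named list of `embedding_space`s (see [load_spaces()]).
#' @param out_dir Optional output directory for [write_report()].
#' @param cutoffs Quantile-rank cutoff grid.
#' @param n_perm Number of permuted networks.
#' @param seed Master seed; the whole run is deterministic given it.
#' @param swap_factor Attempted swaps per edge in the permutation.
#' @param background_n,exact_threshold Background sampling controls
#'   (see [sample_background()]).
#' @param profile_jaccard,negative_ratio Profile-task label controls
#'   (see [build_profile_labels()]); set `profile_jaccard = NA` to skip
#'   the profile task.
#' @return A list of class `support_run`: `support`, `summary`,
#'   `expected`, `enrichment`, `ranking`, `backgrounds`, `params`, and
#'   (after writing) `report`.
#' @export
run_support_analysis <- function(edges, spaces, out_dir = NULL,
                                 cutoffs = c(0.01, 0.05, 0.10, 0.25),
                                 n_perm = 25, seed = 1L, swap_factor = 10,
                                 background_n = 10000,
                                 exact_threshold = 1e6,
                                 profile_jaccard = 0.5,
                                 negative_ratio = 1) {
  backgrounds <- sample_backgrounds(spaces, n = background_n, seed = seed,
                                    exact_threshold = exact_threshold)
  support <- score_dataset(edges, spaces, backgrounds)
  if (nrow(support) == 0) {
    rlang::warn("no applicable metapaths: emitting a degenerate report")
    summary <- NULL; expected <- NULL; enrichment <- NULL; ranking <- NULL
  } else {
    summary <- summarize_support(support, cutoffs)
    expected <- expected_support(edges, spaces, backgrounds,
                                 cutoffs = cutoffs, n_perm = n_perm,
                                 seed = seed, swap_factor = swap_factor,
                                 support = support)
    enrichment <- enrichment_scores(support, expected$ensemble_tables)
    edge_tbl <- edge_aurocs(edges, expected$ensemble, spaces)
    profile_tbl <- NULL
    if (!is.na(profile_jaccard)) {
      sig <- type_signature(edges)
      node_types <- unique(c(sig$src_type, sig$dst_type))
      profile_tbl <- dplyr::bind_rows(lapply(node_types, function(nt) {
        labels <- tryCatch(
          build_profile_labels(edges, nt, jaccard_threshold = profile_jaccard,
                               negative_ratio = negative_ratio,
                               seed = seed + 1000L),
          error = function(e) NULL
        )
        if (is.null(labels)) return(NULL)
        dplyr::bind_rows(lapply(spaces, function(sp) {
          suppressWarnings(profile_auroc(sp, labels))
        }))
      }))
    }
    ranking <- if (nrow(edge_tbl) > 0) {
      rank_metapaths(edge_tbl, profile_tbl)
    } else NULL
  }
  run <- structure(
    list(
      support = support, summary = summary, expected = expected,
      enrichment = enrichment, ranking = ranking,
      backgrounds = backgrounds,
      params = list(
        cutoffs = cutoffs, n_perm = n_perm, seed = seed,
        swap_factor = swap_factor, background_n = background_n,
        exact_threshold = exact_threshold,
        profile_jaccard = profile_jaccard,
        negative_ratio = negative_ratio,
        scheme = "degree_preserving_swap",
        n_edges = nrow(edges),
        version = as.character(utils::packageVersion("assocsupport"))
      )
    ),
    class = "support_run"
  )
  if (!is.null(out_dir)) {
    run$report <- write_report(run, out_dir)
  }
  run
}

#' Write the three result tables, metadata and canvas
#'
#' Emits `support_table.tsv` (one row per scored edge-metapath
#' combination, with enrichment columns), `metapath_summary.tsv`
#' (digested per-metapath counts: coverage and supported counts per
#' cutoff), `metapath_ranking.tsv` (predictive AUROCs), a flat
#' key-value `run_metadata.txt` sufficient to reproduce the run, and
#' `canvas.png`.  Partial results are written with explicit `NA`
#' markers.
#'
#' @param run A `support_run` from [run_support_analysis()].
#' @param out_dir Output directory, created if needed.
#' @return A list (class `run_report`) of output paths plus a
#'   `complete` flag.
#' @export
write_report <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    support_table = file.path(out_dir, "support_table.tsv"),
    summary = file.path(out_dir, "metapath_summary.tsv"),
    ranking = file.path(out_dir, "metapath_ranking.tsv"),
    metadata = file.path(out_dir, "run_metadata.txt"),
    canvas = file.path(out_dir, "canvas.png")
  )

  tab1 <- if (!is.null(run$enrichment)) {
    run$enrichment
  } else {
    tibble::as_tibble(run$support)
  }
  readr::write_tsv(tab1, paths$support_table, progress = FALSE)

  tab2 <- if (!is.null(run$summary)) {
    wide <- tidyr::pivot_wider(
      run$summary$per_metapath,
      id_cols = c("metapath", "n_covered", "coverage"),
      names_from = "cutoff", values_from = "n_supported",
      names_prefix = "n_supported_le_"
    )
    wide
  } else {
    tibble::tibble(metapath = NA_character_, n_covered = NA_integer_,
                   coverage = NA_real_)
  }
  readr::write_tsv(tab2, paths$summary, progress = FALSE)

  tab3 <- if (!is.null(run$ranking)) {
    tibble::as_tibble(run$ranking)
  } else {
    tibble::tibble(metapath = NA_character_, entity_group = NA_character_,
                   auroc_edges = NA_real_, auroc_profile = NA_real_,
                   n_pos = NA_integer_, n_neg = NA_integer_,
                   rank = NA_integer_, is_top = NA)
  }
  readr::write_tsv(tab3, paths$ranking, progress = FALSE)

  meta <- run$params
  meta$cutoffs <- paste(meta$cutoffs, collapse = ",")
  meta_tbl <- tibble::tibble(
    key = names(meta),
    value = vapply(meta, function(v) paste(format(v), collapse = ","), "")
  )
  readr::write_tsv(meta_tbl, paths$metadata, progress = FALSE)

  if (!is.null(run$summary)) {
    render_canvas(run$summary, run$expected, run$enrichment, run$ranking,
                  run$support, path = paths$canvas)
  } else {
    ggplot2::ggsave(
      paths$canvas,
      placeholder_panel("support assessment", "no applicable metapaths"),
      width = 6, height = 4, dpi = 150
    )
  }

  structure(
    c(paths, list(complete = !is.null(run$summary))),
    class = "run_report"
  )
}

#' @export
print.support_run <- function(x, ...) {
  cat("# Support-assessment run\n")
  if (!is.null(x$summary)) print(x$summary)
  if (!is.null(x$expected)) print(x$expected$curve)
  if (!is.null(x$ranking)) {
    cat("# Top metapaths by edge AUROC:\n")
    print(utils::head(tibble::as_tibble(x$ranking), 5))
  }
  invisible(x)
}

#' Glance at a full run
#'
#' @param x A `support_run`.
#' @param ... Passed to [glance.support_summary()].
#' @return A one-row tibble combining the summary glance with the top
#'   metapath and its AUROC.
#' @exportS3Method generics::glance
glance.support_run <- function(x, ...) {
  if (is.null(x$summary)) {
    return(tibble::tibble(n_edges = x$params$n_edges, n_covered = 0L,
                          dataset_coverage = 0))
  }
  g <- glance(x$summary, ...)
  if (!is.null(x$ranking) && nrow(x$ranking) > 0) {
    g$top_metapath <- x$ranking$metapath[1]
    g$top_auroc_edges <- x$ranking$auroc_edges[1]
  }
  g
}
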