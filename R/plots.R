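#' Plot a support summary
#'
#' Supported fraction per quantile-rank cutoff, with dataset coverage
#' in the subtitle.
#'
#' @param object A `support_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.support_summary <- function(object, ...) {
  panel_stratified(object)
}

#' Plot observed versus expected support
#'
#' @param object An `expected_support`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.expected_support <- function(object, ...) {
  panel_expected(object)
}

#' Plot a metapath ranking
#'
#' Horizontal AUROC bars; top edge-task metapaths highlighted, profile
#' task in a second colour.
#'
#' @param object A `metapath_ranking`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.metapath_ranking <- function(object, ...) {
  panel_auroc(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
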