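#' Canonicalise a data frame of typed entity pairs into an edge set
#'
#' An edge set is the dataset under assessment: a deduplicated tibble of
#' typed entity pairs.  Homogeneous pairs (same entity type on both
#' sides, e.g. protein-protein interactions or disease comorbidities)
#' are undirected: they are stored in canonical order (lexicographic on
#' identifier) so that `(a, b)` and `(b, a)` are the same edge.
#' Heterogeneous pairs (e.g. compound-gene) keep their given
#' orientation, since the two sides play different roles.  Self-pairs
#' are rejected rather than scored: a self-distance of zero would
#' trivially inflate support.
#'
#' @param x A data frame with columns `src_id`, `src_type`, `dst_id`,
#'   `dst_type`, or with columns `src_id`, `dst_id` plus `types` giving
#'   the global type pair.
#' @param types Optional character vector of length 2 with the source
#'   and target entity-type codes, for two-column inputs.
#' @param quiet If `TRUE`, suppress the message reporting dropped
#'   duplicate and self-pair rows.
#' @return A tibble of class `assoc_edges` with columns `src_id`,
#'   `src_type`, `dst_id`, `dst_type`, deduplicated and canonically
#'   ordered.  Attributes `n_input`, `n_self_dropped` and
#'   `n_dup_dropped` record what was removed.
#' @examples
#' df <- data.frame(src_id = c("P1", "P2"), src_type = "GEN",
#'                  dst_id = c("P2", "P1"), dst_type = "GEN")
#' as_edges(df)  # one edge: the two rows are the same undirected pair
#' @export
as_edges <- function(x, types = NULL, quiet = FALSE) {
  x <- tibble::as_tibble(x)
  if (!is.null(types)) {
    if (length(types) != 2) {
      rlang::abort("`types` must be a length-2 character vector (src, dst)")
    }
    if (!all(c("src_id", "dst_id") %in% names(x))) {
      rlang::abort("two-column input must have columns src_id, dst_id")
    }
    x$src_type <- types[1]
    x$dst_type <- types[2]
  }
  need <- c("src_id", "src_type", "dst_id", "dst_type")
  if (!all(need %in% names(x))) {
    rlang::abort(paste0(
      "edge input must have columns ",
      paste(need, collapse = ", "),
      " (or src_id, dst_id plus `types`)"
    ))
  }
  x <- dplyr::select(x, dplyr::all_of(need))
  x$src_id <- as.character(x$src_id)
  x$dst_id <- as.character(x$dst_id)
  x$src_type <- as.character(x$src_type)
  x$dst_type <- as.character(x$dst_type)
  if (nrow(x) == 0) rlang::abort("no edges")

  assert_entity_type(x$src_type, "entity type")
  assert_entity_type(x$dst_type, "entity type")
  if (any(!nzchar(x$src_id)) || any(!nzchar(x$dst_id))) {
    rlang::abort("empty identifier in edge list")
  }
  if (any(grepl("[\t\n\r]", x$src_id)) || any(grepl("[\t\n\r]", x$dst_id))) {
    rlang::abort("identifiers must not contain tab or newline characters")
  }

  n_input <- nrow(x)
  self <- x$src_type == x$dst_type & x$src_id == x$dst_id
  n_self <- sum(self)
  x <- x[!self, , drop = FALSE]
  if (nrow(x) == 0) rlang::abort("no edges (all rows were self-pairs)")

  # canonical order for undirected homogeneous pairs
  swap <- x$src_type == x$dst_type & x$src_id > x$dst_id
  if (any(swap)) {
    tmp <- x$src_id[swap]
    x$src_id[swap] <- x$dst_id[swap]
    x$dst_id[swap] <- tmp
  }
  n_before <- nrow(x)
  x <- dplyr::distinct(x)
  n_dup <- n_before - nrow(x)

  if (!quiet && (n_self > 0 || n_dup > 0)) {
    rlang::inform(sprintf(
      "dropped %d self-pair(s) and %d duplicate(s); %d unique edge(s) kept",
      n_self, n_dup, nrow(x)
    ))
  }
  new_edges(x, n_input = n_input, n_self = n_self, n_dup = n_dup)
}

new_edges <- function(x, n_input = nrow(x), n_self = 0L, n_dup = 0L) {
  structure(
    tibble::as_tibble(x),
    n_input = n_input,
    n_self_dropped = n_self,
    n_dup_dropped = n_dup,
    class = c("assoc_edges", class(tibble::tibble()))
  )
}

#' Read a typed edge list from a TSV file
#'
#' The file must have a header line `src_id<TAB>src_type<TAB>dst_id<TAB>
#' dst_type` (four-column dialect) or `src_id<TAB>dst_id` with the type
#' pair supplied via `types` (two-column dialect).  Lines starting with
#' `#` are ignored.  Identifier matching everywhere in the package is
#' exact, case-sensitive string equality; no identifier mapping is
#' attempted.
#'
#' @param path Path to a tab-separated edge file.
#' @param types Optional length-2 character vector naming the source and
#'   target entity types for two-column files.
#' @param quiet Passed on to [as_edges()].
#' @return An `assoc_edges` tibble (see [as_edges()]).
#' @seealso [write_edges()]
#' @export
read_edges <- function(path, types = NULL, quiet = FALSE) {
  if (!file.exists(path)) rlang::abort(sprintf("edge file not found: %s", path))
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (nrow(df) == 0) rlang::abort("no edges")
  if (ncol(df) == 2 && is.null(types)) {
    rlang::abort("two-column edge file requires `types = c(src, dst)`")
  }
  if (ncol(df) == 2) names(df) <- c("src_id", "dst_id")
  as_edges(df, types = if (ncol(df) == 2) types else NULL, quiet = quiet)
}

#' Write an edge set to a TSV file
#'
#' Writes the four-column dialect read back by [read_edges()];
#' `read_edges(write_edges(e, f))` is the identity on canonical edge
#' sets.
#'
#' @param edges An `assoc_edges` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  stopifnot(is.data.frame(edges))
  readr::write_tsv(
    edges[, c("src_id", "src_type", "dst_id", "dst_type")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Type signature of an edge set
#'
#' @param edges An `assoc_edges` tibble.
#' @return A tibble with columns `src_type`, `dst_type`: the distinct
#'   ordered type pairs present in the edge set.
#' @export
type_signature <- function(edges) {
  dplyr::distinct(
    tibble::tibble(src_type = edges$src_type, dst_type = edges$dst_type)
  )
}

# "TYPE:ID" keys; used wherever nodes from several types share one
# namespace (neighbour sets, degree bookkeeping).
node_key <- function(type, id) paste(type, id, sep = ":")

edge_key <- function(edges) {
  paste(edges$src_type, edges$src_id, edges$dst_type, edges$dst_id, sep = "\r")
}

#' @export
print.assoc_edges <- function(x, ...) {
  sig <- type_signature(x)
  cat(sprintf(
    "# Edge set: %d edge(s), %d type pair(s): %s\n",
    nrow(x), nrow(sig),
    paste(sprintf("%s-%s", sig$src_type, sig$dst_type), collapse = ", ")
  ))
  NextMethod()
}
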