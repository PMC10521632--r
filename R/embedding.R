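#' Construct a metapath embedding space
#'
#' An embedding space is one biomedical context: a metapath label (for
#' example `"GEN-ppi-GEN"` or `"CPD-int-GEN"`), the entity types at its
#' two endpoints, and a vocabulary of fixed-dimension real vectors per
#' endpoint role.  Entities that are close in a space share biomedical
#' properties in that context, which is what the support score
#' measures.  Endpoint types are parsed from the first and last
#' hyphen-delimited tokens of the metapath name (the field's naming
#' convention, e.g. `"CPD-trt-DIS-ass-GEN"` runs from compounds to
#' genes).
#'
#' Zero-norm vectors cannot enter a cosine distance; such rows are
#' dropped at construction with a warning.
#'
#' @param metapath Metapath name; its first and last `-`-separated
#'   tokens must be valid entity-type codes.
#' @param vectors For a single-vocabulary (homogeneous) space: a numeric
#'   matrix with one row per entity, rownames = identifiers.
#' @param src_vectors,dst_vectors For a two-vocabulary (heterogeneous)
#'   space: the source-role and target-role matrices, rownames =
#'   identifiers.
#' @return An object of class `embedding_space`: a list with elements
#'   `metapath`, `src_type`, `dst_type`, `dim`, `single_vocab`, and the
#'   role matrices `src` and `dst` (the same matrix when single-vocab).
#' @examples
#' m <- matrix(rnorm(40), 5, 8, dimnames = list(paste0("G", 1:5), NULL))
#' sp <- embedding_space("GEN-ppi-GEN", vectors = m)
#' sp$dim
#' @export
embedding_space <- function(metapath, vectors = NULL,
                            src_vectors = NULL, dst_vectors = NULL) {
  tokens <- strsplit(metapath, "-", fixed = TRUE)[[1]]
  if (length(tokens) < 3) {
    rlang::abort(sprintf("malformed metapath name '%s'", metapath))
  }
  src_type <- tokens[1]
  dst_type <- tokens[length(tokens)]
  if (!is_entity_type(src_type) || !is_entity_type(dst_type)) {
    rlang::abort(sprintf(
      "metapath '%s' endpoint tokens ('%s', '%s') are not valid entity types",
      metapath, src_type, dst_type
    ))
  }

  single <- !is.null(vectors)
  if (single && (!is.null(src_vectors) || !is.null(dst_vectors))) {
    rlang::abort("give either `vectors` or `src_vectors`+`dst_vectors`, not both")
  }
  if (!single && (is.null(src_vectors) || is.null(dst_vectors))) {
    rlang::abort("two-vocabulary space needs both `src_vectors` and `dst_vectors`")
  }
  if (single && src_type != dst_type) {
    rlang::abort("single-vocabulary space requires identical endpoint types")
  }

  check_mat <- function(m, role) {
    if (!is.matrix(m) || !is.numeric(m)) {
      rlang::abort(sprintf("%s vectors must be a numeric matrix", role))
    }
    if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
      rlang::abort(sprintf("%s vector matrix needs unique rownames (identifiers)", role))
    }
    if (anyNA(m)) rlang::abort(sprintf("%s vectors contain NA", role))
    nrm <- sqrt(rowSums(m^2))
    zero <- nrm == 0
    if (any(zero)) {
      rlang::warn(sprintf(
        "space %s: dropped %d zero-norm %s vector(s)", metapath, sum(zero), role
      ))
      m <- m[!zero, , drop = FALSE]
    }
    m
  }

  if (single) {
    src <- dst <- check_mat(vectors, "entity")
  } else {
    src <- check_mat(src_vectors, "source-role")
    dst <- check_mat(dst_vectors, "target-role")
    if (ncol(src) != ncol(dst)) {
      rlang::abort("source- and target-role matrices must share one dimension")
    }
  }
  structure(
    list(
      metapath = metapath, src_type = src_type, dst_type = dst_type,
      dim = ncol(src), single_vocab = single, src = src, dst = dst
    ),
    class = "embedding_space"
  )
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf(
    "# Embedding space %s (%s -> %s), dim %d, %s vocab: %d source / %d target\n",
    x$metapath, x$src_type, x$dst_type, x$dim,
    if (x$single_vocab) "single" else "dual",
    nrow(x$src), nrow(x$dst)
  ))
  invisible(x)
}

read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df[[1]], NULL)
  storage.mode(m) <- "double"
  m
}

write_matrix_tsv <- function(m, path) {
  df <- tibble::as_tibble(m, .name_repair = ~ paste0("v", seq_along(.x)))
  df <- tibble::add_column(df, id = rownames(m), .before = 1)
  readr::write_tsv(df, path, progress = FALSE)
}

#' Load one embedding space from a directory
#'
#' The on-disk layout is a directory with a `meta.yaml` file (keys
#' `metapath`, `dim`, `src_type`, `dst_type`, `single_vocab`) and either
#' one matrix file `emb.tsv` (single vocabulary) or two, `src.tsv` and
#' `dst.tsv` (one per endpoint role).  Matrix files are tab-separated:
#' first column the identifier, then `dim` float columns.
#'
#' @param dirpath Directory of one space.
#' @return An `embedding_space` object.
#' @seealso [write_space()], [load_spaces()]
#' @export
load_space <- function(dirpath) {
  meta_path <- file.path(dirpath, "meta.yaml")
  if (!file.exists(meta_path)) {
    rlang::abort(sprintf("no meta.yaml in %s", dirpath))
  }
  meta <- yaml::read_yaml(meta_path)
  for (k in c("metapath", "dim", "single_vocab")) {
    if (is.null(meta[[k]])) rlang::abort(sprintf("meta.yaml lacks key '%s'", k))
  }
  if (isTRUE(meta$single_vocab)) {
    m <- read_matrix_tsv(file.path(dirpath, "emb.tsv"))
    if (ncol(m) != meta$dim) {
      rlang::abort(sprintf(
        "space %s: declared dim %d but matrix has %d columns",
        meta$metapath, meta$dim, ncol(m)
      ))
    }
    sp <- embedding_space(meta$metapath, vectors = m)
  } else {
    ms <- read_matrix_tsv(file.path(dirpath, "src.tsv"))
    md <- read_matrix_tsv(file.path(dirpath, "dst.tsv"))
    if (ncol(ms) != meta$dim || ncol(md) != meta$dim) {
      rlang::abort(sprintf(
        "space %s: declared dim %d but matrices have %d/%d columns",
        meta$metapath, meta$dim, ncol(ms), ncol(md)
      ))
    }
    sp <- embedding_space(meta$metapath, src_vectors = ms, dst_vectors = md)
  }
  declared <- c(meta$src_type, meta$dst_type)
  if (!is.null(meta$src_type) &&
      !identical(declared, c(sp$src_type, sp$dst_type))) {
    rlang::abort(sprintf(
      "space %s: declared endpoint types (%s, %s) disagree with metapath name",
      meta$metapath, meta$src_type, meta$dst_type
    ))
  }
  sp
}

#' Write an embedding space to a directory
#'
#' Inverse of [load_space()].
#'
#' @param space An `embedding_space`.
#' @param dirpath Target directory (created if needed).
#' @return `dirpath`, invisibly.
#' @export
write_space <- function(space, dirpath) {
  dir.create(dirpath, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    metapath = space$metapath, dim = space$dim,
    src_type = space$src_type, dst_type = space$dst_type,
    single_vocab = space$single_vocab
  )
  yaml::write_yaml(meta, file.path(dirpath, "meta.yaml"))
  if (space$single_vocab) {
    write_matrix_tsv(space$src, file.path(dirpath, "emb.tsv"))
  } else {
    write_matrix_tsv(space$src, file.path(dirpath, "src.tsv"))
    write_matrix_tsv(space$dst, file.path(dirpath, "dst.tsv"))
  }
  invisible(dirpath)
}

#' Load every embedding space under a directory
#'
#' @param dirpath Directory whose subdirectories each hold one space.
#' @return A named list of `embedding_space` objects, keyed by metapath.
#' @export
load_spaces <- function(dirpath) {
  subdirs <- list.dirs(dirpath, recursive = FALSE)
  subdirs <- subdirs[file.exists(file.path(subdirs, "meta.yaml"))]
  if (length(subdirs) == 0) {
    rlang::abort(sprintf("no embedding spaces found under %s", dirpath))
  }
  spaces <- lapply(sort(subdirs), load_space)
  names(spaces) <- vapply(spaces, `[[`, "", "metapath")
  spaces
}

#' Find the embedding spaces applicable to an edge set
#'
#' A space applies to a dataset when its endpoint type pair matches a
#' type pair present in the edge set, in either orientation; the
#' pipeline selects the relevant biomedical contexts automatically this
#' way.  `orientation == "reverse"` means the edge's source maps to the
#' space's target role.
#'
#' @param spaces A list of `embedding_space` objects.
#' @param edges An `assoc_edges` tibble.
#' @return A tibble with one row per applicable (space, edge-type-pair)
#'   combination: columns `metapath`, `edge_src_type`, `edge_dst_type`,
#'   `orientation` (`"forward"`/`"reverse"`) and `n_edges` (edges of
#'   that type pair).  Zero rows (with a warning) when nothing applies.
#' @export
applicable_spaces <- function(spaces, edges) {
  sig <- type_signature(edges)
  n_by_pair <- dplyr::count(
    tibble::as_tibble(edges), .data$src_type, .data$dst_type
  )
  rows <- list()
  for (sp in spaces) {
    for (i in seq_len(nrow(sig))) {
      es <- sig$src_type[i]
      ed <- sig$dst_type[i]
      ori <- NULL
      if (sp$src_type == es && sp$dst_type == ed) {
        ori <- "forward"
      } else if (sp$src_type == ed && sp$dst_type == es) {
        ori <- "reverse"
      }
      if (is.null(ori)) next
      n <- n_by_pair$n[n_by_pair$src_type == es & n_by_pair$dst_type == ed]
      rows[[length(rows) + 1]] <- tibble::tibble(
        metapath = sp$metapath,
        edge_src_type = es, edge_dst_type = ed,
        orientation = ori, n_edges = n
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    metapath = character(), edge_src_type = character(),
    edge_dst_type = character(), orientation = character(),
    n_edges = integer()
  )
  out <- dplyr::filter(out, .data$n_edges > 0)
  if (nrow(out) == 0) {
    rlang::warn("0 applicable metapaths for this edge set")
  }
  out
}

#' Build a space's empirical background distance distribution
#'
#' The support score of a pair is its quantile rank among cosine
#' distances of arbitrary cross-role entity pairs in the same space;
#' this function builds that background.  When the number of distinct
#' cross-role pairs is at most `exact_threshold` all of them are
#' enumerated (`exact = TRUE`); otherwise `n` pairs are drawn uniformly
#' with replacement, excluding same-identifier pairs in
#' single-vocabulary spaces.
#'
#' @param space An `embedding_space`.
#' @param n Sample size for the sampled mode (>= 100).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param exact_threshold Enumerate exhaustively up to this many pairs.
#' @return An object of class `background_sample`: list with `metapath`,
#'   sorted `distances` (each in `[0, 2]`), `n`, `seed`, `exact`.
#' @export
sample_background <- function(space, n = 10000, seed = 1L,
                              exact_threshold = 1e6) {
  if (n < 100) rlang::abort("background sample size must be >= 100")
  ns <- nrow(space$src)
  nd <- nrow(space$dst)
  npairs <- if (space$single_vocab) ns * (ns - 1) / 2 else as.double(ns) * nd
  if ((space$single_vocab && ns < 2) || npairs < 1) {
    rlang::abort(sprintf("space %s too small for a background", space$metapath))
  }
  U <- normalize_rows(space$src)
  V <- if (space$single_vocab) U else normalize_rows(space$dst)

  if (npairs <= exact_threshold) {
    if (space$single_vocab) {
      k <- ns
      i <- rep.int(seq_len(k - 1), (k - 1):1)
      j <- sequence((k - 1):1, from = 2:k)
    } else {
      i <- rep(seq_len(ns), each = nd)
      j <- rep.int(seq_len(nd), ns)
    }
    d <- chunked_row_cosine(U, V, i, j)
    exact <- TRUE
  } else {
    d <- withr::with_seed(seed, {
      i <- sample.int(ns, n, replace = TRUE)
      j <- sample.int(nd, n, replace = TRUE)
      if (space$single_vocab) {
        while (any(clash <- i == j)) {
          j[clash] <- sample.int(nd, sum(clash), replace = TRUE)
        }
      }
      chunked_row_cosine(U, V, i, j)
    })
    exact <- FALSE
  }
  structure(
    list(
      metapath = space$metapath,
      distances = sort(d), n = length(d),
      seed = seed, exact = exact
    ),
    class = "background_sample"
  )
}

#' Build backgrounds for a list of spaces
#'
#' Convenience wrapper over [sample_background()]; each space gets a
#' child seed `seed + position` so streams are independent but
#' reproducible from one master seed.
#'
#' @param spaces Named list of `embedding_space` objects.
#' @param n,exact_threshold Passed to [sample_background()].
#' @param seed Master seed.
#' @return Named list of `background_sample`s, keyed by metapath.
#' @export
sample_backgrounds <- function(spaces, n = 10000, seed = 1L,
                               exact_threshold = 1e6) {
  out <- lapply(seq_along(spaces), function(k) {
    sample_background(spaces[[k]], n = n, seed = seed + k,
                      exact_threshold = exact_threshold)
  })
  names(out) <- vapply(spaces, `[[`, "", "metapath")
  out
}

#' @export
print.background_sample <- function(x, ...) {
  cat(sprintf(
    "# Background for %s: %d %s distances in [%.3f, %.3f]\n",
    x$metapath, x$n, if (x$exact) "exact (all-pairs)" else "sampled",
    min(x$distances), max(x$distances)
  ))
  invisible(x)
}

normalize_rows <- function(m) {
  m / sqrt(rowSums(m^2))
}

# cosine distances for index pairs over pre-normalised matrices,
# chunked so exact all-pairs enumeration stays within modest memory
chunked_row_cosine <- function(U, V, i, j, chunk = 200000L) {
  n <- length(i)
  out <- numeric(n)
  start <- 1L
  while (start <= n) {
    end <- min(start + chunk - 1L, n)
    idx <- start:end
    d <- 1 - rowSums(U[i[idx], , drop = FALSE] * V[j[idx], , drop = FALSE])
    out[idx] <- pmin(pmax(d, 0), 2)
    start <- end + 1L
  }
  out
}
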