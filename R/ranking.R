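#' Area under the ROC curve via the rank-sum statistic
#'
#' Tie-aware Mann-Whitney formulation with midranks: equals the
#' probability that a random positive scores above a random negative,
#' counting ties as one half.  Invariant under any strictly monotone
#' transform of the scores.
#'
#' @param pos,neg Numeric score vectors for the positive and negative
#'   class (higher score = more positive-like).
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(-0.1, -0.5), c(-0.3, -0.7))  # 0.75
#' @export
auroc <- function(pos, neg) {
  np <- length(pos)
  nn <- length(neg)
  if (np == 0 || nn == 0) rlang::abort("both classes must be nonempty")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Per-metapath AUROC for separating dataset edges from permuted ones
#'
#' For each applicable space, positives are the observed edges'
#' cosine distances and negatives the pooled distances of the permuted
#' networks' edges (covered pairs only); scores are negated distances,
#' so a space that places true associations closer than random
#' degree-matched pairs gets AUROC above 0.5.  Pooling all permuted
#' networks gives a large, smooth negative class.
#'
#' @param edges An `assoc_edges` tibble.
#' @param ensemble A `permutation_ensemble` (or list of edge sets).
#' @param spaces Named list of `embedding_space`s.
#' @return A tibble: `metapath`, `entity_group` (the edge type pair the
#'   space was evaluated on), `auroc_edges`, `n_pos`, `n_neg`.  Spaces
#'   where either class has zero covered pairs are omitted with a
#'   warning.
#' @export
edge_aurocs <- function(edges, ensemble, spaces) {
  app <- suppressWarnings(applicable_spaces(spaces, edges))
  by_name <- stats::setNames(spaces, vapply(spaces, `[[`, "", "metapath"))
  rows <- list()
  for (k in seq_len(nrow(app))) {
    sp <- by_name[[app$metapath[k]]]
    pos <- edge_distances_one(
      edges, sp, app$edge_src_type[k], app$edge_dst_type[k], app$orientation[k]
    )$distance
    neg <- unlist(lapply(ensemble, function(e) {
      edge_distances_one(
        e, sp, app$edge_src_type[k], app$edge_dst_type[k], app$orientation[k]
      )$distance
    }), use.names = FALSE)
    if (length(pos) == 0 || length(neg) == 0) {
      rlang::warn(sprintf(
        "metapath %s: a class has zero covered pairs; omitted from ranking",
        sp$metapath
      ))
      next
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      metapath = sp$metapath,
      entity_group = paste(app$edge_src_type[k], app$edge_dst_type[k], sep = "-"),
      auroc_edges = auroc(-pos, -neg),
      n_pos = length(pos), n_neg = length(neg)
    )
  }
  if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    metapath = character(), entity_group = character(),
    auroc_edges = double(), n_pos = integer(), n_neg = integer()
  )
}

#' Label node pairs by interaction-profile similarity
#'
#' Two nodes have a similar interacting profile when they connect to
#' largely the same partners in the input network (for genes: genes
#' interacting with the same genes).  Positives are node pairs of the
#' requested type that are not themselves an input edge and whose
#' neighbour sets have Jaccard similarity at or above the threshold;
#' negatives are a seeded random sample of non-edge, non-positive
#' pairs.
#'
#' @param edges An `assoc_edges` tibble (the input network).
#' @param node_type Entity-type code of the nodes to pair.
#' @param jaccard_threshold Minimum neighbour-set Jaccard for a
#'   positive (default 0.5).
#' @param negative_ratio Negatives sampled per positive (default 1).
#' @param seed Integer seed for the negative sample.
#' @return A tibble of class `profile_labels`: columns `u`, `v`
#'   (identifiers, u < v), `label` (`"pos"`/`"neg"`), `jaccard`;
#'   attributes `node_type` and `jaccard_threshold`.
#' @export
build_profile_labels <- function(edges, node_type, jaccard_threshold = 0.5,
                                 negative_ratio = 1, seed = 1L) {
  tbl <- tibble::as_tibble(edges)
  long <- dplyr::bind_rows(
    tibble::tibble(type = tbl$src_type, id = tbl$src_id,
                   partner = node_key(tbl$dst_type, tbl$dst_id)),
    tibble::tibble(type = tbl$dst_type, id = tbl$dst_id,
                   partner = node_key(tbl$src_type, tbl$src_id))
  )
  long <- dplyr::filter(long, .data$type == node_type)
  nbrs <- split(long$partner, long$id)
  nbrs <- lapply(nbrs, unique)
  nodes <- sort(names(nbrs))
  if (length(nodes) < 3) {
    rlang::abort(sprintf("need >= 3 nodes of type %s in the network", node_type))
  }

  hom <- tbl[tbl$src_type == node_type & tbl$dst_type == node_type, ]
  is_edge_key <- paste(pmin(hom$src_id, hom$dst_id),
                       pmax(hom$src_id, hom$dst_id), sep = "\r")

  k <- length(nodes)
  i <- rep.int(seq_len(k - 1), (k - 1):1)
  j <- sequence((k - 1):1, from = 2:k)
  u <- nodes[i]; v <- nodes[j]
  jac <- vapply(seq_along(u), function(t) {
    a <- nbrs[[u[t]]]; b <- nbrs[[v[t]]]
    length(intersect(a, b)) / length(union(a, b))
  }, 0)
  keep <- !(paste(u, v, sep = "\r") %in% is_edge_key)
  u <- u[keep]; v <- v[keep]; jac <- jac[keep]

  pos <- jac >= jaccard_threshold
  if (!any(pos)) {
    rlang::abort(sprintf(
      "zero positives at Jaccard threshold %g; try a lower threshold",
      jaccard_threshold
    ))
  }
  neg_pool <- which(!pos)
  if (length(neg_pool) == 0) {
    rlang::warn("no negative pairs available; labels contain positives only")
    neg_idx <- integer(0)
  } else {
    n_neg <- min(length(neg_pool), max(1L, round(negative_ratio * sum(pos))))
    neg_idx <- withr::with_seed(seed, {
      neg_pool[sample.int(length(neg_pool), n_neg)]
    })
  }
  out <- dplyr::bind_rows(
    tibble::tibble(u = u[pos], v = v[pos], label = "pos", jaccard = jac[pos]),
    tibble::tibble(u = u[neg_idx], v = v[neg_idx], label = "neg",
                   jaccard = jac[neg_idx])
  )
  structure(out,
            node_type = node_type,
            jaccard_threshold = jaccard_threshold,
            class = c("profile_labels", class(tibble::tibble())))
}

# distances for same-type node pairs in whichever role of the space
# matches the node type (source role preferred)
profile_pair_distances <- function(space, labels) {
  node_type <- attr(labels, "node_type")
  M <- if (space$src_type == node_type) {
    space$src
  } else if (space$dst_type == node_type) {
    space$dst
  } else {
    return(NULL)
  }
  iu <- match(labels$u, rownames(M))
  iv <- match(labels$v, rownames(M))
  keep <- !is.na(iu) & !is.na(iv)
  if (!any(keep)) return(NULL)
  N <- normalize_rows(M)
  tibble::tibble(
    label = labels$label[keep],
    distance = chunked_row_cosine(N, N, iu[keep], iv[keep])
  )
}

#' AUROC of an embedding space on the profile-similarity task
#'
#' Same estimator as [edge_aurocs()] but the classes come from
#' [build_profile_labels()]: does the space place profile-similar node
#' pairs closer than dissimilar ones?
#'
#' @param space An `embedding_space` whose source or target role covers
#'   the labelled node type.
#' @param labels A `profile_labels` tibble.
#' @return A one-row tibble `metapath`, `entity_group`,
#'   `auroc_profile`, `n_pos`, `n_neg`, or zero rows (with a warning)
#'   when a class has no covered pair.
#' @export
profile_auroc <- function(space, labels) {
  empty <- tibble::tibble(
    metapath = character(), entity_group = character(),
    auroc_profile = double(), n_pos = integer(), n_neg = integer()
  )
  d <- profile_pair_distances(space, labels)
  if (is.null(d) || length(unique(d$label)) < 2) {
    rlang::warn(sprintf(
      "metapath %s: profile task has a class with zero covered pairs",
      space$metapath
    ))
    return(empty)
  }
  pos <- d$distance[d$label == "pos"]
  neg <- d$distance[d$label == "neg"]
  tibble::tibble(
    metapath = space$metapath,
    entity_group = attr(labels, "node_type"),
    auroc_profile = auroc(-pos, -neg),
    n_pos = length(pos), n_neg = length(neg)
  )
}

#' Rank metapaths by predictive ability
#'
#' Sorts spaces by their edge-task AUROC (descending; ties broken by
#' metapath name, so the ranking is deterministic) and joins the
#' profile-task AUROCs.  Heterogeneous inputs are grouped per entity
#' pair / node type via `entity_group`.
#'
#' @param edge_tbl Output of [edge_aurocs()].
#' @param profile_tbl Optional row-bound output of [profile_auroc()]
#'   calls.
#' @param top_k How many top edge-task metapaths to flag (default 3).
#' @return A tibble of class `metapath_ranking`: `metapath`,
#'   `entity_group`, `auroc_edges`, `auroc_profile`, `n_pos`, `n_neg`,
#'   `rank`, `is_top`.
#' @export
rank_metapaths <- function(edge_tbl, profile_tbl = NULL, top_k = 3) {
  if (nrow(edge_tbl) == 0) rlang::abort("no metapaths were evaluated")
  out <- dplyr::arrange(edge_tbl, dplyr::desc(.data$auroc_edges), .data$metapath)
  if (!is.null(profile_tbl) && nrow(profile_tbl) > 0) {
    out <- dplyr::left_join(
      out,
      profile_tbl[, c("metapath", "auroc_profile")],
      by = "metapath"
    )
  } else {
    out$auroc_profile <- NA_real_
  }
  out$rank <- seq_len(nrow(out))
  out$is_top <- out$rank <= top_k
  out <- out[, c("metapath", "entity_group", "auroc_edges", "auroc_profile",
                 "n_pos", "n_neg", "rank", "is_top")]
  structure(out, class = c("metapath_ranking", class(tibble::tibble())))
}
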