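test_that("AUROC anchors: perfect separation, worked example, symmetry", {
  # distances: positives closer than negatives on every comparison
  expect_equal(auroc(-c(0.1, 0.2), -c(0.8, 0.9)), 1)
  # 3 of 4 (positive, negative) comparisons concordant
  expect_equal(auroc(-c(0.1, 0.5), -c(0.3, 0.7)), 0.75)
  expect_equal(auroc(c(1, 2), c(1, 2)), 0.5)
  expect_error(auroc(numeric(0), 1), "nonempty")
})

test_that("AUROC equals the brute-force concordance oracle, ties at one half", {
  withr::with_seed(19, {
    for (rep in 1:50) {
      np <- sample(1:50, 1)
      nn <- sample(1:50, 1)
      # coarse rounding makes cross-class ties frequent
      pos <- round(rnorm(np), 1)
      neg <- round(rnorm(nn), 1)
      expect_equal(auroc(pos, neg), brute_auroc(pos, neg))
    }
  })
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  withr::with_seed(23, {
    pos <- runif(40); neg <- runif(60)
    a <- auroc(pos, neg)
    expect_equal(auroc(exp(3 * pos), exp(3 * neg)), a)
    expect_equal(auroc(rank(c(pos, neg))[1:40],
                       rank(c(pos, neg))[41:100]), a)
  })
})

test_that("edge_aurocs separates planted edges from their permutations", {
  fx <- generate_fixture(fixture_config(
    n_spaces = 2, entities_per_type = 80, n_edges = 60, dim = 8,
    signal_fraction = 1, signal_strength = 8, noise_sd = 0.05,
    coverage_dropout = 0, seed = 12
  ))
  ens <- permutation_ensemble(fx$edges, n_perm = 4, seed = 3)
  tab <- edge_aurocs(fx$edges, ens, fx$spaces)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$auroc_edges > 0.9))
  expect_true(all(tab$n_pos > 0 & tab$n_neg > 0))
})

test_that("profile labels recover star and path neighbourhood structure", {
  star <- make_edges(c("a", "a", "a"), c("b", "c", "d"))
  expect_warning(
    lab <- build_profile_labels(star, "GEN", jaccard_threshold = 0.5, seed = 1),
    "positives only"
  )
  pos <- lab[lab$label == "pos", ]
  expect_setequal(paste(pos$u, pos$v), c("b c", "b d", "c d"))
  expect_true(all(pos$jaccard == 1))

  path <- make_edges(c("a", "b"), c("b", "c"))
  lab2 <- suppressWarnings(
    build_profile_labels(path, "GEN", jaccard_threshold = 0.9, seed = 1)
  )
  pos2 <- lab2[lab2$label == "pos", ]
  expect_equal(paste(pos2$u, pos2$v), "a c")

  expect_error(
    build_profile_labels(star, "GEN", jaccard_threshold = 1.01, seed = 1),
    "zero positives"
  )
  expect_error(build_profile_labels(make_edges("a", "b"), "GEN"), ">= 3 nodes")
})

test_that("profile AUROC rewards spaces where similar-profile nodes are collinear", {
  # plant b, c, d collinear; unrelated nodes isotropic
  ids <- c("a", "b", "c", "d", sprintf("x%d", 1:16))
  m <- withr::with_seed(4, {
    mm <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(ids, NULL))
    mm["c", ] <- mm["b", ] + rnorm(6, sd = 0.01)
    mm["d", ] <- mm["b", ] + rnorm(6, sd = 0.01)
    mm
  })
  sp <- embedding_space("GEN-ppi-GEN", vectors = m)
  star <- make_edges(c("a", "a", "a"), c("b", "c", "d"))
  lab <- suppressWarnings(
    build_profile_labels(star, "GEN", jaccard_threshold = 0.5, seed = 2)
  )
  # add sampled negatives among unrelated nodes for a two-class task
  neg <- tibble::tibble(u = sprintf("x%d", 1:8), v = sprintf("x%d", 9:16),
                        label = "neg", jaccard = 0)
  lab2 <- structure(dplyr::bind_rows(lab[lab$label == "pos", ], neg),
                    node_type = "GEN", jaccard_threshold = 0.5,
                    class = class(lab))
  res <- profile_auroc(sp, lab2)
  expect_gt(res$auroc_profile, 0.9)

  # a single positive closer than all negatives scores exactly 1
  one <- structure(dplyr::bind_rows(lab2[1, ], neg),
                   node_type = "GEN", jaccard_threshold = 0.5,
                   class = class(lab))
  expect_equal(profile_auroc(sp, one)$auroc_profile, 1)
})

test_that("rank_metapaths sorts by edge AUROC with deterministic tie-breaks", {
  tbl <- tibble::tibble(
    metapath = c("GEN-b-GEN", "GEN-a-GEN", "GEN-c-GEN"),
    entity_group = "GEN-GEN",
    auroc_edges = c(0.8, 0.8, 0.9),
    n_pos = 10L, n_neg = 20L
  )
  r <- rank_metapaths(tbl, top_k = 1)
  expect_equal(r$metapath, c("GEN-c-GEN", "GEN-a-GEN", "GEN-b-GEN"))
  expect_equal(r$is_top, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(r$auroc_profile)))
  expect_error(rank_metapaths(tbl[0, ]), "no metapaths")
})
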