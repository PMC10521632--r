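test_that("cosine distance hits the parallel/orthogonal/antiparallel anchors", {
  expect_equal(cosine_distance(c(1, 0), c(2, 0)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 0), c(-1, 0)), 2)
  expect_equal(cosine_distance(c(1, 2), c(2, 1)), cosine_distance(c(2, 1), c(1, 2)))
  expect_error(cosine_distance(c(0, 0), c(1, 0)), "zero-norm")
  expect_error(cosine_distance(c(1, 0, 0), c(1, 0)), "dimension")
})

test_that("quantile rank counts background distances <= d, ties included", {
  bg <- structure(list(distances = c(0.1, 0.2, 0.3, 0.4), n = 4L),
                  class = "background_sample")
  expect_equal(quantile_rank(bg, 0.05), 0)
  expect_equal(quantile_rank(bg, 0.25), 0.5)
  expect_equal(quantile_rank(bg, 0.4), 1)   # tie with the maximum counts
  expect_equal(quantile_rank(bg, c(0.1, 0.15)), c(0.25, 0.25))
})

test_that("quantile rank equals the brute-force count oracle and is monotone", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      d_bg <- sort(round(runif(sample(100:400, 1), 0, 2),
                         sample(1:3, 1)))  # rounding forces ties
      bg <- structure(list(distances = d_bg, n = length(d_bg)),
                      class = "background_sample")
      q <- c(runif(50, -0.1, 2.1), sample(d_bg, 10))
      expect_identical(quantile_rank(bg, q), brute_quantile_rank(d_bg, q))
      qs <- quantile_rank(bg, sort(q))
      expect_false(is.unsorted(qs))
    }
  })
})

test_that("score_dataset matches an all-pairs brute-force oracle", {
  sp <- make_space(k = 8, dim = 5, seed = 21)
  bg <- sample_background(sp, seed = 1)
  edges <- make_edges(c("G001", "G002"), c("G005", "G007"))
  tab <- score_dataset(edges, list(sp), list("GEN-ppi-GEN" = bg))
  expect_s3_class(tab, "support_tbl")
  expect_equal(nrow(tab), 2)
  for (i in seq_len(nrow(tab))) {
    d_ref <- brute_cosine(sp$src[tab$src_id[i], ], sp$src[tab$dst_id[i], ])
    expect_equal(tab$distance[i], d_ref, tolerance = 1e-12)
    expect_equal(tab$quantile_rank[i],
                 sum(bg$distances <= tab$distance[i]) / bg$n)
  }
  # the closest pair of the whole space gets the minimal rank 1/bg.n
  all_pairs <- utils::combn(rownames(sp$src), 2)
  d_all <- apply(all_pairs, 2, function(p) brute_cosine(sp$src[p[1], ], sp$src[p[2], ]))
  best <- all_pairs[, which.min(d_all)]
  e_best <- make_edges(best[1], best[2])
  tb <- score_dataset(e_best, list(sp), list("GEN-ppi-GEN" = bg))
  expect_equal(tb$quantile_rank, 1 / bg$n)
})

test_that("uncovered endpoints yield missing entries and reduced coverage", {
  sp <- make_space(k = 5, seed = 2)
  bg <- sample_background(sp, seed = 1)
  edges <- make_edges(c("G001", "G001"), c("G002", "MISSING"))
  tab <- score_dataset(edges, list(sp), list("GEN-ppi-GEN" = bg))
  expect_equal(nrow(tab), 1)
  cov <- support_coverage(tab)
  expect_equal(cov$coverage, 0.5)
  # identical endpoint vectors score distance 0 -> rank = share of bg <= 0
  sp2 <- sp
  sp2$src["G002", ] <- sp2$src["G001", ]
  sp2$dst <- sp2$src
  bg2 <- sample_background(sp2, seed = 1)
  tb2 <- score_dataset(make_edges("G001", "G002"), list(sp2),
                       list("GEN-ppi-GEN" = bg2))
  expect_equal(tb2$quantile_rank, sum(bg2$distances <= 0) / bg2$n)
})

test_that("scoring a homogeneous edge is invariant to endpoint order", {
  sp <- make_space(k = 10, seed = 4)
  bg <- sample_background(sp, seed = 1)
  t1 <- score_dataset(make_edges("G003", "G008"), list(sp),
                      list("GEN-ppi-GEN" = bg))
  t2 <- score_dataset(make_edges("G008", "G003"), list(sp),
                      list("GEN-ppi-GEN" = bg))
  expect_equal(tibble::as_tibble(t1), tibble::as_tibble(t2))
})

test_that("heterogeneous spaces score through the right roles in both orientations", {
  hs <- make_hetero_space(ks = 6, kd = 7, seed = 8)
  bg <- sample_background(hs, seed = 1)
  fwd <- score_dataset(make_edges("C002", "G003", "CPD", "GEN"),
                       list(hs), list("CPD-int-GEN" = bg))
  rev <- score_dataset(make_edges("G003", "C002", "GEN", "CPD"),
                       list(hs), list("CPD-int-GEN" = bg))
  d_ref <- brute_cosine(hs$src["C002", ], hs$dst["G003", ])
  expect_equal(fwd$distance, d_ref, tolerance = 1e-12)
  expect_equal(rev$distance, d_ref, tolerance = 1e-12)
})

test_that("summarize_support applies the minimum rule and counts accumulation", {
  sp1 <- make_space(k = 6, seed = 1, metapath = "GEN-ppi-GEN")
  bg_fake <- function(qrs, metapath) {
    # craft a support table directly to pin aggregation arithmetic
    tibble::tibble(
      src_id = "G001", src_type = "GEN", dst_id = "G002", dst_type = "GEN",
      metapath = metapath, distance = 0.5, quantile_rank = qrs
    )
  }
  tab <- dplyr::bind_rows(bg_fake(0.3, "GEN-m1-GEN"), bg_fake(0.02, "GEN-m2-GEN"))
  tab <- structure(tab, edges = tibble::tibble(src_id = "G001", dst_id = "G002"),
                   class = c("support_tbl", class(tibble::tibble())))
  s <- summarize_support(tab, cutoffs = c(0.01, 0.05))
  expect_equal(s$edge_support$min_qr, 0.02)
  expect_equal(s$supported_fraction$fraction, c(0, 1))

  tab3 <- dplyr::bind_rows(bg_fake(0.01, "GEN-m1-GEN"),
                           bg_fake(0.04, "GEN-m2-GEN"),
                           bg_fake(0.20, "GEN-m3-GEN"))
  tab3 <- structure(tab3, edges = tibble::tibble(src_id = "G001", dst_id = "G002"),
                    class = c("support_tbl", class(tibble::tibble())))
  s3 <- summarize_support(tab3, cutoffs = c(0.05, 0.25))
  expect_equal(s3$edge_support$n_le_0.05, 2)
  expect_equal(s3$edge_support$n_le_0.25, 3)
  expect_lte(max(s3$edge_support$n_le_0.25), s3$edge_support$n_metapaths)

  expect_error(summarize_support(tab3, cutoffs = c(0.5, 0.1)), "ascending")
  empty <- structure(tab3[0, ], edges = tibble::tibble(),
                     class = c("support_tbl", class(tibble::tibble())))
  expect_error(summarize_support(empty), "nothing to summarize")
})

test_that("supported fraction is monotone in the cutoff and 1 at cutoff 1", {
  fx <- generate_fixture(fixture_config(
    n_spaces = 2, entities_per_type = 60, n_edges = 40, dim = 8,
    signal_fraction = 0.3, seed = 5
  ))
  bgs <- sample_backgrounds(fx$spaces, seed = 1)
  tab <- score_dataset(fx$edges, fx$spaces, bgs)
  s <- summarize_support(tab, cutoffs = c(0.01, 0.05, 0.2, 1))
  expect_false(is.unsorted(s$supported_fraction$fraction))
  expect_equal(s$supported_fraction$fraction[4], 1)
  expect_true(all(s$per_metapath$fraction >= 0 & s$per_metapath$fraction <= 1))
  # coverage consistency: per-metapath counts over the input edge count
  cov <- support_coverage(tab)
  expect_equal(cov$coverage, cov$n_covered / nrow(fx$edges))
})

test_that("quantile ranks of random edges are approximately uniform", {
  sp <- make_space(k = 100, dim = 8, seed = 31)
  bg <- sample_background(sp, seed = 1)
  stopifnot(bg$exact)
  ids <- rownames(sp$src)
  pairs <- withr::with_seed(77, {
    t(replicate(2000, sample(ids, 2)))
  })
  edges <- make_edges(pairs[, 1], pairs[, 2])
  tab <- score_dataset(edges, list(sp), list("GEN-ppi-GEN" = bg))
  expect_lt(abs(mean(tab$quantile_rank) - 0.5), 0.02)
})

test_that("tidy and glance expose the summary surfaces", {
  fx <- generate_fixture(fixture_config(
    n_spaces = 2, entities_per_type = 50, n_edges = 30, dim = 6, seed = 9
  ))
  bgs <- sample_backgrounds(fx$spaces, seed = 1)
  s <- summarize_support(score_dataset(fx$edges, fx$spaces, bgs))
  td <- generics::tidy(s)
  expect_true(all(c("metapath", "cutoff", "fraction", "coverage") %in% names(td)))
  g <- generics::glance(s)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_edges, 30)
})
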