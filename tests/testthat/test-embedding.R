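test_that("single- and dual-vocabulary spaces build with types parsed from the name", {
  sp <- make_space(k = 5, dim = 8)
  expect_equal(sp$src_type, "GEN")
  expect_equal(sp$dst_type, "GEN")
  expect_equal(sp$dim, 8)
  expect_true(sp$single_vocab)
  expect_identical(sp$src, sp$dst)

  hs <- make_hetero_space(ks = 3, kd = 4, dim = 8)
  expect_equal(hs$src_type, "CPD")
  expect_equal(hs$dst_type, "GEN")
  expect_false(hs$single_vocab)
  expect_equal(nrow(hs$src), 3)
  expect_equal(nrow(hs$dst), 4)

  # multi-hop names use first and last tokens
  long <- embedding_space("CPD-trt-DIS-ass-GEN",
                          src_vectors = hs$src, dst_vectors = hs$dst)
  expect_equal(c(long$src_type, long$dst_type), c("CPD", "GEN"))
})

test_that("zero-norm rows are dropped with a warning; bad names rejected", {
  m <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("G", 1:5), NULL))
  m[3, ] <- 0
  expect_warning(sp <- embedding_space("GEN-ppi-GEN", vectors = m),
                 "zero-norm")
  expect_equal(nrow(sp$src), 4)
  expect_false("G3" %in% rownames(sp$src))

  expect_error(embedding_space("FOO-ppi-GEN", vectors = m[1:2, ]),
               "not valid entity types")
  expect_error(embedding_space("GENppiGEN", vectors = m[1:2, ]), "malformed")
})

test_that("spaces round-trip through the on-disk layout; dim mismatch is a load error", {
  d <- withr::local_tempdir()
  sp <- make_space(k = 5, dim = 6, seed = 3)
  write_space(sp, file.path(d, "s1"))
  sp2 <- load_space(file.path(d, "s1"))
  expect_equal(sp2$metapath, sp$metapath)
  expect_equal(sp2$src, sp$src)

  hs <- make_hetero_space()
  write_space(hs, file.path(d, "s2"))
  hs2 <- load_space(file.path(d, "s2"))
  expect_equal(hs2$src, hs$src)
  expect_equal(hs2$dst, hs$dst)

  meta <- yaml::read_yaml(file.path(d, "s1", "meta.yaml"))
  meta$dim <- 99
  yaml::write_yaml(meta, file.path(d, "s1", "meta.yaml"))
  expect_error(load_space(file.path(d, "s1")), "declared dim")
})

test_that("load_spaces indexes every space subdirectory by metapath", {
  d <- withr::local_tempdir()
  write_space(make_space(metapath = "GEN-ppi-GEN"), file.path(d, "a"))
  write_space(make_hetero_space(), file.path(d, "b"))
  sps <- load_spaces(d)
  expect_setequal(names(sps), c("GEN-ppi-GEN", "CPD-int-GEN"))
  expect_error(load_spaces(withr::local_tempdir()), "no embedding spaces")
})

test_that("applicable_spaces matches type pairs in either orientation", {
  spaces <- list(make_space(metapath = "GEN-ppi-GEN"),
                 make_hetero_space(metapath = "CPD-int-GEN"))
  gg <- make_edges(c("G001", "G002"), c("G002", "G003"))
  app <- applicable_spaces(spaces, gg)
  expect_equal(app$metapath, "GEN-ppi-GEN")
  expect_equal(app$orientation, "forward")

  # GEN->CPD edges match the CPD-int-GEN space reversed
  gc <- make_edges("G001", "C001", src_type = "GEN", dst_type = "CPD")
  app2 <- applicable_spaces(spaces, gc)
  expect_equal(app2$metapath, "CPD-int-GEN")
  expect_equal(app2$orientation, "reverse")

  dd <- make_edges(c("D1", "D2"), c("D2", "D3"), src_type = "DIS")
  expect_warning(app3 <- applicable_spaces(spaces, dd), "0 applicable")
  expect_equal(nrow(app3), 0)
})

test_that("exact background enumerates all distinct cross-role pairs", {
  sp <- make_space(k = 4, dim = 3, seed = 9)
  bg <- sample_background(sp, n = 100, seed = 1)
  expect_true(bg$exact)
  expect_equal(bg$n, choose(4, 2))
  expect_false(is.unsorted(bg$distances))
  expect_true(all(bg$distances >= 0 & bg$distances <= 2))
  # matches brute force over all unordered pairs
  N <- sp$src
  ref <- sort(apply(utils::combn(4, 2), 2,
                    function(ij) brute_cosine(N[ij[1], ], N[ij[2], ])))
  expect_equal(bg$distances, ref)

  hs <- make_hetero_space(ks = 3, kd = 4)
  expect_equal(sample_background(hs, seed = 1)$n, 12)
})

test_that("exact-mode background of k-entity spaces has k(k-1)/2 entries", {
  for (k in c(5, 9, 17)) {
    bg <- sample_background(make_space(k = k, seed = k), seed = 1)
    expect_equal(bg$n, k * (k - 1) / 2)
  }
})

test_that("sampled backgrounds are deterministic per seed and converge to exact", {
  sp <- make_space(k = 100, dim = 6, seed = 5)
  exact <- sample_background(sp, seed = 1)
  s1 <- sample_background(sp, n = 10000, seed = 2, exact_threshold = 10)
  s2 <- sample_background(sp, n = 10000, seed = 2, exact_threshold = 10)
  s3 <- sample_background(sp, n = 10000, seed = 3, exact_threshold = 10)
  expect_identical(s1$distances, s2$distances)
  expect_false(identical(s1$distances, s3$distances))
  expect_false(s1$exact)
  expect_true(exact$exact)
  # two-sample KS distance between sampled and exact CDFs
  grid <- exact$distances
  ks <- max(abs(findInterval(grid, s1$distances) / s1$n -
                  seq_along(grid) / exact$n))
  expect_lt(ks, 0.05)
})

test_that("degenerate and orthogonal spaces behave as documented", {
  m <- diag(4)
  rownames(m) <- paste0("G", 1:4)
  sp <- embedding_space("GEN-ppi-GEN", vectors = m)
  bg <- sample_background(sp, seed = 1)
  expect_true(all(bg$distances == 1))

  one <- embedding_space("GEN-ppi-GEN",
                         vectors = matrix(1, 1, 2, dimnames = list("G1", NULL)))
  expect_error(sample_background(one, seed = 1), "too small")
  expect_error(sample_background(sp, n = 10, seed = 1), ">= 100")
})
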