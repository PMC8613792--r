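test_that("reference set has the right rows and spans every attribute", {
  m <- toy_scores()
  cfg <- rapbeef_config(n_anchor_pairs = 2L)
  aug <- build_reference_set(m, cfg)
  expect_identical(nrow(aug), 3L + 2L + 2L * 2L)
  expect_identical(unname(aug["GOOD", ]), rep(6, 4))
  expect_identical(unname(aug["BAD", ]), rep(1, 4))
  expect_true(all(aug["GOOD", ] != aug["BAD", ]))
  # anchors are complementary within each pair
  expect_identical(unname(aug["ANCHOR1a", ] + aug["ANCHOR1b", ]), rep(7, 4))
  # no anchors when switched off
  aug0 <- build_reference_set(m, rapbeef_config(n_anchor_pairs = 0L))
  expect_identical(nrow(aug0), 5L)
  expect_error(build_reference_set(m[, 1, drop = FALSE]), "2 attributes")
})

test_that("score normalization maps the 1-6 scale to 0-100", {
  expect_equal(normalize_scores(matrix(c(1, 6, 3.5, 2.4), 1)),
               matrix(c(0, 100, 50, 28), 1))
  expect_error(normalize_scores(matrix(0.5)), "\\[1, 6\\]")
})

test_that("metric MDS recovers exactly embeddable configurations", {
  cfg <- rapbeef_config()
  # 3 points realisable in the plane
  pts3 <- rbind(c(0, 0), c(3, 0), c(0, 4))
  d3 <- as.matrix(dist(pts3))
  fit3 <- mds_ordinate(d3, cfg)
  expect_lt(fit3$stress1, 1e-6)
  expect_lt(fit3$sstress, 1e-6)
  expect_equal(as.matrix(dist(fit3$coords)), d3, tolerance = 1e-6,
               ignore_attr = TRUE)
  # 4 points: configuration matches the classical-scaling oracle
  pts4 <- rbind(c(0, 0), c(2, 1), c(-1, 3), c(4, -2))
  d4 <- as.matrix(dist(pts4))
  fit4 <- mds_ordinate(d4, cfg)
  oracle <- stats::cmdscale(d4, k = 2)
  expect_lt(procrustes_rms(fit4$coords, oracle), 1e-4)
  expect_lt(fit4$stress1, 1e-6)
  # 2 points at separation d
  d2 <- matrix(c(0, 5, 5, 0), 2)
  fit2 <- mds_ordinate(d2, cfg)
  expect_equal(dist(fit2$coords)[1], 5, tolerance = 1e-8)
  expect_lt(fit2$stress1, 1e-9)
})

test_that("MDS validates its input and tracks convergence", {
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(mds_ordinate(bad), "symmetric")
  expect_error(mds_ordinate(matrix(c(0, -1, -1, 0), 2)), "non-negative")
  slow <- rapbeef_config(max_iter = 1L, tolerance = 1e-16)
  set.seed(3)
  d <- as.matrix(dist(matrix(rnorm(40), 10, 4)))  # not embeddable in 2-D
  fit <- mds_ordinate(d, slow)
  expect_false(fit$converged)     # flagged, not an error
})

test_that("raw stress is non-increasing within the winning restart", {
  syn <- generate_synthetic(8, 5, seed = 11)
  fit <- rapbeef(syn$scores, config = fast_config())
  expect_true(all(diff(fit$trace) <= 1e-9))
})

test_that("axis alignment is a rigid motion placing GOOD right of BAD", {
  co <- rbind(GOOD = c(0, 1), BAD = c(0, -1), e1 = c(0.5, 0.2))
  al <- align_axes(co)
  expect_equal(unname(al["GOOD", ]), c(1, 0), tolerance = 1e-12)
  expect_equal(unname(al["BAD", ]), c(-1, 0), tolerance = 1e-12)
  expect_equal(as.matrix(dist(al)), as.matrix(dist(co)), tolerance = 1e-12)
  # already aligned input is unchanged
  expect_equal(align_axes(al), al, tolerance = 1e-12)
  # mirrored input is reflected so GOOD ends up right
  mi <- rbind(GOOD = c(-2, 0), BAD = c(2, 0), e1 = c(1, 1))
  alm <- align_axes(mi)
  expect_gt(alm["GOOD", 1], alm["BAD", 1])
  expect_error(align_axes(rbind(GOOD = c(1, 1), BAD = c(1, 1))), "degenerate")
})

test_that("index projection anchors GOOD at 100 and BAD at 0", {
  co <- rbind(GOOD = c(10, 0), BAD = c(-10, 0),
              at_good = c(10, 0), at_bad = c(-10, 0), mid = c(0, 3))
  idx <- sustainability_index(co)
  expect_equal(unname(idx[c("at_good", "at_bad", "mid")]), c(100, 0, 50))
})

test_that("collinear profiles ordinate to the analytic index", {
  # constant rows: all information lies on the bad-good diagonal
  s <- c(1, 2, 3.5, 5, 6)
  m <- matrix(s, 5, 4, dimnames = list(paste0("e", 1:5), paste0("A", 1:4)))
  fit <- rapbeef(m, config = rapbeef_config(n_anchor_pairs = 0L))
  expect_equal(unname(fit$index), (s - 1) / 5 * 100, tolerance = 1e-6)
  expect_lt(fit$stress1, 1e-7)
})

test_that("ordination pipeline anchors, bands and reproduces degeneracy", {
  m <- toy_scores()
  for (seed in c(1L, 77L, 20210923L)) {
    fit <- rapbeef(m, config = rapbeef_config(seed = seed))
    expect_equal(unname(fit$index_all["GOOD"]), 100)
    expect_equal(unname(fit$index_all["BAD"]), 0)
  }
  # every entity at GOOD: all indices 100; without anchors only two
  # distinct profiles remain, so the embedding is exact
  allgood <- matrix(6, 3, 4, dimnames = list(paste0("e", 1:3), paste0("A", 1:4)))
  expect_equal(unname(rapbeef(allgood)$index), rep(100, 3), tolerance = 1e-6)
  fitg <- rapbeef(allgood, config = rapbeef_config(n_anchor_pairs = 0L))
  expect_equal(unname(fitg$index), rep(100, 3), tolerance = 1e-6)
  expect_lt(fitg$stress1, 1e-6)
})

test_that("published farm ordering holds for the environmental dimension", {
  fix <- region_fixture()
  fit <- rapbeef(fix$farm_scores, "environmental")
  expect_gt(fit$index["Semarang"], fit$index["Sragen"])
  expect_gt(fit$index["Semarang"], fit$index["Boyolali"])
  expect_lt(fit$S, 0.25)
})

test_that("dimension filtering uses attached definitions and validates", {
  fix <- region_fixture()
  eco <- rapbeef(fix$farm_scores, "economic")
  expect_identical(sort(colnames(eco$scores)), c("PE1", "PE2", "PE3", "PE4"))
  expect_error(rapbeef(toy_scores(), "economic"), "attributes")
})

test_that("index recovers the latent ordering of synthetic data", {
  syn <- generate_synthetic(50, 9, sd = 0.5, seed = 123)
  fit <- rapbeef(syn$scores, config = fast_config())
  rho <- cor(syn$latent, fit$index, method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("single-attribute improvement never meaningfully lowers the index", {
  syn <- generate_synthetic(10, 6, sd = 0.4, seed = 5)
  cfg <- fast_config()
  base <- rapbeef(syn$scores, config = cfg)
  set.seed(42)
  worsened <- 0L
  for (k in 1:100) {
    m <- syn$scores
    repeat {
      i <- sample(nrow(m), 1)
      j <- sample(ncol(m), 1)
      if (m[i, j] < 6L) break
    }
    m[i, j] <- m[i, j] + 1L
    pert <- rapbeef(m, config = cfg)
    if (pert$index[i] < base$index[i] - 1.0) worsened <- worsened + 1L
  }
  expect_identical(worsened, 0L)
})

test_that("identical inputs and seed give bit-identical results", {
  fix <- region_fixture()
  a <- rapbeef(fix$farm_scores, "multi")
  b <- rapbeef(fix$farm_scores, "multi")
  expect_identical(a$coordinates, b$coordinates)
  expect_identical(a$index, b$index)
  expect_identical(a$S, b$S)
})

test_that("fit methods expose indices, residuals and summaries", {
  fit <- rapbeef(toy_scores())
  expect_identical(coef(fit), fit$index)
  res <- residuals(fit)
  expect_length(res, choose(nrow(fit$coordinates), 2))
  expect_equal(fit$stress1,
               sqrt(sum(res^2) / sum(fit$distances[lower.tri(fit$distances)]^2)),
               tolerance = 1e-10)
  s <- summary(fit)
  expect_s3_class(s, "summary.rapbeef")
  expect_output(print(fit), "Anchored MDS")
  expect_output(print(s), "goodness of fit")
})
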