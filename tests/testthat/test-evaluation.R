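test_that("nmi endpoints, hand example, and symmetry", {
  expect_equal(nmi(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1.0)
  expect_equal(nmi(c(1, 1, 2, 2, 3, 3), rep(1, 6)), 0.0)
  # hand-computed 2x2 contingency example
  truth <- c(0, 0, 1, 1); pred <- c(0, 1, 1, 1)
  expect_equal(nmi(truth, pred), oracle_nmi(truth, pred), tolerance = 1e-9)
  # frozen value from the entropy formulas:
  # MI = 0.25 ln2 + 0.25 ln(2/3) + 0.5 ln(4/3) = 0.2157616,
  # normalizer (ln2 + 0.5623351)/2 = 0.6277411, ratio = 0.3437110
  expect_equal(nmi(truth, pred), 0.3437110, tolerance = 1e-6)
  expect_equal(nmi(truth, pred), nmi(pred, truth), tolerance = 1e-12)
  expect_error(nmi(1:3, 1:4), "length")
})

test_that("ari endpoints, pair-counting oracle, and invariances", {
  expect_equal(ari(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1.0)
  truth <- c(0, 0, 1, 1); pred <- c(0, 1, 0, 1)
  expect_equal(ari(truth, pred), oracle_ari(truth, pred), tolerance = 1e-12)
  expect_equal(ari(truth, pred), -0.5, tolerance = 1e-12) # frozen oracle value
  set.seed(3)
  a <- sample(3, 40, replace = TRUE); b <- sample(4, 40, replace = TRUE)
  expect_equal(ari(a, b), oracle_ari(a, b), tolerance = 1e-12)
  # renaming predicted clusters never changes ARI or NMI
  relab <- c(9, 7, 5, 3)[b]
  expect_equal(ari(a, relab), ari(a, b), tolerance = 1e-12)
  expect_equal(nmi(a, relab), nmi(a, b), tolerance = 1e-12)
  expect_equal(ari(a, b), ari(b, a), tolerance = 1e-12)
})

test_that("random independent labelings score ARI about 0", {
  set.seed(42)
  vals <- replicate(100, {
    a <- sample(5, 1000, replace = TRUE)
    b <- sample(5, 1000, replace = TRUE)
    ari(a, b)
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("silhouette_scaled matches a hand distance-table oracle", {
  # 4 points in 1-D at (0, 0.1, 10, 10.1), labels (A, A, B, B):
  # a = 0.1 everywhere; b = (10+10.1)/2 or (9.9+10)/2; s ~= 1 - 0.1/9.95
  Z <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c("A", "A", "B", "B")
  hand <- mean(c((10.05 - 0.1) / 10.05, (9.95 - 0.1) / 9.95,
                 (9.95 - 0.1) / 9.95, (10.05 - 0.1) / 10.05))
  expect_equal(silhouette_scaled(Z, lab), (hand + 1) / 2, tolerance = 1e-9)
  expect_equal(silhouette_scaled(Z, lab),
               (oracle_silhouette(Z, lab) + 1) / 2, tolerance = 1e-9)
  # far-separated tight clusters approach 1
  set.seed(1)
  Z2 <- rbind(matrix(rnorm(60, 0, 0.01), 30, 2),
              matrix(rnorm(60, 1000, 0.01), 30, 2))
  expect_gt(silhouette_scaled(Z2, rep(1:2, each = 30)), 0.99)
  expect_error(silhouette_scaled(Z2, rep(1, 60)), "single")
  # affine endpoints of the rescale map
  expect_equal((c(-1, 0, 1) + 1) / 2, c(0, 0.5, 1))
})

test_that("deviation_ratio follows its definition and sign semantics", {
  expect_equal(deviation_ratio(10, 10), 0.0)
  expect_equal(deviation_ratio(12, 10), 0.2)
  expect_equal(deviation_ratio(5, 10), -0.5)
  expect_error(deviation_ratio(3, 0), "k_true")
  # asymmetric by design
  expect_false(isTRUE(all.equal(deviation_ratio(4, 8), deviation_ratio(8, 4))))
})

test_that("metric_report aggregates coherently and round-trips labels", {
  set.seed(6)
  sim <- simulate_latent_mixture(90, 2, 3, mean_separation = 12, seed = 2)
  pred <- sim$labels
  rep_ <- metric_report(sim$labels, pred, latent = sim$Z)
  expect_equal(rep_$nmi, 1); expect_equal(rep_$ari, 1)
  expect_equal(rep_$mean_score, mean(c(rep_$nmi, rep_$ari, rep_$sc_scaled)),
               tolerance = 1e-12)
  expect_equal(rep_$deviation_ratio, 0)
  # single predicted cluster: silhouette reported as NA, not an error
  rep2 <- metric_report(sim$labels, rep(1, 90), latent = sim$Z)
  expect_true(is.na(rep2$sc_scaled))
  # label CSV round trip
  dir <- withr::local_tempdir()
  p <- file.path(dir, "labels.csv")
  write_labels(pred, paste0("c", 1:90), p)
  back <- read_labels(p)
  expect_equal(back$label, pred)
  expect_equal(back$cell_id, paste0("c", 1:90))
})
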