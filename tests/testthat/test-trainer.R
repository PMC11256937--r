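make_tiny_data <- function(n = 120, g = 40, K = 3, seed = 5) {
  rec <- simulation_recipe(n_cells = n, n_genes = g, K = K,
                           de_fraction = 0.2, fold_change = 8, seed = seed)
  sim <- simulate_counts(rec)
  list(sim = sim, data = preprocess_counts(sim$counts, n_hvg = g))
}

test_that("pretrain_ae descends, is seeded, and traces per epoch", {
  td <- make_tiny_data()
  cfg <- dac_config(pretrain_epochs = 15, batch_size = 64, seed = 1)
  p1 <- pretrain_ae(td$data, cfg)
  p2 <- pretrain_ae(td$data, cfg)
  expect_identical(p1$trace, p2$trace)            # same seed, same run
  expect_identical(p1$encoder, p2$encoder)
  expect_lt(tail(p1$trace$recon, 1), p1$trace$recon[1])
  expect_identical(p1$trace$epoch, seq_len(nrow(p1$trace)))
})

test_that("pretraining approaches the oracle NLL on rank-1 Poisson data", {
  set.seed(3)
  n <- 60; g <- 30
  row_f <- exp(rnorm(n, 0, 0.4)); col_f <- exp(rnorm(g, 0.5, 0.6))
  rates <- outer(row_f, col_f)
  Xr <- matrix(rpois(n * g, rates), n, g)
  cm <- count_matrix(Xr)
  data <- preprocess_counts(cm, n_hvg = g)
  # oracle: exact NLL at the generating rates (order genes as selected)
  oracle <- mean(sapply(seq_len(n), function(i)
    poisson_nll(data$raw_hvg[i, ], rates[i, data$processed$hvg_indices])))
  cfg <- dac_config(pretrain_epochs = 400, batch_size = 64, lr = 1e-3,
                    hidden = c(32, 16), latent_dim = 4, seed = 2)
  p <- pretrain_ae(data, cfg)
  final <- tail(p$trace$recon, 1)
  expect_lt(final, oracle * 1.05)   # within 5% of the generating-rate NLL
})

test_that("lambda = 0 training steps equal autoencoder-only steps", {
  td <- make_tiny_data()
  Xs <- td$data$processed$values; Xr <- td$data$raw_hvg
  lg <- rowSums(lgamma(Xr + 1))
  enc <- mlp_init(c(ncol(Xs), 16, 4), seed = 1)
  dec <- mlp_init(c(4, 16, ncol(Xs)), seed = 2)
  oe <- celldpm:::adamw_init(enc); od <- celldpm:::adamw_init(dec)
  st <- fit_S(matrix(rnorm(240), 120, 2), K_max = 4, seed = 1,
              merge_moves = FALSE)
  # a state is present but lambda = 0: must reproduce the AE-only update
  s_cpl <- celldpm:::train_step(enc, dec, oe, od, Xs, Xr, lg,
                                state = NULL, lambda = 0, lr = 1e-3)
  s_ae <- celldpm:::train_step(enc, dec, oe, od, Xs, Xr, lg, lr = 1e-3)
  expect_identical(s_cpl$enc, s_ae$enc)
  expect_identical(s_cpl$dec, s_ae$dec)
  expect_identical(s_cpl$recon, s_ae$recon)
})

test_that("train returns a coherent model and is reproducible end-to-end", {
  td <- make_tiny_data()
  cfg <- dac_config(pretrain_epochs = 30, epochs = 10, batch_size = 64,
                    K_max = 8, s_update_every = 2, seed = 7)
  f1 <- dac_fit(td$sim$counts, cfg)
  f2 <- dac_fit(td$sim$counts, cfg)
  expect_identical(f1$result$labels, f2$result$labels)
  expect_length(f1$result$labels, 120)
  expect_false(anyNA(f1$result$labels))
  expect_s3_class(f1$state, "dpmm_state")
  expect_true(all(c("pretrain", "train") %in% f1$trace$phase))
  # combined-loss trend: late epochs not worse than the first epoch
  trt <- subset(f1$trace, phase == "train")
  expect_lte(tail(trt$combined, 1), trt$combined[1] + 1e-8)
})

test_that("infer_labels is deterministic, total, and shape-checked", {
  td <- make_tiny_data()
  cfg <- dac_config(pretrain_epochs = 20, epochs = 5, batch_size = 64,
                    K_max = 8, seed = 3)
  fit <- dac_fit(td$sim$counts, cfg)
  r1 <- infer_labels(td$data, fit$encoder, fit$state)
  r2 <- infer_labels(td$data, fit$encoder, fit$state)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$k_eff, length(unique(r1$labels)))
  # a cell whose latent sits exactly at an occupied component mean is
  # assigned that component
  occ <- unique(fit$state$hard_labels)[1]
  r <- responsibilities(fit$state$mu[occ, ], fit$state)
  expect_identical(which.max(r), as.integer(occ))
  # latent-dimension mismatch is caught
  bad_state <- fit$state; bad_state$D <- 5L
  expect_error(infer_labels(td$data, fit$encoder, bad_state), "mismatch")
})

test_that("checkpoints round-trip the model and support transform", {
  td <- make_tiny_data()
  cfg <- dac_config(pretrain_epochs = 10, epochs = 3, batch_size = 64,
                    K_max = 6, seed = 2)
  fit <- dac_fit(td$sim$counts, cfg)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "model.json")
  save_checkpoint(fit, p)
  back <- load_checkpoint(p)
  Z1 <- encode_counts(fit, td$sim$counts)
  Z2 <- encode_counts(back, td$sim$counts)
  expect_equal(Z1, Z2, tolerance = 1e-12)
  r <- infer_labels(td$data$processed$values, back$encoder, back$state)
  expect_identical(r$labels, fit$result$labels)
})

test_that("the CLI wires simulate/fit/evaluate together", {
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "sim.mtx")
  run_cli(c("simulate", "--n-cells", "100", "--n-genes", "40", "--k", "2",
            "--seed", "5", "--out", mtx))
  expect_true(file.exists(mtx))
  expect_true(file.exists(file.path(dir, "truth_labels.csv")))
  labs <- file.path(dir, "labels.csv")
  suppressMessages(run_cli(c(
    "fit", "--input", mtx, "--format", "mtx", "--n-hvg", "40",
    "--epochs", "3", "--pretrain-epochs", "5", "--kmax", "6",
    "--batch-size", "64", "--seed", "1", "--out-labels", labs)))
  expect_true(file.exists(labs))
  out <- file.path(dir, "metrics.json")
  suppressMessages(run_cli(c(
    "evaluate", "--truth", file.path(dir, "truth_labels.csv"),
    "--pred", labs, "--out", out)))
  rep_ <- jsonlite::read_json(out)
  expect_true(all(c("nmi", "ari", "deviation_ratio") %in% names(rep_)))
})
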