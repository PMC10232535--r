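# The synthetic-data generator: shapes, reproducibility, the latent
# SPR, the domain-shift perturbation, and end-to-end recovery.

test_that("default configuration reproduces the study-scale dataset shapes", {
  cfg <- synthetic_config(seed = 4)
  lib <- generate_descriptor_library(cfg)
  expect_equal(dim(lib$tables$indole), c(11L, 35L))
  expect_equal(dim(lib$tables$alkene), c(14L, 6L))
  expect_equal(dim(lib$tables$cca), c(25L, 66L))
  expect_equal(nrow(lib$candidates), 360L)

  src <- generate_source_domain(cfg, lib)
  expect_equal(nrow(src$records), 59L)
  expect_equal(length(src$latent$w), 108L)
  expect_false(anyDuplicated(src$records$reaction_id) > 0)

  tgt <- generate_target_domain(cfg, lib, src$latent)
  expect_equal(nrow(tgt$records), 10L)
  expect_equal(length(unique(tgt$records$indole_id)), 1L)
  expect_equal(length(unique(tgt$records$alkene_id)), 1L)
})

test_that("generation is reproducible from the seed, byte for byte", {
  cfg <- synthetic_config(seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- simulate_to_csv(cfg, d1)
  p2 <- simulate_to_csv(cfg, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  d3 <- withr::local_tempdir()
  p3 <- simulate_to_csv(synthetic_config(seed = 10), d3)
  expect_false(identical(readLines(p1[["cca"]]), readLines(p3[["cca"]])))
})

test_that("generated selectivities stay in the physical range", {
  for (s in 1:5) {
    cfg <- synthetic_config(seed = s)
    lib <- generate_descriptor_library(cfg)
    src <- generate_source_domain(cfg, lib)
    tgt <- generate_target_domain(cfg, lib, src$latent)
    ee <- c(src$records$ee_observed, tgt$records$ee_observed)
    expect_true(all(ee >= 0 & ee <= 0.999))
    expect_true(all(is.finite(c(src$records$ddg_exp, tgt$records$ddg_exp))))
  }
})

test_that("in the noiseless limit observations equal the latent SPR", {
  cfg <- synthetic_config(seed = 6, noise_sd = 0, perturbation_mode = "none")
  lib <- generate_descriptor_library(cfg)
  src <- generate_source_domain(cfg, lib)
  x <- encode_reactions(src$records, lib$tables)
  truth <- drop(x %*% src$latent$w) + src$latent$intercept
  expect_equal(src$records$ddg_exp, unname(truth), tolerance = 1e-9)

  tgt <- generate_target_domain(cfg, lib, src$latent)
  xt <- encode_reactions(tgt$records, lib$tables)
  truth_t <- drop(xt %*% src$latent$w) + src$latent$intercept
  expect_equal(tgt$records$ddg_exp, unname(truth_t), tolerance = 1e-9)
})

test_that("descriptor columns are standard normal-ish but inter-correlated", {
  cfg <- synthetic_config(seed = 2, n_ccas = 400)
  lib <- generate_descriptor_library(cfg)
  m <- unclass(lib$tables$cca)
  expect_lt(max(abs(colMeans(m))), 0.3)
  expect_true(all(apply(m, 2, sd) > 0.7 & apply(m, 2, sd) < 1.4))
  cm <- cor(m)
  expect_gt(mean(abs(cm[upper.tri(cm)])), 0.2)  # low-rank structure
})

test_that("the perturbation magnitude matches the configured amplitude", {
  # Monte-Carlo over seeds: mean |g| over target CCAs ~ 0.3 kcal/mol
  mean_g <- vapply(1:100, function(s) {
    cfg <- synthetic_config(seed = s, noise_sd = 0)
    lib <- generate_descriptor_library(cfg)
    src <- generate_source_domain(cfg, lib)
    tgt <- generate_target_domain(cfg, lib, src$latent)
    cca_desc <- unclass(lib$tables$cca)[tgt$records$cca_id, , drop = FALSE]
    mean(abs(tgt$latent$perturbation$g(cca_desc)))
  }, numeric(1))
  expect_gt(mean(mean_g), 0.15)
  expect_lt(mean(mean_g), 0.45)
})

test_that("the nonlinear perturbation mode is bounded and nontrivial", {
  cfg <- synthetic_config(seed = 3, perturbation_mode = "nonlinear_on_cca")
  lib <- generate_descriptor_library(cfg)
  src <- generate_source_domain(cfg, lib)
  tgt <- generate_target_domain(cfg, lib, src$latent)
  g <- tgt$latent$perturbation$g(unclass(lib$tables$cca))
  expect_true(all(is.finite(g)))
  expect_gt(sd(g), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_ccas = 0), "positive")
  expect_error(synthetic_config(noise_sd = -1), ">= 0")
  expect_error(synthetic_config(n_target_ccas = 30), "exceed")
})

test_that("zero perturbation and noise make transfer equal base-only", {
  rep <- recovery_experiment(
    synthetic_config(seed = 11, noise_sd = 0, perturbation_mode = "none"),
    base_spec = regressor_spec("linear_svr", cost = 10, epsilon = 1e-3))
  expect_lt(abs(rep$target_mae_transfer - rep$target_mae_base), 0.02)
})

test_that("the true best candidate is found by the transfer screen", {
  reports <- default_recovery_reports()
  rank_t <- vapply(reports, function(r) r$rank_true_best_transfer, numeric(1))
  rank_n <- vapply(reports, function(r) r$rank_true_best_naive, numeric(1))
  expect_gte(mean(rank_t <= 3), 0.8)
  expect_lt(median(rank_t), median(rank_n))
})

test_that("noiseless unperturbed data give near-perfect cross-validation", {
  cfg <- synthetic_config(seed = 1, noise_sd = 0, perturbation_mode = "none")
  lib <- generate_descriptor_library(cfg)
  src <- generate_source_domain(cfg, lib)
  cv <- kfold_cv(encoded_dataset(src$records, lib$tables),
                 regressor_spec("linear_svr", cost = 1e4, epsilon = 1e-5),
                 k = 10, seed = 0)
  expect_gt(cv$pearson_r, 0.99)
})
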