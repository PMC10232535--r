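# Delta learning: residual records, the correction model, leave-one-out
# evaluation, additivity and the pooled baseline.

delta_setup <- function(seed = 1, ...) {
  cfg <- synthetic_config(seed = seed, ...)
  lib <- generate_descriptor_library(cfg)
  src <- generate_source_domain(cfg, lib)
  tgt <- generate_target_domain(cfg, lib, src$latent)
  base <- fit_base(encoded_dataset(src$records, lib$tables))
  list(cfg = cfg, lib = lib, src = src, tgt = tgt, base = base,
       tables = lib$tables)
}

test_that("residual records carry D = ddg_pred - ddg_exp exactly", {
  s <- delta_setup()
  dr <- compute_residuals(s$base, s$tgt$records, s$tables)
  expect_equal(nrow(dr), 10)
  expect_identical(dr$D, dr$ddg_pred_base - dr$ddg_exp)
  expect_equal(dr$ddg_exp, s$tgt$records$ddg_exp)
})

test_that("a base model that reproduces the target yields D = 0 and a null delta", {
  s <- delta_setup()
  dr <- compute_residuals(s$base, s$tgt$records, s$tables)
  dr$D <- rep(0, nrow(dr))  # as if the base were exact
  dm <- fit_delta(dr)
  x <- attr(dr, "encoded")
  expect_lt(max(abs(chirtransfer:::predict_D(dm, x))), 0.02)
})

test_that("a constant residual is captured as an intercept", {
  s <- delta_setup()
  dr <- compute_residuals(s$base, s$tgt$records, s$tables)
  dr$D <- rep(0.25, nrow(dr))
  dm <- fit_delta(dr)
  x <- attr(dr, "encoded")
  expect_equal(unname(chirtransfer:::predict_D(dm, x)), rep(0.25, nrow(x)),
               tolerance = 0.05)
})

test_that("substrate columns frozen across the delta set are dropped and recorded", {
  s <- delta_setup()
  dr <- compute_residuals(s$base, s$tgt$records, s$tables)
  dm <- fit_delta(dr)
  expect_true("temperature" %in% dm$dropped)
  expect_true(all(grepl("^(indole|alkene)\\.|^temperature$", dm$dropped)))
  expect_equal(sort(c(dm$keep, dm$dropped)), sort(dm$schema))
})

test_that("transfer prediction is exactly base minus predicted D", {
  s <- delta_setup()
  tm <- fit_transfer(s$base, s$tgt$records, s$tables)
  x <- encode_reactions(s$tgt$records, s$tables)
  parts <- predict(tm, x, components = TRUE)
  expect_identical(parts$ddg_corrected, parts$ddg_base - parts$D_hat)
  expect_identical(predict(tm, x), parts$ddg_base - parts$D_hat)
  expect_equal(parts$ddg_base, unname(predict(s$base, x)))
})

test_that("both sign conventions define the same corrected predictor", {
  s <- delta_setup()
  x <- encode_reactions(s$tgt$records, s$tables)
  a <- fit_transfer(s$base, s$tgt$records, s$tables,
                    regressor_spec("ridge", lambda = 0.1),
                    convention = "base_minus_D", loo = FALSE)
  b <- fit_transfer(s$base, s$tgt$records, s$tables,
                    regressor_spec("ridge", lambda = 0.1),
                    convention = "base_plus_negD", loo = FALSE)
  expect_equal(predict(a, x), predict(b, x), tolerance = 1e-8)
})

test_that("a zero-predicting delta model leaves the base prediction unchanged", {
  s <- delta_setup()
  tm <- fit_transfer(s$base, s$tgt$records, s$tables, loo = FALSE)
  tm$delta$fit <- list(kind = "linear",
                       w = setNames(rep(0, length(tm$delta$keep)), tm$delta$keep),
                       b = 0)
  x <- encode_reactions(s$tgt$records, s$tables)
  expect_equal(predict(tm, x), unname(predict(s$base, x)))
})

test_that("leave-one-out evaluation is deterministic and order invariant", {
  s <- delta_setup()
  dr <- compute_residuals(s$base, s$tgt$records, s$tables)
  a <- loo_evaluate(dr)
  expect_identical(a, loo_evaluate(dr))

  perm <- c(4, 1, 9, 2, 10, 3, 7, 5, 8, 6)
  recs_perm <- s$tgt$records[perm, ]
  dr_perm <- compute_residuals(s$base, recs_perm, s$tables)
  b <- loo_evaluate(dr_perm)
  expect_equal(a$mae_uncorrected, b$mae_uncorrected, tolerance = 1e-10)
  expect_equal(a$mae_corrected, b$mae_corrected, tolerance = 1e-8)
  m <- match(a$per_point$cca_id, b$per_point$cca_id)
  expect_equal(a$per_point$ddg_corrected, b$per_point$ddg_corrected[m],
               tolerance = 1e-8)
})

test_that("identical residuals are corrected regardless of base error", {
  s <- delta_setup()
  dr <- compute_residuals(s$base, s$tgt$records, s$tables)
  dr$ddg_exp <- dr$ddg_pred_base - 0.3  # constant shift
  dr$D <- dr$ddg_pred_base - dr$ddg_exp
  rep <- loo_evaluate(dr)
  expect_equal(rep$mae_uncorrected, 0.3, tolerance = 1e-10)
  expect_lt(rep$mae_corrected, 0.05)
})

test_that("structured residuals are corrected; shuffled residuals are not", {
  set.seed(99)
  gains <- vapply(1:8, function(s) {
    st <- delta_setup(seed = s)
    dr <- compute_residuals(st$base, st$tgt$records, st$tables)
    structured <- loo_evaluate(dr)
    structured$mae_corrected / structured$mae_uncorrected
  }, numeric(1))
  expect_lt(mean(gains), 0.75)

  # destroy the descriptor-residual link: no free lunch
  st <- delta_setup(seed = 1)
  dr <- compute_residuals(st$base, st$tgt$records, st$tables)
  ratios <- vapply(1:12, function(i) {
    sh <- dr
    sh$D <- sample(dr$D) * sample(c(-1, 1), nrow(dr), replace = TRUE)
    sh$ddg_exp <- sh$ddg_pred_base - sh$D
    rep <- loo_evaluate(sh)
    rep$mae_corrected / rep$mae_uncorrected
  }, numeric(1))
  expect_gt(mean(ratios), 0.8)
})

test_that("delta fitting demands enough records", {
  s <- delta_setup()
  dr <- compute_residuals(s$base, s$tgt$records, s$tables)
  one <- dr[1, , drop = FALSE]
  attr(one, "encoded") <- attr(dr, "encoded")[1, , drop = FALSE]
  class(one) <- class(dr)
  expect_error(fit_delta(one), "at least 2")
  two <- dr[1:2, , drop = FALSE]
  attr(two, "encoded") <- attr(dr, "encoded")[1:2, , drop = FALSE]
  class(two) <- class(dr)
  expect_error(loo_evaluate(two), "at least 3")
})

test_that("pooled training with an empty target set equals the base fit", {
  s <- delta_setup()
  empty <- s$tgt$records[0, ]
  pooled <- fit_naive_pooled(s$src$records, empty, s$tables)
  x <- encode_reactions(s$src$records, s$tables)
  expect_equal(predict(pooled, x), predict(s$base, x), tolerance = 1e-10)
})

test_that("with identical source and target SPRs pooling barely moves the model", {
  cfg <- synthetic_config(seed = 5, perturbation_mode = "none", noise_sd = 0)
  lib <- generate_descriptor_library(cfg)
  src <- generate_source_domain(cfg, lib)
  tgt <- generate_target_domain(cfg, lib, src$latent)
  ds <- encoded_dataset(src$records, lib$tables)
  base <- fit_base(ds, regressor_spec("ridge", lambda = 0.1))
  pooled <- fit_naive_pooled(src$records, tgt$records, lib$tables,
                             regressor_spec("ridge", lambda = 0.1))
  cb <- coef(base); cp <- coef(pooled)
  expect_lt(sqrt(sum((cb - cp)^2)) / sqrt(sum(cb^2)), 0.2)
  xt <- encode_reactions(tgt$records, lib$tables)
  expect_lt(mae(predict(pooled, xt), predict(base, xt)), 0.05)
})
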