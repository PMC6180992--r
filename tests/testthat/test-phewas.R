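test_that("visit counts map to case/control/excluded and filter at 50 cases", {
  v <- matrix(c(0L, 1L, 2L, 3L, 7L, 0L), 3, 2,
              dimnames = list(paste0("s", 1:3), c("250.00", "272.00")))
  cc <- assign_case_control(v)
  expect_equal(unclass(cc)[, "250.00"], c(s1 = "control", s2 = "excluded",
                                          s3 = "excluded"))
  expect_equal(unclass(cc)[, "272.00"], c(s1 = "case", s2 = "case",
                                          s3 = "control"))
  ## statuses partition subjects for every code
  expect_true(all(unclass(cc) %in% c("case", "control", "excluded")))
  expect_error(assign_case_control(matrix(-1L, 1, 1)),
               class = "adipoquant_schema_error")

  ## filter boundary: 49 cases dropped, 50 kept
  v2 <- matrix(0L, 60, 2, dimnames = list(paste0("p", 1:60), c("a", "b")))
  v2[1:49, 1] <- 5L
  v2[1:50, 2] <- 5L
  cc2 <- assign_case_control(v2)
  expect_equal(filter_codes(cc2, 50), "b")
  expect_equal(filter_codes(cc2, 49), c("a", "b"))
  empty <- assign_case_control(matrix(0L, 2, 0))
  expect_length(filter_codes(empty), 0L)
})

test_that("quantitative cleaning trims single-pass 2.5-SD outliers", {
  ## constant vector: sd 0, nothing removed
  expect_equal(clean_quantitative(rep(5, 10))$n_removed, 0)

  ## one value at mean + 3 sd of the others is removed (verified directly)
  set.seed(1)
  base <- rnorm(200, 10, 2)
  spike <- mean(base) + 3 * sd(base)
  x <- c(base, spike)
  expect_true(abs(spike - mean(x)) > 2.5 * sd(x))  # oracle: direct arithmetic
  cl <- clean_quantitative(x)
  expect_false(cl$keep[201])

  ## natural-log branch
  expect_equal(clean_quantitative(c(1, exp(1), exp(2)), log_transform = TRUE)$values,
               c(0, 1, 2))
  expect_error(clean_quantitative(c(-1, 1, 2), log_transform = TRUE),
               class = "adipoquant_invalid_params")
  expect_error(clean_quantitative(c(1, 2)), class = "adipoquant_invalid_params")
})

test_that("Box-Cox branches match their closed forms and the MLE finds ~0 for lognormal", {
  y <- c(0.5, 1, 2, 3, 5, 8, 13, 21, 34, 55)
  b0 <- boxcox_mle(y, lambda_grid = 0)
  expect_equal(b0$transformed, log(y))
  b1 <- boxcox_mle(y, lambda_grid = 1)
  expect_equal(b1$transformed, y - 1)

  set.seed(42)
  z <- exp(rnorm(2000, 0, 0.6))
  fit <- boxcox_mle(z)
  expect_gte(fit$lambda, -0.15); expect_lte(fit$lambda, 0.15)
  ## independent oracle: MASS profile likelihood on a coarse grid
  mb <- MASS::boxcox(z ~ 1, lambda = seq(-2, 2, 0.05), plotit = FALSE)
  expect_lt(abs(fit$lambda - mb$x[which.max(mb$y)]), 0.06)
  ## transform is monotone in the input
  expect_true(all(diff(fit$transformed[order(z)]) >= 0))

  expect_error(boxcox_mle(c(-1, 2:20)), class = "adipoquant_invalid_params")
  expect_error(boxcox_mle(1:5), class = "adipoquant_invalid_params")
})

test_that("logistic fits match the 2x2 cross-product odds ratio", {
  y <- c(rep(1, 40), rep(0, 40))
  x <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  r <- fit_logistic(y, x)
  expect_equal(r$or_, 9.0, tolerance = 1e-6)
  expect_true(r$converged)
  expect_true(r$ci_lo <= r$or_ && r$or_ <= r$ci_hi)
  expect_equal(r$n_cases, 40L); expect_equal(r$n_controls, 40L)

  expect_error(fit_logistic(rep(1, 20), rnorm(20)),
               class = "adipoquant_invalid_params")
  expect_error(fit_logistic(rbinom(20, 1, 0.5), rep(2, 20)),
               class = "adipoquant_rank_error")

  ## complete separation is flagged, not thrown
  ys <- c(rep(0, 20), rep(1, 20))
  xs <- c(rnorm(20, -5), rnorm(20, 5))
  expect_false(fit_logistic(ys, xs)$converged)
})

test_that("linear fits recover exact and null slopes", {
  x <- seq(-3, 3, length.out = 50)
  ## lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(fit_linear(2 * x, x))
  expect_equal(fit$beta, 2, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-20)
  expect_true(is.na(fit$or_))

  set.seed(11)
  null <- fit_linear(rnorm(200), rnorm(200))
  expect_lt(abs(null$beta), 0.2)

  expect_error(fit_linear(1:2, 1:2), class = "adipoquant_rank_error")
})

test_that("Bonferroni thresholds follow the family arithmetic", {
  expect_equal(signif(bonferroni_threshold(multiple_testing_config(0.01, 35, 4)), 3),
               7.14e-5)
  expect_equal(bonferroni_threshold(multiple_testing_config(0.05, 1, 1)), 0.05)
  expect_equal(bonferroni_threshold(multiple_testing_config(0.01, 1233, 4)),
               0.01 / 4932)
})

test_that("BH step-up matches hand execution and p.adjust", {
  r <- bh_fdr(c(0.001, 0.02, 0.03, 0.5), 0.05)
  expect_equal(r$p_cutoff, 0.03)
  expect_equal(r$rejected, c(TRUE, TRUE, TRUE, FALSE))

  expect_equal(bh_fdr(rep(1, 5), 0.05)$rejected, rep(FALSE, 5))
  expect_true(bh_fdr(0.001, 0.01)$rejected)

  ## oracle equivalence on random p-vectors: BH rejection set equals
  ## p.adjust-based step-up
  for (seed in 1:20) {
    set.seed(seed)
    p <- runif(sample(5:50, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_equal(bh_fdr(p, q)$rejected, p.adjust(p, "BH") <= q)
  }
  expect_error(bh_fdr(numeric(0), 0.05), class = "adipoquant_invalid_params")
  expect_error(bh_fdr(c(0, 0.5), 0.05), class = "adipoquant_invalid_params")
})

test_that("run_phewas wires outcomes, strata, and annotation together", {
  gen <- generate_synth_ehr(800, synth_effect_spec(), seed = 3)
  cfg <- phewas_config(exposures = c("vat", "sat"))
  res <- run_phewas(gen$adipose, gen$visits, gen$labs, gen$covars, cfg)
  expect_true(all(c("exposure", "outcome", "model", "stratum", "beta", "se",
                    "p_value", "or_", "ci_lo", "ci_hi", "n_cases",
                    "n_controls", "n_obs", "converged", "family",
                    "bonferroni_threshold", "bonferroni_sig", "fdr_cutoff",
                    "fdr_sig") %in% names(res)))
  expect_setequal(unique(res$stratum), c("combined", "F", "M"))
  expect_true(all(res$model[res$family == "lab"] == "linear"))

  ## combined n equals F n + M n for every converged triple
  for (i in which(res$stratum == "combined" & res$converged)) {
    fm <- res[res$exposure == res$exposure[i] & res$outcome == res$outcome[i] &
              res$stratum %in% c("F", "M") & res$converged, ]
    if (nrow(fm) == 2L) {
      if (res$model[i] == "logistic")
        expect_equal(res$n_cases[i] + res$n_controls[i],
                     sum(fm$n_cases) + sum(fm$n_controls))
      else expect_equal(res$n_obs[i], sum(fm$n_obs))
    }
  }

  ## the planted VAT association (OR 2.0 on 250.00) clears Bonferroni
  hit <- res[res$exposure == "vat" & res$outcome == "250.00" &
             res$stratum == "combined", ]
  expect_true(hit$bonferroni_sig)

  ## misaligned covariates are an error
  expect_error(run_phewas(gen$adipose, gen$visits, NULL, gen$covars[-1, ], cfg),
               class = "adipoquant_alignment_error")
})

test_that("a null cohort produces essentially no Bonferroni rejections", {
  n_hits <- vapply(1:5, function(seed) {
    gen <- generate_synth_ehr(500, null_effect_spec(n_codes = 30, n_labs = 0),
                              seed = seed)
    res <- run_phewas(gen$adipose, gen$visits, NULL, gen$covars,
                      phewas_config(exposures = "vat", strata = "combined"))
    sum(res$bonferroni_sig)
  }, numeric(1))
  expect_true(all(n_hits <= 1))
})
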