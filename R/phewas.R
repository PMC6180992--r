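#' ICD-9 case/control assignment from visit counts
#'
#' For each subject x code cell: `>= min_case_visits` visits makes a case,
#' zero visits a control, and anything in between (one or two visits under
#' the default rule) is excluded from analysis for that code.
#'
#' @param visits Integer matrix, subjects (rows, named) x 5-digit ICD-9
#'   codes (columns, named); cells are non-negative visit counts.
#' @param min_case_visits Minimum visits to qualify as a case.
#' @return Character matrix of the same shape with entries `"case"`,
#'   `"control"`, `"excluded"`; class `case_control_table`.
#' @export
assign_case_control <- function(visits, min_case_visits = 3L) {
  visits <- as.matrix(visits)
  if (any(visits < 0) || any(visits != round(visits)))
    adq_error("visit counts must be non-negative integers",
              "adipoquant_schema_error")
  status <- matrix("excluded", nrow(visits), ncol(visits),
                   dimnames = dimnames(visits))
  status[visits >= min_case_visits] <- "case"
  status[visits == 0] <- "control"
  structure(status, class = c("case_control_table", class(status)))
}

#' Retain codes with enough cases
#'
#' @param cc A `case_control_table` from [assign_case_control].
#' @param min_cases Minimum case count for a code to be analyzed.
#' @return Character vector of retained code names, input order preserved.
#' @export
filter_codes <- function(cc, min_cases = 50L) {
  n_cases <- colSums(unclass(cc) == "case")
  colnames(cc)[n_cases >= min_cases]
}

#' Outlier removal and optional log transform for a quantitative measure
#'
#' Single-pass two-sided trim: values farther than `sd_cutoff` standard
#' deviations from the mean (both computed on the full input) are removed;
#' a natural-log transform is then applied when requested. A constant
#' vector (zero SD) is passed through untouched.
#'
#' @param values Numeric vector with at least 3 finite values.
#' @param sd_cutoff Trim threshold in SD units.
#' @param log_transform Apply `log()` after trimming (requires positive
#'   values).
#' @return `list(values = cleaned vector, keep = logical for the original
#'   positions, n_removed)`.
#' @export
clean_quantitative <- function(values, sd_cutoff = 2.5, log_transform = FALSE) {
  if (sum(is.finite(values)) < 3L)
    adq_error("need at least 3 finite values", "adipoquant_invalid_params")
  m <- mean(values[is.finite(values)])
  s <- sd(values[is.finite(values)])
  keep <- is.finite(values) & (s == 0 | abs(values - m) <= sd_cutoff * s)
  out <- values[keep]
  if (log_transform) {
    if (any(out <= 0))
      adq_error("log transform requires positive values",
                "adipoquant_invalid_params")
    out <- log(out)
  }
  list(values = out, keep = keep, n_removed = sum(is.finite(values)) - sum(keep))
}

#' Box-Cox transformation with maximum-likelihood lambda
#'
#' `y(lambda) = (y^lambda - 1) / lambda` for `lambda != 0` and `log(y)` at
#' `lambda = 0`. The power is chosen by maximizing the profile
#' log-likelihood over a grid on `[-5, 5]` with step 0.01. Inputs must be
#' strictly positive; no automatic shifting is applied.
#'
#' @param values Positive numeric vector, `n >= 10`.
#' @param lambda_grid Candidate powers.
#' @return `list(lambda, transformed, loglik)` of class `boxcox_result`.
#' @export
boxcox_mle <- function(values, lambda_grid = seq(-5, 5, by = 0.01)) {
  if (any(!is.finite(values)) || any(values <= 0))
    adq_error("Box-Cox requires finite positive values",
              "adipoquant_invalid_params")
  n <- length(values)
  if (n < 10L)
    adq_error("Box-Cox needs at least 10 observations",
              "adipoquant_invalid_params")
  ly <- log(values)
  sly <- sum(ly)
  loglik <- vapply(lambda_grid, function(lam) {
    z <- if (abs(lam) < .Machine$double.eps) ly else (values^lam - 1) / lam
    v <- mean((z - mean(z))^2)          # MLE variance
    -n / 2 * log(v) + (lam - 1) * sly
  }, numeric(1))
  lam <- lambda_grid[which.max(loglik)]
  z <- if (abs(lam) < .Machine$double.eps) ly else (values^lam - 1) / lam
  structure(list(lambda = lam, transformed = z,
                 loglik = data.frame(lambda = lambda_grid, loglik = loglik)),
            class = "boxcox_result")
}

.assoc_row <- function(exposure, outcome, model, stratum, beta = NA_real_,
                       se = NA_real_, p_value = NA_real_, or_ = NA_real_,
                       ci_lo = NA_real_, ci_hi = NA_real_,
                       n_cases = NA_integer_, n_controls = NA_integer_,
                       n_obs = NA_integer_, converged = FALSE) {
  data.frame(exposure = exposure, outcome = outcome, model = model,
             stratum = stratum, beta = beta, se = se, p_value = p_value,
             or_ = or_, ci_lo = ci_lo, ci_hi = ci_hi, n_cases = n_cases,
             n_controls = n_controls, n_obs = n_obs, converged = converged,
             stringsAsFactors = FALSE)
}

#' Logistic association between a binary outcome and an exposure
#'
#' Maximum-likelihood logistic regression (IRLS, tolerance 1e-8, up to 100
#' iterations) of the outcome on the exposure plus covariates. Reports the
#' Wald standard error, a normal-approximation two-sided p-value, the odds
#' ratio `exp(beta)` and its 95 percent CI `exp(beta +/- 1.96 se)`.
#' Separation or non-convergence is reported as `converged = FALSE`, not
#' as an error, mirroring the practice of flagging and dropping
#' non-converged models.
#'
#' @param outcome Binary vector (0/1 or logical); both classes required.
#' @param exposure Numeric exposure vector.
#' @param covariates Optional data frame of covariates.
#' @param exposure_name,outcome_name,stratum Labels for the result row.
#' @return One-row data frame (see `.assoc_row` fields).
#' @export
fit_logistic <- function(outcome, exposure, covariates = NULL,
                         exposure_name = "exposure",
                         outcome_name = "outcome", stratum = "combined") {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1) | is.na(y)))
    adq_error("outcome must be binary", "adipoquant_invalid_params")
  df <- data.frame(.y = y, .x = as.numeric(exposure))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$.y)) < 2L)
    adq_error("outcome must contain both classes", "adipoquant_invalid_params")
  if (length(unique(df$.x)) < 2L)
    adq_error("exposure is constant (rank-deficient design)",
              "adipoquant_rank_error")
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  beta <- sm[".x", "Estimate"]; se <- sm[".x", "Std. Error"]
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  converged <- isTRUE(fit$converged) && !separated && is.finite(se) && se < 100
  .assoc_row(exposure_name, outcome_name, "logistic", stratum,
             beta = beta, se = se, p_value = p, or_ = exp(beta),
             ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
             n_cases = sum(df$.y == 1), n_controls = sum(df$.y == 0),
             n_obs = nrow(df), converged = converged)
}

#' Linear association between a quantitative outcome and an exposure
#'
#' Ordinary least squares of the outcome on the exposure plus covariates,
#' with the t-based two-sided p-value for the exposure coefficient. No
#' odds-ratio fields are populated.
#'
#' @inheritParams fit_logistic
#' @param outcome Numeric outcome vector.
#' @return One-row data frame (see `.assoc_row` fields).
#' @export
fit_linear <- function(outcome, exposure, covariates = NULL,
                       exposure_name = "exposure", outcome_name = "outcome",
                       stratum = "combined") {
  df <- data.frame(.y = as.numeric(outcome), .x = as.numeric(exposure))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) <= ncol(df))
    adq_error("need more observations than parameters",
              "adipoquant_rank_error")
  if (length(unique(df$.x)) < 2L)
    adq_error("exposure is constant (rank-deficient design)",
              "adipoquant_rank_error")
  fit <- lm(.y ~ ., data = df)
  if (any(is.na(coef(fit))))
    adq_error("rank-deficient design", "adipoquant_rank_error")
  sm <- summary(fit)$coefficients
  .assoc_row(exposure_name, outcome_name, "linear", stratum,
             beta = sm[".x", "Estimate"], se = sm[".x", "Std. Error"],
             p_value = sm[".x", "Pr(>|t|)"], n_obs = nrow(df),
             converged = TRUE)
}

#' Multiple-testing configuration
#'
#' @param family_alpha Family-wise alpha for the Bonferroni correction.
#' @param n_outcomes Number of outcomes tested in the family.
#' @param n_phenotypes Number of adipose exposures tested.
#' @param fdr_q Target false discovery rate for the step-up procedure.
#' @return An object of class `multiple_testing_config`.
#' @export
multiple_testing_config <- function(family_alpha = 1e-2, n_outcomes = 35L,
                                    n_phenotypes = 4L, fdr_q = 0.01) {
  if (family_alpha <= 0 || fdr_q <= 0 || fdr_q >= 1)
    adq_error("invalid multiple-testing configuration",
              "adipoquant_invalid_params")
  structure(list(family_alpha = family_alpha,
                 n_outcomes = as.integer(n_outcomes),
                 n_phenotypes = as.integer(n_phenotypes), fdr_q = fdr_q),
            class = "multiple_testing_config")
}

#' Bonferroni significance threshold
#'
#' `family_alpha / (n_outcomes * n_phenotypes)`; e.g. 0.01 over 35 lab
#' outcomes and 4 adipose phenotypes gives 7.14e-5.
#'
#' @param cfg A [multiple_testing_config].
#' @return Scalar threshold.
#' @export
bonferroni_threshold <- function(cfg) {
  denom <- cfg$n_outcomes * cfg$n_phenotypes
  if (denom < 1)
    adq_error("threshold denominator must be >= 1",
              "adipoquant_invalid_params")
  cfg$family_alpha / denom
}

#' Benjamini-Hochberg step-up FDR procedure
#'
#' Sorts the p-values ascending, finds the largest `k` with
#' `p(k) <= k q / m`, and rejects every hypothesis with `p <= p(k)`.
#'
#' @param p_values P-values in `(0, 1]`.
#' @param q Target FDR.
#' @return `list(p_cutoff = p(k) or 0 when nothing is rejected,
#'   rejected = logical flags in input order)`.
#' @export
bh_fdr <- function(p_values, q) {
  if (length(p_values) == 0L)
    adq_error("empty p-value vector", "adipoquant_invalid_params")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    adq_error("p-values must lie in (0, 1]", "adipoquant_invalid_params")
  m <- length(p_values)
  ps <- sort(p_values)
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0L)
    return(list(p_cutoff = 0, rejected = rep(FALSE, m)))
  cutoff <- ps[max(ok)]
  list(p_cutoff = cutoff, rejected = p_values <= cutoff)
}

#' Phenome-wide association scan of adipose measures
#'
#' Runs the full association procedure: Box-Cox-normalized and
#' standardized adipose exposures against (a) ICD-9 diagnosis outcomes
#' built by the visit-count case/control rule and the minimum-case filter,
#' via logistic regression, and (b) cleaned clinical lab outcomes via
#' linear regression. Sex-combined models adjust for age and sex (and
#' optionally a diabetes flag); sex-stratified models adjust for age.
#' Results are annotated with the per-family Bonferroni threshold and the
#' Benjamini-Hochberg flag computed within family, stratum, and model over
#' converged rows.
#'
#' @param adipose Data frame with `subject_id` and one column per exposure
#'   in `cfg$exposures` (e.g. `vat`, `sat`, `tat`, `bmi`).
#' @param visits Integer matrix subjects x ICD-9 codes (rownames =
#'   subject ids), as from [read_visits] or [generate_synth_ehr].
#' @param labs Optional data frame with `subject_id` and one numeric
#'   column per lab.
#' @param covars Data frame with `subject_id`, `age`, `sex` and optional
#'   `t2d`; must cover every subject in `adipose`.
#' @param cfg List of settings; see [phewas_config].
#' @return Data frame of association rows with annotation columns
#'   `bonferroni_threshold`, `bonferroni_sig`, `fdr_cutoff`, `fdr_sig`.
#' @export
run_phewas <- function(adipose, visits, labs = NULL, covars,
                       cfg = phewas_config()) {
  ids <- as.character(adipose$subject_id)
  if (anyDuplicated(ids))
    adq_error("duplicate subject ids in adipose table",
              "adipoquant_alignment_error")
  if (!all(ids %in% as.character(covars$subject_id)))
    adq_error("covariate table does not cover all subjects",
              "adipoquant_alignment_error")
  cov <- covars[match(ids, as.character(covars$subject_id)), , drop = FALSE]
  use_t2d <- isTRUE(cfg$include_t2d) && "t2d" %in% names(cov)

  ## exposures: Box-Cox normalize (positive measures only), standardize
  expo <- lapply(cfg$exposures, function(e) {
    x <- adipose[[e]]
    if (is.null(x))
      adq_error(paste("missing exposure column:", e),
                "adipoquant_alignment_error")
    if (isTRUE(cfg$boxcox) && all(x > 0)) x <- boxcox_mle(x)$transformed
    as.numeric(scale(x))
  })
  names(expo) <- cfg$exposures

  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r

  ## -- ICD-9 diagnosis outcomes -------------------------------------------
  n_codes <- 0L
  if (!is.null(visits)) {
    if (!all(ids %in% rownames(visits)))
      adq_error("visit table does not cover all subjects",
                "adipoquant_alignment_error")
    cc <- assign_case_control(visits[ids, , drop = FALSE],
                              cfg$min_case_visits)
    codes <- filter_codes(cc, cfg$min_cases)
    n_codes <- length(codes)
    for (code in codes) {
      status <- unclass(cc)[, code]
      y <- ifelse(status == "case", 1, ifelse(status == "control", 0, NA))
      for (e in cfg$exposures) {
        for (st in cfg$strata) {
          sel <- if (st == "combined") rep(TRUE, length(ids)) else cov$sex == st
          cv <- if (st == "combined") {
            d <- data.frame(age = cov$age, sex = factor(cov$sex))
            if (use_t2d) d$t2d <- cov$t2d
            d
          } else {
            d <- data.frame(age = cov$age)
            if (use_t2d) d$t2d <- cov$t2d
            d
          }
          r <- tryCatch(
            fit_logistic(y[sel], expo[[e]][sel], cv[sel, , drop = FALSE],
                         exposure_name = e, outcome_name = code, stratum = st),
            adipoquant_error = function(err)
              .assoc_row(e, code, "logistic", st))
          r$family <- "icd9"
          add(r)
        }
      }
    }
  }

  ## -- clinical lab outcomes ----------------------------------------------
  lab_names <- character(0)
  if (!is.null(labs)) {
    lab_names <- setdiff(names(labs), "subject_id")
    if (!all(ids %in% as.character(labs$subject_id)))
      adq_error("lab table does not cover all subjects",
                "adipoquant_alignment_error")
    lab <- labs[match(ids, as.character(labs$subject_id)), , drop = FALSE]
    for (ln in lab_names) {
      cl <- clean_quantitative(lab[[ln]], cfg$sd_cutoff,
                               log_transform = ln %in% cfg$log_labs)
      y <- rep(NA_real_, length(ids))
      y[cl$keep] <- cl$values
      for (e in cfg$exposures) {
        for (st in cfg$strata) {
          sel <- if (st == "combined") rep(TRUE, length(ids)) else cov$sex == st
          cv <- if (st == "combined")
            data.frame(age = cov$age, sex = factor(cov$sex))
          else data.frame(age = cov$age)
          r <- tryCatch(
            fit_linear(y[sel], expo[[e]][sel], cv[sel, , drop = FALSE],
                       exposure_name = e, outcome_name = ln, stratum = st),
            adipoquant_error = function(err)
              .assoc_row(e, ln, "linear", st))
          r$family <- "lab"
          add(r)
        }
      }
    }
  }

  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)

  ## multiple-testing annotation, per outcome family
  res$bonferroni_threshold <- NA_real_
  res$bonferroni_sig <- FALSE
  res$fdr_cutoff <- NA_real_
  res$fdr_sig <- FALSE
  for (fam in unique(res$family)) {
    n_out <- if (fam == "icd9") n_codes else length(lab_names)
    thr <- bonferroni_threshold(multiple_testing_config(
      cfg$family_alpha, n_out, length(cfg$exposures), cfg$fdr_q))
    sel <- res$family == fam
    res$bonferroni_threshold[sel] <- thr
    res$bonferroni_sig[sel] <- sel[sel] & res$converged[sel] &
      !is.na(res$p_value[sel]) & res$p_value[sel] < thr
    for (st in unique(res$stratum[sel])) {
      ss <- sel & res$stratum == st & res$converged & !is.na(res$p_value)
      if (!any(ss)) next
      fdr <- bh_fdr(res$p_value[ss], cfg$fdr_q)
      res$fdr_cutoff[ss] <- fdr$p_cutoff
      res$fdr_sig[ss] <- fdr$rejected
    }
  }
  rownames(res) <- NULL
  res
}

#' Configuration for [run_phewas]
#'
#' @param exposures Names of adipose exposure columns to test.
#' @param boxcox Box-Cox normalize positive exposures before testing.
#' @param min_case_visits,min_cases Case/control rule settings.
#' @param sd_cutoff Lab outlier trim, in SD units.
#' @param log_labs Lab names to natural-log transform after trimming.
#' @param family_alpha,fdr_q Multiple-testing settings.
#' @param include_t2d Add the diabetes flag as a covariate when present.
#' @param strata Strata to fit; subset of `c("combined", "F", "M")`.
#' @return A configuration list.
#' @export
phewas_config <- function(exposures = c("vat", "sat", "tat"), boxcox = TRUE,
                          min_case_visits = 3L, min_cases = 50L,
                          sd_cutoff = 2.5, log_labs = character(0),
                          family_alpha = 1e-2, fdr_q = 0.01,
                          include_t2d = FALSE,
                          strata = c("combined", "F", "M")) {
  list(exposures = exposures, boxcox = boxcox,
       min_case_visits = min_case_visits, min_cases = min_cases,
       sd_cutoff = sd_cutoff, log_labs = log_labs,
       family_alpha = family_alpha, fdr_q = fdr_q,
       include_t2d = include_t2d, strata = strata)
}
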