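#' Effect specification for the synthetic EHR generator
#'
#' Declares the generating association structure: per-diagnosis odds
#' ratios on the standardized adipose exposures (plus age and sex
#' effects and a baseline prevalence), and per-lab linear slopes with
#' noise. Odds ratios and slopes are user choices for calibration and
#' power studies, not estimates of any cohort.
#'
#' @param codes Data frame with columns `code`, `or_vat`, `or_sat`,
#'   `or_age`, `or_sexM`, `base_rate`.
#' @param labs Data frame with columns `lab`, `slope_vat`, `slope_sat`,
#'   `intercept`, `noise_sd`.
#' @return A list of class `synth_effect_spec`.
#' @export
synth_effect_spec <- function(
    codes = data.frame(
      code = c("250.00", "278.01", "327.23", "733.00", "401.10"),
      or_vat = c(2.0, 1.0, 1.5, 1.0, 1.0),
      or_sat = c(1.0, 1.8, 1.0, 1.0, 1.0),
      or_age = c(1.3, 1.0, 1.1, 1.4, 1.3),
      or_sexM = c(1.1, 0.9, 1.5, 0.6, 1.0),
      base_rate = c(0.15, 0.12, 0.10, 0.08, 0.20),
      stringsAsFactors = FALSE),
    labs = data.frame(
      lab = c("hdl", "trig", "wbc", "chol"),
      slope_vat = c(-0.075, 0.153, 0.05, 0),
      slope_sat = c(-0.02, 0.05, 0.02, 0),
      intercept = c(3.9, 4.8, 1.9, 5.2),
      noise_sd = c(0.25, 0.45, 0.25, 0.2),
      stringsAsFactors = FALSE)) {
  if (!is.null(codes)) {
    need <- c("code", "or_vat", "or_sat", "or_age", "or_sexM", "base_rate")
    if (!all(need %in% names(codes)) ||
        any(codes$base_rate <= 0 | codes$base_rate >= 1) ||
        any(codes$or_vat <= 0 | codes$or_sat <= 0))
      adq_error("invalid code effect specification",
                "adipoquant_invalid_params")
  }
  if (!is.null(labs)) {
    need <- c("lab", "slope_vat", "slope_sat", "intercept", "noise_sd")
    if (!all(need %in% names(labs)) || any(labs$noise_sd < 0))
      adq_error("invalid lab effect specification",
                "adipoquant_invalid_params")
  }
  structure(list(codes = codes, labs = labs), class = "synth_effect_spec")
}

#' A global-null effect specification
#'
#' All odds ratios 1, all lab slopes 0: every apparent association in data
#' generated from it is a false positive, which makes it the reference
#' input for type-I-error calibration.
#'
#' @param n_codes,n_labs Number of diagnosis codes / labs to emit.
#' @param base_rate Prevalence shared by all codes.
#' @return A [synth_effect_spec].
#' @export
null_effect_spec <- function(n_codes = 10L, n_labs = 4L, base_rate = 0.15) {
  codes <- if (n_codes > 0)
    data.frame(code = sprintf("%03d.%02d", 100 + seq_len(n_codes), 0),
               or_vat = 1, or_sat = 1, or_age = 1, or_sexM = 1,
               base_rate = base_rate, stringsAsFactors = FALSE)
  else NULL
  labs <- if (n_labs > 0)
    data.frame(lab = sprintf("lab%02d", seq_len(n_labs)),
               slope_vat = 0, slope_sat = 0, intercept = 4, noise_sd = 0.3,
               stringsAsFactors = FALSE)
  else NULL
  synth_effect_spec(codes, labs)
}

#' Generate a synthetic EHR cohort with known association structure
#'
#' Emulates the tables an imaging-PheWAS consumes: per-subject adipose
#' areas, ICD-9 visit counts, clinical labs, and covariates. Demographics
#' follow the anchoring cohort's marginals (age ~ Normal(54, 17) truncated
#' to 18-95; 51.4 percent female). VAT and SAT are correlated lognormals
#' (latent correlation 0.5) with sex-specific means (male VAT higher,
#' female SAT higher). Each diagnosis is drawn from a logistic model on
#' the standardized log-adipose measures, age, and sex; visit counts give
#' diseased subjects `2 + Poisson(3)` visits (mostly cases under the
#' >= 3-visit rule) and healthy subjects 0 visits with probability 0.9,
#' otherwise `1 + Poisson(0.5)` (populating the excluded 1-2-visit band).
#' Labs are linear in the standardized measures plus Gaussian noise.
#'
#' @param n_subjects Cohort size (>= 200).
#' @param effect_spec A [synth_effect_spec].
#' @param seed RNG seed; identical seeds give identical tables.
#' @return `list(adipose, visits, labs, covars, truth)`; `truth` records
#'   every generating parameter plus the standardized exposures
#'   (`z_vat`, `z_sat`) the effects were applied to.
#' @export
generate_synth_ehr <- function(n_subjects, effect_spec = synth_effect_spec(),
                               seed = 1L) {
  if (n_subjects < 200L)
    adq_error("n_subjects must be >= 200", "adipoquant_invalid_params")
  stopifnot(inherits(effect_spec, "synth_effect_spec"))
  with_seed(as.integer(seed), {
    n <- as.integer(n_subjects)
    ids <- sprintf("S%05d", seq_len(n))

    age <- rnorm(n, 54, 17)
    while (any(bad <- age < 18 | age > 95))
      age[bad] <- rnorm(sum(bad), 54, 17)
    sex <- ifelse(rbinom(n, 1, 0.514) == 1, "F", "M")

    rho <- 0.5
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    meanlog_vat <- ifelse(sex == "M", 4.9, 4.6)
    meanlog_sat <- ifelse(sex == "M", 5.0, 5.2)
    vat <- exp(meanlog_vat + 0.5 * z1)
    sat <- exp(meanlog_sat + 0.5 * z2)
    tat <- vat + sat
    z_vat <- as.numeric(scale(log(vat)))
    z_sat <- as.numeric(scale(log(sat)))
    bmi <- pmax(15, 27 + 2.5 * z_sat + 1.0 * z_vat + rnorm(n, 0, 2))
    z_age <- as.numeric(scale(age))

    spec <- effect_spec
    visits <- NULL
    disease <- NULL
    if (!is.null(spec$codes) && nrow(spec$codes) > 0) {
      k <- nrow(spec$codes)
      visits <- matrix(0L, n, k, dimnames = list(ids, spec$codes$code))
      disease <- matrix(FALSE, n, k, dimnames = list(ids, spec$codes$code))
      for (j in seq_len(k)) {
        cs <- spec$codes[j, ]
        eta <- qlogis(cs$base_rate) + log(cs$or_vat) * z_vat +
          log(cs$or_sat) * z_sat + log(cs$or_age) * z_age +
          log(cs$or_sexM) * (sex == "M")
        d <- rbinom(n, 1, plogis(eta)) == 1
        v <- integer(n)
        v[d] <- 2L + rpois(sum(d), 3)
        noisy <- !d & runif(n) > 0.9
        v[noisy] <- 1L + rpois(sum(noisy), 0.5)
        visits[, j] <- v
        disease[, j] <- d
      }
    }

    labs <- NULL
    if (!is.null(spec$labs) && nrow(spec$labs) > 0) {
      labs <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
      for (j in seq_len(nrow(spec$labs))) {
        ls <- spec$labs[j, ]
        labs[[ls$lab]] <- ls$intercept + ls$slope_vat * z_vat +
          ls$slope_sat * z_sat + rnorm(n, 0, ls$noise_sd)
      }
    }

    list(
      adipose = data.frame(subject_id = ids, vat = vat, sat = sat,
                           tat = tat, bmi = bmi, stringsAsFactors = FALSE),
      visits = visits,
      labs = labs,
      covars = data.frame(subject_id = ids, age = age, sex = sex,
                          t2d = as.integer(rbinom(n, 1, 0.294)),
                          stringsAsFactors = FALSE),
      truth = list(effect_spec = spec, seed = as.integer(seed),
                   z_vat = z_vat, z_sat = z_sat, disease = disease,
                   demographics = list(age_mean = 54, age_sd = 17,
                                       p_female = 0.514, rho = rho)))
  })
}
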