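#' Generative truth for a longitudinal lobar cohort
#'
#' Defines the balanced design and generative parameters for a simulated
#' cohort: every subject is seen at baseline and after 3, 12 and 24 months,
#' and contributes one record per visit for each of the six lung regions.
#' Each endpoint follows a mixed model with fixed effects for age, severe
#' air trapping (A3) and the examination time point, plus random intercepts
#' for patient and region-within-patient:
#' `y = b0 + b_age*age + b_A3*A3 + b_t + u_patient + u_region(patient) + e`.
#' Linear-family endpoints add Gaussian noise on the response scale; the
#' beta-family endpoint (wall percentage) applies the linear predictor on
#' the logit of the proportion and draws the response from a beta
#' distribution with precision `phi`.
#'
#' Default coefficient scales mirror the magnitudes of the cross-sectional
#' model fitted at the study design size (36 subjects x 4 visits x 6
#' regions), e.g. age 0.046 on the bronchiectasis index and A3 0.004 on the
#' wall-percentage logit. Baseline age is Uniform(8, 16) years, matching a
#' school-age cohort with median age near 12.
#'
#' @param n_subjects number of subjects (default 36).
#' @param endpoints named list of per-endpoint parameter lists with entries
#'   `family` ("linear" or "beta"), `intercept`, `beta_age`, `beta_A3`,
#'   `beta_tp` (named by the non-baseline months "3", "12", "24"),
#'   `sd_patient`, `sd_region`, and `sd_resid` (linear) or `phi` (beta).
#' @param a3_shape,a3_scale gamma parameters of the positively skewed A3 (%)
#'   distribution (the lobar A3 distribution is configurable, not a claim
#'   about any particular cohort).
#' @param timepoints visit months; the default schedule 0/3/12/24 advances
#'   age by 0, 0.25, 1 and 2 years.
#' @param seed integer seed.
#' @return an object of class `cohort_truth`.
#' @export
cohort_truth <- function(n_subjects = 36,
                         endpoints = default_endpoints(),
                         a3_shape = 1.5, a3_scale = 3,
                         timepoints = c(0, 3, 12, 24),
                         seed = 1L) {
  stopifnot(n_subjects >= 2, length(timepoints) >= 2)
  for (nm in names(endpoints)) {
    ep <- endpoints[[nm]]
    sds <- c(ep$sd_patient, ep$sd_region,
             if (identical(ep$family, "linear")) ep$sd_resid)
    if (any(sds < 0)) stop("random-effect and residual SDs must be >= 0 (",
                           nm, ")", call. = FALSE)
    if (identical(ep$family, "beta") && ep$phi <= 0) {
      stop("beta precision phi must be > 0 (", nm, ")", call. = FALSE)
    }
    need_tp <- setdiff(as.character(timepoints[-1]), names(ep$beta_tp))
    if (length(need_tp)) {
      stop("endpoint ", nm, " lacks timepoint coefficients for: ",
           paste(need_tp, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), endpoints = endpoints,
         a3_shape = a3_shape, a3_scale = a3_scale,
         timepoints = timepoints, seed = as.integer(seed)),
    class = "cohort_truth"
  )
}

#' @rdname cohort_truth
#' @export
default_endpoints <- function() {
  list(
    BEI = list(
      family = "linear", intercept = -0.1, beta_age = 0.046, beta_A3 = 0.003,
      beta_tp = c("3" = 0.019, "12" = 0.015, "24" = 0.006),
      sd_patient = 0.20, sd_region = 0.15, sd_resid = 0.20
    ),
    LA_5_10 = list(
      family = "linear", intercept = 3.0, beta_age = 0.598, beta_A3 = -0.006,
      beta_tp = c("3" = 0.112, "12" = -0.016, "24" = -0.035),
      sd_patient = 1.5, sd_region = 1.0, sd_resid = 1.0
    ),
    WP_5_10 = list(
      family = "beta", intercept = 0.55, beta_age = -0.042, beta_A3 = 0.004,
      beta_tp = c("3" = -0.025, "12" = 0.04, "24" = 0.086),
      sd_patient = 0.15, sd_region = 0.10, phi = 150
    )
  )
}

#' Simulate a balanced longitudinal lobar cohort
#'
#' Draws one record per subject, region and visit from the generative model
#' of a [cohort_truth()]. Age advances deterministically with the visit
#' schedule; A3 (%) is drawn fresh at every record from the configured
#' gamma distribution. The latent fixed-effect linear predictor and the
#' random intercepts of every endpoint are recorded in `.lp_*`, `.u_pat_*`
#' and `.u_reg_*` columns so tests can introspect the generative state.
#'
#' @param truth a [cohort_truth()].
#' @return tibble with `n_subjects * visits * 6` rows: `subject`,
#'   `timepoint_months`, `age_years`, `region`, one column per endpoint
#'   (WP_5_10 in percent), `A3`, and the latent columns.
#' @examples
#' cohort <- simulate_cohort(cohort_truth(n_subjects = 4, seed = 7))
#' nrow(cohort)  # 4 x 4 x 6
#' @export
simulate_cohort <- function(truth) {
  stopifnot(inherits(truth, "cohort_truth"))
  lobes <- names(lobe_labels())
  run <- local_rng(truth$seed)
  run({
    n <- truth$n_subjects
    tps <- truth$timepoints
    subj <- sprintf("S%03d", seq_len(n))
    base_age <- stats::runif(n, 8, 16)
    df <- tidyr::expand_grid(
      subject = subj, timepoint_months = tps, region = lobes
    )
    df$age_years <- base_age[match(df$subject, subj)] + df$timepoint_months / 12
    df$A3 <- stats::rgamma(nrow(df), shape = truth$a3_shape,
                           scale = truth$a3_scale)
    for (nm in names(truth$endpoints)) {
      ep <- truth$endpoints[[nm]]
      u_pat <- stats::setNames(stats::rnorm(n, 0, ep$sd_patient), subj)
      cells <- paste(rep(subj, each = length(lobes)),
                     rep(lobes, times = n), sep = ":")
      u_reg <- stats::setNames(
        stats::rnorm(length(cells), 0, ep$sd_region), cells
      )
      tp_coef <- c("0" = 0, ep$beta_tp)[as.character(df$timepoint_months)]
      lp <- ep$intercept + ep$beta_age * df$age_years + ep$beta_A3 * df$A3 +
        unname(tp_coef)
      up <- unname(u_pat[df$subject])
      ur <- unname(u_reg[paste(df$subject, df$region, sep = ":")])
      eta <- lp + up + ur
      if (identical(ep$family, "linear")) {
        y <- eta + stats::rnorm(nrow(df), 0, ep$sd_resid)
      } else {
        mu <- stats::plogis(eta)
        y <- stats::rbeta(nrow(df), mu * ep$phi, (1 - mu) * ep$phi) * 100
      }
      df[[nm]] <- y
      df[[paste0(".lp_", nm)]] <- lp
      df[[paste0(".u_pat_", nm)]] <- up
      df[[paste0(".u_reg_", nm)]] <- ur
    }
    dplyr::relocate(df, "subject", "timepoint_months", "age_years", "region")
  })
}

#' Write / read a cohort table as CSV
#'
#' The on-disk schema keeps the analysis columns
#' `subject,timepoint_months,age_years,region,BEI,LA_5_10,WP_5_10,A3`;
#' latent `.`-prefixed columns are dropped on write.
#'
#' @param cohort a cohort tibble.
#' @param path CSV path.
#' @return invisibly `path`; `read_cohort_csv()` returns a tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  keep <- !startsWith(names(cohort), ".")
  utils::write.csv(cohort[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
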