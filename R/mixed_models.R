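#' Boundary-shrunk proportion transform
#'
#' Maps a percentage endpoint into the open unit interval for beta-family
#' modelling: `y/100` followed by the usual boundary shrinkage
#' `(p * (n - 1) + 0.5) / n`, which keeps exact 0s and 100s inside (0, 1).
#'
#' @param y_pct values in [0, 100].
#' @param n sample size used for the shrinkage (default `length(y_pct)`).
#' @return values in (0, 1).
#' @export
shrink_proportion <- function(y_pct, n = length(y_pct)) {
  if (any(y_pct < 0 | y_pct > 100, na.rm = TRUE)) {
    stop("percentage endpoint outside [0, 100]", call. = FALSE)
  }
  p <- y_pct / 100
  (p * (n - 1) + 0.5) / n
}

#' Specification of a mixed model for a lobar QCT endpoint
#'
#' @param endpoint response column name.
#' @param family `"linear"` for an identity-link Gaussian mixed model,
#'   `"beta"` for a logit-link beta mixed model (endpoint must be mapped
#'   into (0, 1) before fitting; see [shrink_proportion()]).
#' @param fixed character vector of fixed-effect terms.
#' @param random character vector of random-intercept grouping factors
#'   (default patient and region-within-patient).
#' @param robust if `TRUE` (default), iterate Huber weights (c = 1.345) on
#'   scaled residuals to REML/ML convergence; plain fits with `FALSE`.
#' @param huber_c Huber tuning constant.
#' @return an object of class `qct_model_spec`.
#' @export
qct_model_spec <- function(endpoint, family = c("linear", "beta"),
                           fixed = c("age_years", "A3", "timepoint"),
                           random = c("subject", "subject:region"),
                           robust = TRUE, huber_c = 1.345) {
  structure(
    list(endpoint = endpoint, family = match.arg(family), fixed = fixed,
         random = random, robust = robust, huber_c = huber_c),
    class = "qct_model_spec"
  )
}

fit_formula <- function(spec) {
  stats::as.formula(paste(
    ".y ~", paste(spec$fixed, collapse = " + "), "+",
    paste(sprintf("(1 | `%s`)", spec$random), collapse = " + ")
  ))
}

huber_weights <- function(resid, c_tune) {
  s <- stats::mad(resid, center = 0)
  if (s <= 0) return(rep(1, length(resid)))
  u <- abs(resid / s)
  ifelse(u <= c_tune, 1, c_tune / u)
}

#' Fit a (robust) linear or beta mixed model
#'
#' Linear family: a random-intercept Gaussian mixed model fit by REML
#' (lme4). Beta family: a logit-link beta mixed model with Laplace-
#' approximated random intercepts (glmmTMB). With `robust = TRUE` the fit
#' is re-estimated under Huber weights (c = 1.345) computed from scaled
#' (Pearson) residuals, iterated until the fixed effects stabilize — a
#' robustness scheme that downweights outlying lobe-visit records instead
#' of discarding them. Wald standard errors are reported with 95%
#' confidence intervals and P-values on Satterthwaite denominator degrees
#' of freedom for the linear family (normal reference for the beta family);
#' all P-values are descriptive (no multiplicity correction inside model
#' reports). Non-convergence is reported, never
#' silently worked around; variance components estimated at the boundary
#' are flagged as singular.
#'
#' @param data a data frame containing the endpoint, the fixed-effect
#'   columns and the grouping factors.
#' @param spec a [qct_model_spec()].
#' @return an object of class `qct_fit`; see [tidy.qct_fit()].
#' @export
fit_mixed <- function(data, spec) {
  stopifnot(inherits(spec, "qct_model_spec"))
  dd <- tibble::as_tibble(data)
  if (!spec$endpoint %in% names(dd)) {
    stop("endpoint column not found: ", spec$endpoint, call. = FALSE)
  }
  for (g in spec$random) {
    parts <- strsplit(g, ":", fixed = TRUE)[[1]]
    missing_parts <- setdiff(parts, names(dd))
    if (length(missing_parts)) {
      stop("grouping column(s) missing: ", paste(missing_parts, collapse = ", "),
           call. = FALSE)
    }
    dd[[g]] <- interaction(dd[parts], drop = TRUE)
  }
  dd$.y <- dd[[spec$endpoint]]
  if (stats::sd(dd$.y, na.rm = TRUE) == 0) {
    stop("endpoint has zero variance", call. = FALSE)
  }
  if (identical(spec$family, "beta") &&
      (any(dd$.y <= 0, na.rm = TRUE) || any(dd$.y >= 1, na.rm = TRUE))) {
    stop("beta family needs a response strictly inside (0, 1); ",
         "map percentages with shrink_proportion() first", call. = FALSE)
  }
  form <- fit_formula(spec)
  dd$.w <- rep(1, nrow(dd))
  fit_once <- function(dd) {
    if (identical(spec$family, "linear")) {
      lme4::lmer(form, data = dd, weights = .w, REML = TRUE,
                 control = lme4::lmerControl(optimizer = "bobyqa",
                                             check.conv.singular = "ignore",
                                             # one record per patient-region
                                             # cell is legitimate in the
                                             # two-visit longitudinal design;
                                             # the cell variance then sits at
                                             # the boundary and is flagged
                                             check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.nRE = "ignore"))
    } else {
      glmmTMB::glmmTMB(form, data = dd, weights = .w,
                       family = glmmTMB::beta_family(link = "logit"))
    }
  }
  fixef_of <- function(fit) {
    if (identical(spec$family, "linear")) lme4::fixef(fit)
    else glmmTMB::fixef(fit)$cond
  }
  fit <- fit_once(dd)
  n_iter <- 0L
  if (isTRUE(spec$robust)) {
    for (it in 1:12) {
      r <- stats::residuals(fit, type = "pearson")
      w_new <- huber_weights(r, spec$huber_c)
      old <- fixef_of(fit)
      dd$.w <- w_new
      fit_new <- fit_once(dd)
      n_iter <- it
      delta <- max(abs(fixef_of(fit_new) - old) /
                     pmax(abs(old), 1e-4))
      fit <- fit_new
      if (delta < 1e-4) break
    }
  }
  # convergence / singularity diagnostics
  if (identical(spec$family, "linear")) {
    singular <- lme4::isSingular(fit, tol = 1e-5)
    msgs <- unlist(fit@optinfo$conv$lme4$messages)
    converged <- is.null(fit@optinfo$conv$lme4$code) ||
      fit@optinfo$conv$lme4$code == 0
    est <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    # Satterthwaite denominator df: Wald-normal intervals are anti-
    # conservative for between-patient effects at cohort-sized cluster counts
    ddf <- tryCatch({
      sm <- summary(lmerTest::as_lmerModLmerTest(fit))$coefficients
      sm[match(names(est), rownames(sm)), "df"]
    }, error = function(e) rep(Inf, length(est)))
    ddf[!is.finite(ddf) | ddf <= 0] <- Inf
  } else {
    converged <- isTRUE(fit$fit$convergence == 0) || is.null(fit$fit$convergence)
    sdre <- sqrt(unlist(lapply(glmmTMB::VarCorr(fit)$cond, function(m) diag(m))))
    singular <- any(sdre < 1e-4)
    msgs <- NULL
    est <- glmmTMB::fixef(fit)$cond
    vc <- tryCatch({
      v <- glmmTMB::VarCorr(fit)$cond
      data.frame(grp = names(v),
                 sdcor = vapply(v, function(m) sqrt(diag(m)[1]), numeric(1)))
    }, error = function(e) NULL)
    se <- sqrt(diag(as.matrix(stats::vcov(fit)$cond)))
    ddf <- rep(Inf, length(est))
  }
  if (!converged) {
    warning("mixed-model optimizer reported non-convergence; ",
            "estimates are returned with converged = FALSE", call. = FALSE)
  }
  z <- est / se
  crit <- ifelse(is.finite(ddf), stats::qt(0.975, ddf), stats::qnorm(0.975))
  coefs <- tibble::tibble(
    term = names(est), estimate = unname(est), std_error = unname(se),
    df = unname(ddf),
    ci_lo = unname(est - crit * se),
    ci_hi = unname(est + crit * se),
    p_value = unname(ifelse(is.finite(ddf), 2 * stats::pt(-abs(z), ddf),
                            2 * stats::pnorm(-abs(z))))
  )
  structure(
    list(
      model = fit, spec = spec,
      formula = paste(spec$endpoint, "~",
                      paste(spec$fixed, collapse = " + "), "+",
                      paste(sprintf("(1 | %s)", spec$random), collapse = " + ")),
      scale = if (identical(spec$family, "beta"))
        "logit of the proportion (beta family)" else "response scale",
      coefs = coefs, varcomp = vc, n_obs = nrow(dd),
      robust_iterations = n_iter, converged = converged, singular = singular,
      optimizer_messages = msgs
    ),
    class = "qct_fit"
  )
}

#' @export
print.qct_fit <- function(x, ...) {
  cat("Mixed-effects model fit (", x$spec$family, " family",
      if (x$spec$robust) ", Huber-robust", ")\n", sep = "")
  cat("  formula:", x$formula, "\n")
  cat("  coefficient scale:", x$scale, "\n")
  cat("  n =", x$n_obs,
      if (x$singular) " [singular variance component(s)]", "\n")
  tab <- x$coefs
  cat(sprintf("  %-14s %9s  (%8s - %8s) %8s %8s\n",
              "term", "EstE", "LL", "UL", "SE", "P"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-14s %9.4g  (%8.4g - %8.4g) %8.3g %8.3g\n",
                tab$term[i], tab$estimate[i], tab$ci_lo[i], tab$ci_hi[i],
                tab$std_error[i], tab$p_value[i]))
  }
  cat("  (all P-values are descriptive)\n")
  invisible(x)
}

#' Tidy and glance methods for mixed-model fits
#'
#' `tidy()` returns one row per fixed effect with estimate, Wald SE, 95%
#' confidence limits and P-value; `glance()` returns one-row fit-level
#' diagnostics.
#'
#' @param x a `qct_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.qct_fit <- function(x, ...) {
  dplyr::mutate(x$coefs, endpoint = x$spec$endpoint, .before = 1)
}

#' @rdname tidy.qct_fit
#' @export
glance.qct_fit <- function(x, ...) {
  tibble::tibble(
    endpoint = x$spec$endpoint, family = x$spec$family,
    robust = x$spec$robust, n_obs = x$n_obs,
    converged = x$converged, singular = x$singular,
    robust_iterations = x$robust_iterations
  )
}

#' Cross-sectional mixed model linking airway endpoints to air trapping
#'
#' Fits `endpoint ~ age + A3 + timepoint + (1 | patient) +
#' (1 | region within patient)` over all visits stacked, the structure used
#' to relate regional airway geometry to severe air trapping at single time
#' points. The wall-percentage endpoint uses the beta family on the logit
#' of the shrunk proportion; the bronchiectasis index and lumen area use
#' the linear family.
#'
#' @param data a cohort table (see [simulate_cohort()]): columns `subject`,
#'   `timepoint_months`, `age_years`, `region`, `A3` and the endpoint.
#' @param endpoint one of the endpoint columns, e.g. `"BEI"`, `"LA_5_10"`,
#'   `"WP_5_10"`.
#' @param family `NULL` for the convention above, or `"linear"`/`"beta"`.
#' @param robust passed to [qct_model_spec()].
#' @return a `qct_fit`.
#' @export
crosssectional_model <- function(data, endpoint, family = NULL, robust = TRUE) {
  dd <- tibble::as_tibble(data)
  req <- c("subject", "timepoint_months", "age_years", "region", "A3", endpoint)
  miss <- setdiff(req, names(dd))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (is.null(family)) {
    family <- if (identical(endpoint, "WP_5_10")) "beta" else "linear"
  }
  tps <- sort(unique(dd$timepoint_months))
  dd$timepoint <- factor(dd$timepoint_months, levels = tps)
  yname <- endpoint
  if (identical(family, "beta")) {
    yname <- paste0(".", endpoint, "_01")
    dd[[yname]] <- shrink_proportion(dd[[endpoint]], n = nrow(dd))
  }
  spec <- qct_model_spec(yname, family = family,
                         fixed = c("age_years", "A3", "timepoint"),
                         random = c("subject", "subject:region"),
                         robust = robust)
  out <- fit_mixed(dd, spec)
  out$spec$endpoint <- endpoint
  out$coefs <- dplyr::mutate(out$coefs, endpoint = endpoint, .before = 1)
  out$formula <- sub("^\\.\\S+ ~", paste(endpoint, "~"), out$formula)
  out
}

#' Longitudinal mixed model between two visits
#'
#' For an interval (t0, t1) the endpoint at the later visit is regressed on
#' age, A3 and the endpoint itself at the earlier visit, with patient and
#' region-within-patient random intercepts:
#' `y(t1) ~ age(t0) + A3(t0) + y(t0) + (1 | patient) + (1 | patient:region)`.
#' The baseline-endpoint coefficient measures tracking: values near 1 mean
#' the regional pattern persists unchanged over the interval. Subject-region
#' cells missing either visit are dropped and counted.
#'
#' @inheritParams crosssectional_model
#' @param interval numeric length 2: the two visit months, e.g. `c(0, 3)`
#'   or `c(0, 24)`.
#' @return a `qct_fit` with attribute `n_dropped` (incomplete cells).
#' @export
longitudinal_model <- function(data, endpoint, interval = c(0, 3),
                               family = NULL, robust = TRUE) {
  dd <- tibble::as_tibble(data)
  req <- c("subject", "timepoint_months", "age_years", "region", "A3", endpoint)
  miss <- setdiff(req, names(dd))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  if (is.null(family)) {
    family <- if (identical(endpoint, "WP_5_10")) "beta" else "linear"
  }
  t0 <- dd[dd$timepoint_months == interval[1],
           c("subject", "region", "age_years", "A3", endpoint)]
  t1 <- dd[dd$timepoint_months == interval[2],
           c("subject", "region", endpoint)]
  names(t0)[names(t0) == endpoint] <- "baseline_endpoint"
  names(t0)[names(t0) == "age_years"] <- "age_years"
  names(t1)[names(t1) == endpoint] <- ".y1"
  both <- dplyr::inner_join(t0, t1, by = c("subject", "region"))
  n_dropped <- nrow(t0) + nrow(t1) - 2L * nrow(both)
  if (nrow(both) == 0L) {
    stop("no subject-region cells have both visits ", interval[1], " and ",
         interval[2], call. = FALSE)
  }
  yname <- ".y1"
  if (identical(family, "beta")) {
    both$.y1 <- shrink_proportion(both$.y1, n = nrow(both))
    both$baseline_endpoint <- both$baseline_endpoint / 100
  }
  spec <- qct_model_spec(yname, family = family,
                         fixed = c("age_years", "A3", "baseline_endpoint"),
                         random = c("subject", "subject:region"),
                         robust = robust)
  out <- fit_mixed(both, spec)
  out$spec$endpoint <- endpoint
  out$coefs <- dplyr::mutate(out$coefs, endpoint = endpoint,
                             interval = paste(interval, collapse = "-"),
                             .before = 1)
  out$formula <- paste0(endpoint, "(t=", interval[2], ") ~ age_years + A3 + ",
                        endpoint, "(t=", interval[1],
                        ") + (1 | subject) + (1 | subject:region)")
  attr(out, "n_dropped") <- n_dropped
  out
}
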