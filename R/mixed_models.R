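# Linear mixed-effects stage: treatment comparisons with device/root random
# intercepts (oxygen-gradient experiment) and growth-rate / light-dark
# models of O2 minima (timelapse experiment), with Nakagawa-style marginal
# and conditional R2 variance partitioning.

#' Specify a mixed-effects model
#'
#' @param response Response column name.
#' @param fixed_terms Character vector of fixed-effect terms (R formula
#'   syntax, e.g. `c("growth_rate", "treatment", "period",
#'   "treatment:period")`); empty for an intercept-only model.
#' @param random_intercepts Character vector of grouping factors receiving
#'   independent random intercepts (e.g. `c("device", "device:root")` for
#'   roots nested in devices); empty for ordinary least squares.
#' @param transform `"none"` or `"log"` (natural log of the response, for
#'   right-skewed length metrics).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(response, fixed_terms = character(),
                       random_intercepts = character(),
                       transform = c("none", "log")) {
  transform <- match.arg(transform)
  structure(list(response = response, fixed_terms = fixed_terms,
                 random_intercepts = random_intercepts, transform = transform),
            class = "model_spec")
}

.spec_formula <- function(spec, resp_name) {
  rhs <- if (length(spec$fixed_terms)) paste(spec$fixed_terms, collapse = " + ") else "1"
  re <- if (length(spec$random_intercepts))
    paste(sprintf("(1 | %s)", spec$random_intercepts), collapse = " + ")
  else ""
  stats::as.formula(paste(resp_name, "~", rhs,
                          if (nzchar(re)) paste("+", re) else ""))
}

# reference levels follow the study's contrasts: Sterile and light first
.prepare_factors <- function(data) {
  if ("treatment" %in% names(data) && !is.factor(data$treatment)) {
    lev <- unique(data$treatment)
    pref <- c("Sterile", setdiff(sort(lev), "Sterile"))
    data$treatment <- factor(data$treatment, levels = pref[pref %in% lev])
  }
  if ("period" %in% names(data) && !is.factor(data$period)) {
    lev <- unique(data$period)
    pref <- c("light", setdiff(sort(lev), "light"))
    data$period <- factor(data$period, levels = pref[pref %in% lev])
  }
  data
}

#' Fit a linear mixed-effects model from a specification
#'
#' Restricted-maximum-likelihood fit (via `lme4::lmer`) of the specified
#' fixed effects with independent random intercepts. Reports fixed-effect
#' estimates and SEs, Wald t statistics with residual degrees of freedom,
#' variance components, and marginal/conditional R2. With no random terms
#' the model reduces to ordinary least squares. Singular or non-converged
#' fits are flagged on the returned object, never silently accepted.
#'
#' @param data Tidy data.frame holding the response, fixed-effect and
#'   grouping columns.
#' @param spec A `model_spec`.
#' @return Object of class `model_fit`: `estimates` (data.frame with
#'   term/estimate/se/t/df/p/stars), `variance_components` (named vector
#'   including `residual`), `r2_marginal`, `r2_conditional`, `converged`,
#'   `singular`, plus the underlying fitted model.
#' @export
fit_lmm <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  need <- unique(c(spec$response,
                   all.vars(stats::as.formula(paste(
                     "~", paste(c("1", spec$fixed_terms), collapse = "+")))),
                   unlist(strsplit(spec$random_intercepts, ":", fixed = TRUE))))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(data[[spec$response]])))
    stop("response contains non-finite values")
  data <- .prepare_factors(data)
  resp <- ".rhizO2_y"
  data[[resp]] <- if (spec$transform == "log") {
    if (any(data[[spec$response]] <= 0))
      stop("log transform requires a strictly positive response")
    log(data[[spec$response]])
  } else data[[spec$response]]
  for (g in spec$random_intercepts) {
    cols <- strsplit(g, ":", fixed = TRUE)[[1L]]
    glev <- interaction(data[cols], drop = TRUE)
    if (nlevels(glev) < 2L)
      stop("random factor ", g, " has fewer than 2 groups")
  }
  form <- .spec_formula(spec, resp)

  if (length(spec$random_intercepts) == 0L) {
    fit <- stats::lm(form, data = data)
    X <- stats::model.matrix(fit)
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    df <- stats::df.residual(fit)
    vc <- c(residual = stats::sigma(fit)^2)
    fixed_pred <- drop(X %*% beta)
    converged <- TRUE; singular <- FALSE
    model <- fit
  } else {
    ctrl <- lme4::lmerControl(optCtrl = list(xtol_abs = 1e-8, ftol_abs = 1e-8,
                                             maxeval = 500))
    warn <- character()
    model <- withCallingHandlers(
      lme4::lmer(form, data = data, REML = TRUE, control = ctrl),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    beta <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
    df <- nrow(data) - length(beta)
    vcd <- as.data.frame(lme4::VarCorr(model))
    vc <- stats::setNames(vcd$vcov, ifelse(vcd$grp == "Residual", "residual", vcd$grp))
    X <- lme4::getME(model, "X")
    fixed_pred <- drop(X %*% beta)
    singular <- lme4::isSingular(model, tol = 1e-6)
    converged <- length(warn) == 0L
  }

  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  stars <- cut(pval, c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  var_fixed <- stats::var(fixed_pred)
  var_random <- sum(vc[names(vc) != "residual"])
  var_resid <- unname(vc["residual"])
  denom <- var_fixed + var_random + var_resid
  if (denom <= 0) stop("zero total variance; R2 undefined")
  structure(list(
    estimates = data.frame(term = names(beta), estimate = unname(beta),
                           se = unname(se), t = unname(tstat), df = df,
                           p = unname(pval), stars = as.character(stars),
                           stringsAsFactors = FALSE),
    variance_components = vc,
    var_fixed = var_fixed,
    r2_marginal = var_fixed / denom,
    r2_conditional = (var_fixed + var_random) / denom,
    converged = converged, singular = singular,
    spec = spec, n = nrow(data), model = model),
    class = "model_fit")
}

#' Marginal and conditional R2 of a mixed-model fit
#'
#' Variance partition in the Nakagawa sense: the marginal R2 is the variance
#' of the fixed-effect predictions over the total (fixed + random + residual)
#' variance; the conditional R2 adds the random-intercept variances to the
#' numerator.
#'
#' @param fit A `model_fit`.
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
r2_variance_partition <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  c(r2_marginal = fit$r2_marginal, r2_conditional = fit$r2_conditional)
}

#' Simple linear regression of O2 minima on growth rate
#'
#' Ordinary least squares of `y` on `x`, used for the per-panel growth-rate
#' versus O2-minimum relationship.
#'
#' @param x Growth rates (um/h); must not be constant.
#' @param y O2 minima (mg l-1).
#' @return List: `slope`, `intercept`, `r_squared`, `n`.
#' @export
simple_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 points")
  if (stats::var(x) == 0) stop("constant x: regression undefined")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits; the R^2 of 1 is still well defined
  r2 <- if (stats::var(y) == 0) 0 else
    suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2, n = length(x))
}

#' Model specifications for the oxygen-gradient experiment
#'
#' Six response metrics (longitudinal mature-zone O2, longitudinal hypoxic
#' and suboxic lengths, transverse hypoxic and suboxic lengths, transverse
#' maximum decrease), each with treatment as the fixed effect and random
#' intercepts for device and root nested in device.
#'
#' @return Named list of six `model_spec`s.
#' @export
build_exp1_specs <- function() {
  responses <- c("long_mean_mature_o2", "long_hypoxic_length",
                 "long_suboxic_length", "trans_hypoxic_length",
                 "trans_suboxic_length", "trans_max_decrease")
  out <- lapply(responses, function(r)
    model_spec(r, fixed_terms = "treatment",
               random_intercepts = c("device", "device:root")))
  stats::setNames(out, responses)
}

#' Model specifications for the timelapse experiment
#'
#' Model 1: O2 minimum on growth rate. Model 2: growth rate, treatment,
#' light/dark period and the treatment-by-period interaction. Both use a
#' random intercept per root nested within treatment.
#'
#' @return Named list of two `model_spec`s (`model1`, `model2`).
#' @export
build_exp2_specs <- function() {
  list(
    model1 = model_spec("o2_min", fixed_terms = "growth_rate",
                        random_intercepts = "treatment:root_id"),
    model2 = model_spec("o2_min",
                        fixed_terms = c("growth_rate", "treatment", "period",
                                        "treatment:period"),
                        random_intercepts = "treatment:root_id"))
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model: %s ~ %s\n", x$spec$response,
              if (length(x$spec$fixed_terms)) paste(x$spec$fixed_terms, collapse = " + ") else "1"))
  if (length(x$spec$random_intercepts))
    cat("  random intercepts:", paste(x$spec$random_intercepts, collapse = ", "), "\n")
  cat(sprintf("  n = %d, R2m = %.3f, R2c = %.3f%s%s\n", x$n,
              x$r2_marginal, x$r2_conditional,
              if (!x$converged) " [convergence warning]" else "",
              if (x$singular) " [singular fit]" else ""))
  est <- x$estimates
  est$estimate <- signif(est$estimate, 4)
  est$se <- signif(est$se, 4)
  est$p <- signif(est$p, 3)
  print(est[, c("term", "estimate", "se", "p", "stars")], row.names = FALSE)
  invisible(x)
}

#' Tidy fit report for a list of model fits
#'
#' One row per fixed-effect term per model, mirroring a results table
#' (estimate, SE, significance stars, marginal and conditional R2).
#'
#' @param fits Named list of `model_fit`s.
#' @return data.frame.
#' @export
fit_report <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    cbind(model = nm, f$estimates[, c("term", "estimate", "se", "p", "stars")],
          r2_marginal = f$r2_marginal, r2_conditional = f$r2_conditional,
          converged = f$converged, singular = f$singular)
  }))
}
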