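#' Environmental descriptor dictionaries
#'
#' The reference-condition models use eight environmental descriptors per
#' site: upstream catchment area (km2), river slope (per mille), river width
#' (m), mean annual air temperature at the site and over the catchment
#' (degrees C), annual rainfall over the catchment (mm), hydrological regime
#' and dominant sediment (categoricals with declared levels).
#'
#' @return A list with the categorical level dictionaries.
#' @export
env_dictionaries <- function() {
  list(regime = c("pluvial", "pluvio-nival", "nival"),
       sediment = c("gravel", "sand", "silt"))
}

env_numeric_vars <- c("area_km2", "slope_pm", "width_m",
                      "temp_site_c", "temp_catch_c", "rainfall_mm")

#' Validate an environmental-descriptor table
#'
#' @param env A data frame with columns `site`, the six numeric descriptors
#'   (`area_km2`, `slope_pm`, `width_m`, `temp_site_c`, `temp_catch_c`,
#'   `rainfall_mm`) and the two categoricals (`regime`, `sediment`).
#' @return `env` as a tibble; errors on domain violations.
#' @export
validate_env_descriptors <- function(env) {
  env <- as_tibble(env)
  need <- c("site", env_numeric_vars, "regime", "sediment")
  missing_cols <- setdiff(need, names(env))
  if (length(missing_cols) > 0) {
    abort(paste0("Environmental table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(env$area_km2 <= 0) || any(env$width_m <= 0)) {
    abort("Catchment area and river width must be positive.")
  }
  if (any(env$slope_pm < 0)) abort("River slope must be non-negative.")
  dict <- env_dictionaries()
  if (!all(env$regime %in% dict$regime)) {
    abort(paste0("Unknown regime level(s); allowed: ",
                 paste(dict$regime, collapse = ", ")))
  }
  if (!all(env$sediment %in% dict$sediment)) {
    abort(paste0("Unknown sediment level(s); allowed: ",
                 paste(dict$sediment, collapse = ", ")))
  }
  env
}

# Fixed standardisation constants for the encoded design. Centres/scales are
# declared (not data-dependent) so coefficient vectors are comparable across
# datasets and between the generator and the fitter.
env_encoding <- list(
  log_area = list(var = "area_km2", log = TRUE, centre = 7, scale = 2),
  log_slope = list(var = "slope_pm", log = TRUE, centre = 0.7, scale = 1.5),
  log_width = list(var = "width_m", log = TRUE, centre = 3.3, scale = 0.9),
  z_temp_site = list(var = "temp_site_c", log = FALSE, centre = 11, scale = 1.7),
  z_temp_catch = list(var = "temp_catch_c", log = FALSE, centre = 10, scale = 1.7),
  z_rainfall = list(var = "rainfall_mm", log = FALSE, centre = 1200, scale = 350)
)

#' Encoded design matrix for the eight environmental descriptors
#'
#' Numeric descriptors are log-transformed where their natural spread is
#' multiplicative (area, slope, width) and standardised with fixed declared
#' constants; the two categoricals are dummy-encoded against their first
#' dictionary level. The same encoding is used by the reference-model fitter
#' and by the synthetic-data generator.
#'
#' @param env A validated environmental-descriptor table.
#' @return A numeric matrix with an intercept column, one row per site.
#' @export
env_model_matrix <- function(env) {
  env <- validate_env_descriptors(env)
  dict <- env_dictionaries()
  num <- vapply(env_encoding, function(e) {
    v <- env[[e$var]]
    if (e$log) v <- log(pmax(v, .Machine$double.eps))
    (v - e$centre) / e$scale
  }, numeric(nrow(env)))
  num <- matrix(num, nrow = nrow(env),
                dimnames = list(NULL, names(env_encoding)))
  fac <- data.frame(
    regime = factor(env$regime, levels = dict$regime),
    sediment = factor(env$sediment, levels = dict$sediment)
  )
  dummies <- model.matrix(~ regime + sediment, fac)[, -1, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, num, dummies)
  rownames(X) <- env$site
  X
}

empirical_logit <- function(p, eps = 0.005) qlogis(pmin(pmax(p, eps), 1 - eps))
count_link <- function(x) log(x + 0.5)

#' Fit reference-condition models for the index metrics
#'
#' For each index metric, fits a model of the metric's expected value in
#' least-disturbed reference conditions as a function of the eight
#' environmental descriptors: a Poisson log-link GLM for species-count
#' metrics and a Gaussian regression on the empirical-logit scale for
#' relative metrics. The residual spread `sigma` on the link scale
#' (log(x + 0.5) for counts, empirical logit for proportions) is stored per
#' metric and later standardises observed-vs-expected departures into EQRs.
#' A metric that is constant across reference sites is flagged `degenerate`
#' (its near-zero sigma cannot standardise departures meaningfully).
#'
#' @param ref_data A data frame of reference sites carrying the
#'   environmental-descriptor columns plus one column per metric.
#' @param registry Metric registry ([index_metric_registry()] by default);
#'   rows define metric name, unit and disturbance orientation.
#' @return An object of class `ref_model_set`: per-metric family,
#'   coefficients, `sigma`, orientation, deviance and degeneracy flag.
#' @export
fit_reference_models <- function(ref_data, registry = index_metric_registry()) {
  ref_data <- as_tibble(ref_data)
  missing_m <- setdiff(registry$metric, names(ref_data))
  if (length(missing_m) > 0) {
    abort(paste0("Reference data lacks metric column(s): ",
                 paste(missing_m, collapse = ", ")))
  }
  X <- env_model_matrix(ref_data)
  p <- ncol(X)
  n <- nrow(X)
  if (n < 10 * p) {
    abort(sprintf(
      "Under-determined reference fit: %d sites for %d encoded predictors (need >= %d).",
      n, p, 10 * p))
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    abort(paste0("Singular design; collinear descriptor column(s): ",
                 paste(dropped, collapse = ", ")))
  }

  models <- purrr::pmap(registry, function(metric, guild, unit, orientation) {
    y <- ref_data[[metric]]
    if (unit == "n-species") {
      if (any(y < 0) || any(y != round(y))) {
        abort(sprintf("Metric '%s' must be non-negative integer counts.", metric))
      }
      fit <- glm(y ~ X - 1, family = poisson())
      beta <- setNames(coef(fit), colnames(X))
      mu <- as.vector(exp(X %*% beta))
      resid_link <- count_link(y) - count_link(mu)
      dev <- fit$deviance
      family <- "count-log"
      se <- sqrt(diag(vcov(fit)))
    } else {
      if (any(y < 0) || any(y > 1)) {
        abort(sprintf("Metric '%s' must be a proportion in [0, 1].", metric))
      }
      yl <- empirical_logit(y)
      fit <- lm(yl ~ X - 1)
      beta <- setNames(coef(fit), colnames(X))
      resid_link <- as.vector(yl - X %*% beta)
      dev <- sum(resid_link^2)
      family <- "proportion-logit"
      se <- sqrt(diag(vcov(fit)))
    }
    sigma <- sd(resid_link)
    list(metric = metric, guild = guild, unit = unit,
         orientation = orientation, family = family,
         coefficients = beta, se = setNames(se, colnames(X)),
         sigma = sigma, deviance = dev,
         degenerate = !is.finite(sigma) || sigma < 1e-8)
  })
  names(models) <- registry$metric
  degen <- registry$metric[vapply(models, `[[`, logical(1), "degenerate")]
  if (length(degen) > 0) {
    warn(paste0("Degenerate (constant) metric fit(s): ",
                paste(degen, collapse = ", ")))
  }
  structure(list(models = models, predictors = colnames(X),
                 n_sites = n, registry = registry),
            class = "ref_model_set")
}

#' @export
print.ref_model_set <- function(x, ...) {
  cat("Reference-condition model set:", length(x$models), "metric(s),",
      x$n_sites, "reference sites,", length(x$predictors),
      "encoded predictors\n")
  print(glance(x))
  invisible(x)
}

#' @export
tidy.ref_model_set <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    tibble(metric = m$metric, term = names(m$coefficients),
           estimate = unname(m$coefficients), std_error = unname(m$se))
  })
}

#' @export
glance.ref_model_set <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    tibble(metric = m$metric, family = m$family, unit = m$unit,
           orientation = m$orientation, sigma = m$sigma,
           deviance = m$deviance, degenerate = m$degenerate)
  })
}

#' Expected metric value under reference conditions
#'
#' @param models A `ref_model_set`.
#' @param metric Metric name.
#' @param env One-or-more-row environmental table.
#' @return Expected metric value(s) on the response scale.
#' @export
predict_reference <- function(models, metric, env) {
  m <- models$models[[metric]]
  if (is.null(m)) abort(sprintf("No reference model for metric '%s'.", metric))
  X <- env_model_matrix(env)
  eta <- as.vector(X %*% m$coefficients)
  if (m$family == "count-log") exp(eta) else plogis(eta)
}

#' Ecological quality ratio for one metric
#'
#' Standardises the observed metric against its reference expectation:
#' `z = (link(observed) - link(expected)) / sigma`, with the count link
#' `log(x + 0.5)` and the proportion link the empirical logit. The EQR is
#' the probability transform of `z`, oriented so that departure in the
#' disturbance direction lowers the score: `Phi(z)` for metrics that
#' decrease with disturbance and `1 - Phi(z)` for metrics that increase.
#' Values are clipped to `[0.001, 0.999]`. An observation exactly at its
#' expectation scores 0.5.
#'
#' @param observed Observed metric value (count or proportion).
#' @param expected Expected value under reference conditions (response
#'   scale); usually from [predict_reference()].
#' @param sigma Link-scale residual spread of the reference fit.
#' @param orientation `"increases"` or `"decreases"` (with disturbance).
#' @param unit Metric unit (decides the link transform).
#' @return EQR value(s) in `[0.001, 0.999]`.
#' @export
#' @examples
#' compute_eqr(0.2, 0.2, sigma = 0.5, orientation = "decreases",
#'             unit = "rel-individuals") # 0.5
compute_eqr <- function(observed, expected, sigma,
                        orientation = c("decreases", "increases"),
                        unit = metric_units()) {
  orientation <- arg_match(orientation)
  unit <- arg_match(unit)
  if (unit == "n-species") {
    if (any(observed < 0)) abort("Count metrics must be non-negative.")
    z <- (count_link(observed) - count_link(expected)) / sigma
  } else {
    if (any(observed < 0 | observed > 1)) {
      abort("Relative metrics must lie in [0, 1].")
    }
    z <- (empirical_logit(observed) - empirical_logit(expected)) / sigma
  }
  z[observed == expected] <- 0  # exact agreement scores 0.5 even if sigma ~ 0
  eqr <- if (orientation == "decreases") pnorm(z) else 1 - pnorm(z)
  pmin(pmax(eqr, 0.001), 0.999)
}
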