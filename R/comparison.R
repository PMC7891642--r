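#' Round half up
#'
#' Decimal rounding with halves away from zero (printed-table convention),
#' unlike base `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimals to keep.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  q <- 10^digits
  sign(x) * floor(abs(x) * q + 0.5) / q
}

#' Summarise a review table of assessment-method metrics
#'
#' Derives the headline counts and percentage shares from a metric-type by
#' unit review table: totals per unit, the trait-based share (the five guild
#' rows), the taxonomy-based share, per-guild-family shares of the
#' trait-based metrics, and the eDNA-compatibility share (metrics expressed
#' in species richness or relative abundance, the units computable from eDNA
#' samples). Percentages are reported to one decimal, rounded half up, and
#' always recomputed from the counts.
#'
#' @param review A review tibble (`metric_type`, `unit`, `n`), e.g.
#'   [load_table1_fixture()].
#' @return An object of class `review_summary`.
#' @export
#' @examples
#' summarize_review(load_table1_fixture())
summarize_review <- function(review) {
  review <- validate_review_table(review)
  total <- sum(review$n)
  pct <- function(n, denom = total) round_half_up(100 * n / denom, 1)

  unit_summary <- review %>%
    group_by(.data$unit) %>%
    summarise(n = sum(.data$n), .groups = "drop") %>%
    mutate(share_pct = pct(.data$n)) %>%
    arrange(desc(.data$n))

  unit_n <- setNames(unit_summary$n, unit_summary$unit)
  unit_count <- function(nm) {
    v <- unname(unit_n[nm])
    ifelse(is.na(v), 0, v)
  }
  richness <- unit_count("Species richness")
  relabund <- unit_count("Relative abundance")
  relbio <- unit_count("Relative biomass")

  trait_tbl <- filter(review, .data$metric_type %in% trait_based_types)
  trait_n <- sum(trait_tbl$n)
  guild_family_shares <- trait_tbl %>%
    group_by(.data$metric_type) %>%
    summarise(n = sum(.data$n), .groups = "drop") %>%
    mutate(pct_of_trait_based = pct(.data$n, trait_n))

  taxo_n <- sum(review$n[review$metric_type == "Taxonomy-based metrics"])
  compat_n <- richness + relabund

  structure(list(
    total = total,
    unit_summary = unit_summary,
    relative_units_n = unname(richness + relabund + relbio),
    trait_based = list(n = trait_n, pct = pct(trait_n)),
    taxonomy_based = list(n = taxo_n, pct = pct(taxo_n)),
    guild_family_shares = guild_family_shares,
    compatibility = list(n = unname(compat_n), pct = pct(compat_n),
                         pct_rounded = round_half_up(100 * compat_n / total, 0))
  ), class = "review_summary")
}

#' @export
print.review_summary <- function(x, ...) {
  cat("Review of", x$total, "assessment metrics\n")
  cat(sprintf("  trait-based: %d (%.1f%%); taxonomy-based: %d (%.1f%%)\n",
              x$trait_based$n, x$trait_based$pct,
              x$taxonomy_based$n, x$taxonomy_based$pct))
  cat(sprintf("  eDNA-compatible (richness + relative abundance): %d (%.0f%%)\n",
              x$compatibility$n, x$compatibility$pct_rounded))
  print(x$unit_summary)
  invisible(x)
}

#' Compare a metric between sampling methods with a GLM
#'
#' Tests the method effect (eDNA vs electrofishing) on a metric after
#' accounting for the river-stretch effect. Species-count metrics use a
#' Poisson log-link GLM; metrics based on numbers of individuals use a
#' negative binomial GLM with `log(total individuals)` as offset to control
#' for sample size. Residual deviance is reported as the goodness-of-fit
#' criterion. If the negative binomial fit fails to converge the model falls
#' back to quasi-Poisson with a warning.
#'
#' @param data A data frame with columns `method`, `stretch`, `value` and —
#'   for the negative binomial family — `total` (total individuals per
#'   sample).
#' @param family `"poisson"` or `"negbin"`.
#' @return An object of class `method_comparison` wrapping the fit, with
#'   [tidy()] and [glance()] methods.
#' @export
fit_method_comparison <- function(data, family = c("poisson", "negbin")) {
  family <- arg_match(family)
  data <- as_tibble(data)
  need <- c("method", "stretch", "value")
  if (!all(need %in% names(data))) {
    abort("Data needs columns method, stretch, value.")
  }
  if (n_distinct(data$method) < 2) abort("Need at least 2 methods.")
  if (n_distinct(data$stretch) < 2) abort("Need at least 2 stretches.")
  if (any(data$value < 0) || any(data$value != round(data$value))) {
    abort("Count families need non-negative integer responses.")
  }
  data$method <- factor(data$method)
  data$stretch <- factor(data$stretch)

  fell_back <- FALSE
  if (family == "poisson") {
    fit <- glm(value ~ method + stretch, data = data, family = poisson())
  } else {
    if (!"total" %in% names(data)) {
      abort("The negative binomial family needs a `total` column for the offset.")
    }
    if (any(data$total <= 0)) abort("Offset totals must be positive.")
    fit <- tryCatch(
      MASS::glm.nb(value ~ method + stretch + offset(log(total)), data = data),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit) || !fit$converged) {
      warn("Negative binomial fit did not converge; falling back to quasi-Poisson.")
      fell_back <- TRUE
      fit <- glm(value ~ method + stretch + offset(log(total)),
                 data = data, family = stats::quasipoisson())
    }
  }
  cf <- summary(fit)$coefficients
  mterm <- grep("^method", rownames(cf), value = TRUE)[1]
  structure(list(
    fit = fit,
    family = if (fell_back) "quasipoisson-log"
             else if (family == "poisson") "poisson-log" else "negbin-log",
    method_term = mterm,
    method_effect = unname(cf[mterm, "Estimate"]),
    method_rate_ratio = unname(exp(cf[mterm, "Estimate"])),
    method_p_value = unname(cf[mterm, 4]),
    residual_deviance = fit$deviance
  ), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Method comparison (", x$family, ")\n", sep = "")
  cat(sprintf("  method rate ratio %.3f, p = %.4g; residual deviance %.2f\n",
              x$method_rate_ratio, x$method_p_value, x$residual_deviance))
  invisible(x)
}

#' @export
tidy.method_comparison <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, "Estimate"],
         std_error = cf[, "Std. Error"], statistic = cf[, 3],
         p_value = cf[, 4])
}

#' @export
glance.method_comparison <- function(x, ...) {
  tibble(family = x$family, method_rate_ratio = x$method_rate_ratio,
         method_p_value = x$method_p_value,
         residual_deviance = x$residual_deviance,
         df_residual = x$fit$df.residual)
}

#' Yates continuity-corrected chi-square test for a 2x2 table
#'
#' `statistic = N * (max(0, |ad - bc| - N/2))^2 / (r1 r2 c1 c2)` with one
#' degree of freedom; the correction term is clamped at zero so a
#' near-independent table cannot yield an inflated statistic. The statistic
#' is invariant to transposition and to swapping both rows and both columns.
#'
#' @param x A 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return A tibble with `statistic`, `df`, `p_value` and the input counts
#'   in a list-column `table`.
#' @export
#' @examples
#' yates_chi_square(matrix(c(12, 2, 1, 10), 2)) # 11.58
yates_chi_square <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2, 2))) abort("Need a 2x2 table.")
  if (any(x < 0) || any(x != round(x))) {
    abort("Counts must be non-negative integers.")
  }
  r <- rowSums(x); cl <- colSums(x); N <- sum(x)
  if (any(r == 0) || any(cl == 0)) {
    abort("All row and column margins must be positive.")
  }
  det_abs <- abs(x[1, 1] * x[2, 2] - x[1, 2] * x[2, 1])
  stat <- N * max(0, det_abs - N / 2)^2 / prod(r, cl)
  tibble(statistic = stat, df = 1L,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         table = list(x))
}
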