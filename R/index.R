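#' Aggregate per-metric EQRs into an index score
#'
#' The index is the mean of the `k` lowest metric EQRs (the metrics
#' signalling the strongest departure from reference). By default `k` is the
#' lowest half, rounded up: 5 of 10 metrics, 3 of 6. Selection is
#' deterministic: EQRs are ordered by value and then by metric name, and the
#' first `k` are averaged.
#'
#' @param eqrs Named numeric vector of per-metric EQRs (names are metric
#'   ids), or a data frame with columns `metric` and `eqr`.
#' @param k Number of lowest EQRs to average; default `ceiling(M / 2)`.
#' @return The index score in `[0, 1]`.
#' @export
#' @examples
#' aggregate_index(c(a = 0.2, b = 0.4, c = 0.6, d = 0.8), k = 2) # 0.3
aggregate_index <- function(eqrs, k = NULL) {
  if (is.data.frame(eqrs)) eqrs <- setNames(eqrs$eqr, eqrs$metric)
  if (length(eqrs) == 0) abort("Cannot aggregate an empty EQR vector.")
  if (is.null(names(eqrs))) names(eqrs) <- as.character(seq_along(eqrs))
  if (is.null(k)) k <- ceiling(length(eqrs) / 2)
  if (k < 1 || k > length(eqrs)) {
    abort(sprintf("k must be in [1, %d].", length(eqrs)))
  }
  ord <- order(eqrs, names(eqrs))
  mean(eqrs[ord][seq_len(k)])
}

#' Validate a class-boundary vector
#'
#' @param boundaries Named numeric vector `c(high=, good=, moderate=, poor=)`
#'   with strictly decreasing values in (0, 1).
#' @return The boundaries, invisibly valid.
#' @export
validate_boundaries <- function(boundaries) {
  need <- c("high", "good", "moderate", "poor")
  if (!all(need %in% names(boundaries))) {
    abort("Boundaries need named entries high, good, moderate, poor.")
  }
  b <- boundaries[need]
  if (any(!is.finite(b)) || any(diff(b) >= 0)) {
    abort("Boundaries must be finite and strictly decreasing high > good > moderate > poor.")
  }
  b
}

#' Default class boundaries
#'
#' The generic five-class grid (0.8, 0.6, 0.4, 0.2). Boundaries are
#' river-type specific in operational use and must be overridden per type;
#' see [read_class_boundaries()] and [calibrate_class_boundaries()].
#'
#' @return Named numeric vector.
#' @export
default_boundaries <- function() {
  c(high = 0.8, good = 0.6, moderate = 0.4, poor = 0.2)
}

#' Classify an index score into an ecological status class
#'
#' Classes are assigned by the first boundary not exceeding the score, with
#' closed lower bounds: a score exactly at the Good boundary is Good. The
#' good/degraded dichotomy opposes the high-good classes to
#' moderate-poor-bad.
#'
#' @param score Numeric score(s) in `[0, 1]`.
#' @param boundaries A [validate_boundaries()] vector.
#' @return A tibble with columns `score`, `class` (ordered factor Bad <
#'   Poor < Moderate < Good < High) and `dichotomy` (`"good"` or
#'   `"degraded"`).
#' @export
#' @examples
#' classify_status(c(1, 0.59), default_boundaries())
classify_status <- function(score, boundaries = default_boundaries()) {
  b <- validate_boundaries(boundaries)
  cls <- case_when(
    score >= b["high"] ~ "High",
    score >= b["good"] ~ "Good",
    score >= b["moderate"] ~ "Moderate",
    score >= b["poor"] ~ "Poor",
    TRUE ~ "Bad"
  )
  tibble(
    score = score,
    class = factor(cls, levels = c("Bad", "Poor", "Moderate", "Good", "High"),
                   ordered = TRUE),
    dichotomy = ifelse(cls %in% c("High", "Good"), "good", "degraded")
  )
}

#' eDNA-adapted predictive multimetric fish index
#'
#' Full assessment of one or more samples: computes the index metrics from
#' the MOTU table, their reference expectations from the environmental
#' descriptors, per-metric EQRs, the aggregated index score (mean of the
#' lowest half of the EQRs), the five-class status and the good/degraded
#' dichotomy. The `"6FI"` variant uses only the six metrics expressed in
#' relative abundance of species or individuals; `"10FI"` adds the four
#' species-count metrics.
#'
#' @param x A MOTU tibble (one or more samples).
#' @param traits Trait tibble covering the index guilds.
#' @param models A `ref_model_set` from [fit_reference_models()].
#' @param env Environmental table with one row per assessed sample; its
#'   `site` column is matched against the sample identifiers of `x`.
#' @param variant `"10FI"` or `"6FI"`.
#' @param boundaries Class boundaries (named vector).
#' @param k Number of lowest EQRs aggregated; default lowest half.
#' @return A tibble of class `eqr_assessment`, one row per sample:
#'   `sample`, `variant`, `score`, `class`, `dichotomy` and a nested
#'   list-column `audit` holding the per-metric observed, expected and EQR
#'   values.
#' @export
edna_fish_index <- function(x, traits, models, env,
                            variant = c("10FI", "6FI"),
                            boundaries = default_boundaries(), k = NULL) {
  variant <- arg_match(variant)
  reg <- index_metric_registry(variant)
  env <- validate_env_descriptors(env)
  obs <- index_metric_vector(x, traits, variant = variant)

  audit <- obs %>%
    left_join(glance(models) %>%
                select("metric", "orientation", "sigma"),
              by = "metric") %>%
    left_join(select(env, sample = "site"), by = "sample")
  if (any(is.na(audit$sigma))) {
    gap <- unique(audit$metric[is.na(audit$sigma)])
    abort(paste0("Model set lacks metric(s): ", paste(gap, collapse = ", ")))
  }

  samples <- unique(obs$sample)
  env_idx <- match(samples, env$site)
  if (any(is.na(env_idx))) {
    abort(paste0("No environmental descriptors for sample(s): ",
                 paste(samples[is.na(env_idx)], collapse = ", ")))
  }

  per_sample <- purrr::map_dfr(samples, function(s) {
    env_s <- env[env_idx[match(s, samples)], , drop = FALSE]
    aud <- filter(audit, .data$sample == s) %>%
      mutate(
        expected = vapply(.data$metric, function(m)
          predict_reference(models, m, env_s), numeric(1)),
        eqr = purrr::pmap_dbl(
          list(.data$value, .data$expected, .data$sigma,
               .data$orientation, .data$unit),
          function(v, e, sg, o, u)
            compute_eqr(v, e, sg, orientation = o, unit = u))
      ) %>%
      select("metric", "guild", "unit", observed = "value",
             "expected", "sigma", "orientation", "eqr")
    score <- aggregate_index(setNames(aud$eqr, aud$metric), k = k)
    cls <- classify_status(score, boundaries)
    tibble(sample = s, variant = variant, score = score,
           class = cls$class, dichotomy = cls$dichotomy,
           audit = list(aud))
  })
  structure(per_sample, class = c("eqr_assessment", class(per_sample)))
}

#' Plot an assessment's per-metric EQR profile
#'
#' @param object An `eqr_assessment` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.eqr_assessment <- function(object, ...) {
  aud <- object %>%
    select("sample", "audit") %>%
    tidyr::unnest("audit")
  ggplot2::ggplot(aud, ggplot2::aes(x = .data$metric, y = .data$eqr)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::facet_wrap(~sample) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Metric EQR")
}

#' Calibrate class boundaries from reference-site index scores
#'
#' Reference-condition analogue of boundary setting: the High/Good boundary
#' is the 25th percentile of index scores at reference sites and the
#' Good/Moderate boundary their 1st percentile (so nominally 1% of
#' undisturbed sites fall below Good); Moderate/Poor and Poor/Bad subdivide
#' the interval below Good at 2/3 and 1/3 of its value.
#'
#' @param reference_scores Numeric vector of index scores computed at
#'   reference (least-disturbed) sites through the same observation pipeline
#'   that will be used in assessment.
#' @param probs Quantile levels for the High/Good and Good/Moderate
#'   boundaries.
#' @return A named boundary vector.
#' @export
calibrate_class_boundaries <- function(reference_scores,
                                       probs = c(high = 0.25, good = 0.01)) {
  if (length(reference_scores) < 20) {
    abort("Need at least 20 reference scores to calibrate boundaries.")
  }
  q <- quantile(reference_scores, probs = probs, names = FALSE, type = 7)
  b <- c(high = q[1], good = q[2],
         moderate = q[2] * 2 / 3, poor = q[2] * 1 / 3)
  validate_boundaries(b)
}
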