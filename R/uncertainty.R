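#' Enumerate unordered pairs of sample identifiers
#'
#' All `n (n - 1) / 2` unordered pairs, lexicographically ordered, no
#' duplicates. Ten replicate water samples give the 45 possible two-sample
#' combinations used for spatial uncertainty assessment.
#'
#' @param ids Character vector of distinct sample identifiers (n >= 2).
#' @return A tibble with columns `id1`, `id2`.
#' @export
#' @examples
#' nrow(enumerate_pairs(paste0("s", 1:10))) # 45
enumerate_pairs <- function(ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate sample id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(ids) < 2) abort("Need at least 2 sample ids.")
  ids <- sort(ids)
  cmb <- utils::combn(ids, 2)
  tibble(id1 = cmb[1, ], id2 = cmb[2, ])
}

#' Spatial uncertainty of an index from replicate water samples
#'
#' Computes the index for every unordered pair of replicate samples
#' collected at one site and summarises its spread. By default each pair is
#' pooled (read counts summed, mirroring the standard two-capsule sampling
#' effort) before assessment; `mode = "average"` instead averages the two
#' single-replicate index scores. The coefficient of variation uses the
#' sample (n - 1) standard deviation.
#'
#' @param replicates A count-unit MOTU tibble of >= 3 replicate samples from
#'   one site.
#' @param assess A closure taking a MOTU tibble (one pooled sample) and
#'   returning a single numeric index score.
#' @param mode `"pool"` (default) or `"average"`.
#' @param boundaries Optional class boundaries; when supplied, per-pair
#'   classes, the modal class and the class-stability fraction are reported.
#' @return An object of class `uncertainty_result`: list with `pairs` (a
#'   tibble `id1`, `id2`, `score`, and `class` when classified), `n`,
#'   `mean`, `sd`, `cv`, `mode`, and `modal_class` / `stability` when
#'   classified.
#' @export
pairwise_index_cv <- function(replicates, assess,
                              mode = c("pool", "average"),
                              boundaries = NULL) {
  mode <- arg_match(mode)
  validate_motu_table(replicates)
  ids <- unique(replicates$sample)
  if (length(ids) < 3) {
    abort("Need >= 3 replicates; the CV is undefined for a single pair.")
  }
  pairs <- enumerate_pairs(ids)
  score_pair <- function(a, b) {
    if (mode == "pool") {
      pooled <- pool_replicates(
        filter(replicates, .data$sample %in% c(a, b)),
        tibble(sample = c(a, b), group = paste(a, b, sep = "+")))
      assess(pooled)
    } else {
      mean(c(assess(filter(replicates, .data$sample == a)),
             assess(filter(replicates, .data$sample == b))))
    }
  }
  pairs$score <- purrr::map2_dbl(pairs$id1, pairs$id2, score_pair)
  out <- list(pairs = pairs, n = length(ids),
              mean = mean(pairs$score), sd = sd(pairs$score),
              cv = sd(pairs$score) / mean(pairs$score), mode = mode)
  if (!is.null(boundaries)) {
    cls <- classify_status(pairs$score, boundaries)
    out$pairs$class <- cls$class
    tab <- sort(table(cls$class), decreasing = TRUE)
    out$modal_class <- names(tab)[1]
    out$stability <- unname(tab[1]) / nrow(pairs)
  }
  structure(out, class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat(sprintf(
    "Pairwise index uncertainty: %d replicates, %d pairs (%s mode)\n",
    x$n, nrow(x$pairs), x$mode))
  cat(sprintf("  score %.3f +/- %.4f (sd, n-1), CV = %.4f\n",
              x$mean, x$sd, x$cv))
  if (!is.null(x$modal_class)) {
    cat(sprintf("  modal class %s, stability %.2f\n", x$modal_class,
                x$stability))
  }
  invisible(x)
}

#' Plot per-pair index scores
#'
#' @param object An `uncertainty_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.uncertainty_result <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = "", y = .data$score)) +
    ggplot2::geom_boxplot(width = 0.3) +
    ggplot2::geom_jitter(width = 0.05, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "Index score (per sample pair)")
}

#' Seasonal stability of an index series
#'
#' Classifies each dated score of a site's index series and counts
#' departures from the modal class (ties on the mode resolved towards the
#' better class). A stable site has zero departures.
#'
#' @param series A data frame with columns `date` (coercible to `Date`,
#'   strictly increasing) and `score`; one site.
#' @param boundaries Class boundaries for the site's river type.
#' @return A list with `records` (tibble `date`, `score`, `class`,
#'   `departure`), `modal_class` and `n_departures`.
#' @export
#' @examples
#' s <- data.frame(date = as.Date("2016-01-01") + (0:3) * 60,
#'                 score = c(0.7, 0.7, 0.5, 0.7))
#' seasonal_stability(s, default_boundaries())$n_departures # 1
seasonal_stability <- function(series, boundaries = default_boundaries()) {
  series <- as_tibble(series)
  if (!all(c("date", "score") %in% names(series))) {
    abort("Series needs columns `date` and `score`.")
  }
  if (nrow(series) < 2) abort("Need at least 2 dates.")
  dates <- as.Date(series$date)
  if (any(diff(dates) <= 0)) abort("Dates must be strictly increasing.")
  cls <- classify_status(series$score, boundaries)
  tab <- table(cls$class)
  best <- names(tab)[tab == max(tab)]
  modal <- best[length(best)]  # factor levels run Bad..High; last is best
  records <- tibble(date = dates, score = series$score, class = cls$class,
                    departure = as.character(cls$class) != modal)
  list(records = records, modal_class = modal,
       n_departures = sum(records$departure))
}
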