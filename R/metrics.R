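#' Trait-guild metrics per sample
#'
#' Computes guild metrics for every sample of a MOTU table, in any of three
#' units. Presence is abundance > 0 (no minimum-read threshold by default;
#' set `min_abundance` to impose one). Taxa without a resolved trait profile
#' are dropped from guild metrics, with a log message, and never enter
#' relative-species denominators; this keeps denominators stable when a MOTU
#' is excluded rather than deleted.
#'
#' * `n-species`: number of present taxa carrying the guild;
#' * `rel-species`: that count divided by the number of present resolved taxa;
#' * `rel-individuals`: the guild's share of summed abundance of resolved
#'   taxa, in `[0, 1]`.
#'
#' @param x A MOTU tibble (counts or percent; shares are scale-free).
#' @param traits A trait tibble covering the taxa of `x`.
#' @param guilds Guild codes to compute (default: the nine comparison guilds).
#' @param units Units to compute, subset of [metric_units()].
#' @param min_abundance Presence threshold; a taxon counts as present when
#'   its abundance is strictly greater than this (default 0).
#' @return A tibble `sample`, `guild`, `unit`, `value`.
#' @export
#' @examples
#' fx <- load_table2_fixture()
#' guild_metrics(fx$edna, fx$traits, guilds = "POT", units = "n-species")
guild_metrics <- function(x, traits, guilds = comparison_guilds(),
                          units = metric_units(), min_abundance = 0) {
  validate_motu_table(x)
  assert_known_guilds(guilds)
  units <- match.arg(units, metric_units(), several.ok = TRUE)
  assert_trait_coverage(x, traits)

  resolved <- resolved_taxa(traits)
  dropped <- setdiff(unique(x$taxon), resolved)
  if (length(dropped) > 0) {
    inform(paste0("Dropping taxa without resolved traits from guild metrics: ",
                  paste(dropped, collapse = ", ")))
  }
  present <- x %>%
    filter(.data$abundance > min_abundance, .data$taxon %in% resolved)

  per_sample <- present %>%
    group_by(.data$sample) %>%
    summarise(richness = n_distinct(.data$taxon),
              total = sum(.data$abundance), .groups = "drop")

  grid <- tidyr::expand_grid(sample = unique(x$sample), guild = guilds)
  memb <- filter(traits, !is.na(.data$guild), .data$guild %in% guilds)

  stats_tbl <- present %>%
    inner_join(memb, by = "taxon", relationship = "many-to-many") %>%
    group_by(.data$sample, .data$guild) %>%
    summarise(n_sp = n_distinct(.data$taxon),
              ab = sum(.data$abundance), .groups = "drop")

  out <- grid %>%
    left_join(stats_tbl, by = c("sample", "guild")) %>%
    left_join(per_sample, by = "sample") %>%
    mutate(
      n_sp = ifelse(is.na(.data$n_sp), 0L, .data$n_sp),
      ab = ifelse(is.na(.data$ab), 0, .data$ab),
      `n-species` = .data$n_sp,
      `rel-species` = ifelse(is.na(.data$richness) | .data$richness == 0,
                             NA_real_, .data$n_sp / .data$richness),
      `rel-individuals` = ifelse(is.na(.data$total) | .data$total == 0,
                                 NA_real_, .data$ab / .data$total)
    ) %>%
    select("sample", "guild", all_of(units)) %>%
    tidyr::pivot_longer(all_of(units), names_to = "unit", values_to = "value")
  arrange(out, .data$sample, .data$guild, .data$unit)
}

#' Single guild metric for one sample
#'
#' Scalar convenience wrapper around [guild_metrics()].
#'
#' @param x A MOTU tibble restricted (or restrictable) to `sample`.
#' @param sample Sample identifier.
#' @param guild Guild code.
#' @param unit One of [metric_units()].
#' @inheritParams guild_metrics
#' @return A single numeric value.
#' @export
guild_metric <- function(x, sample, guild, unit, traits, min_abundance = 0) {
  res <- guild_metrics(filter(x, .data$sample == !!sample), traits,
                       guilds = guild, units = unit,
                       min_abundance = min_abundance)
  res$value[1]
}

#' The ten index metrics for each sample
#'
#' Evaluates the metric set of the predictive fish index (see
#' [index_metric_registry()]) for every sample: four species counts
#' (limnophilic-reproduction, stenothermal, omnivorous, tolerant), three
#' relative species shares (limnophilic, oxyphilous, intolerant) and three
#' relative individual shares (oxyphilous, habitat-degradation intolerant,
#' running-water spawning). The `"6FI"` variant drops the four species-count
#' metrics, keeping only metrics comparable between eDNA and electrofishing.
#'
#' @inheritParams guild_metrics
#' @param variant `"10FI"` or `"6FI"`.
#' @return A tibble `sample`, `metric`, `guild`, `unit`, `value`, ordered as
#'   the registry.
#' @export
index_metric_vector <- function(x, traits, variant = c("10FI", "6FI"),
                                min_abundance = 0) {
  variant <- arg_match(variant)
  reg <- index_metric_registry(variant)
  gap <- setdiff(reg$guild, unique(traits$guild))
  if (length(gap) > 0) {
    abort(paste0("Trait table lacks index guild(s): ",
                 paste(gap, collapse = ", ")))
  }
  vals <- guild_metrics(x, traits, guilds = unique(reg$guild),
                        units = unique(reg$unit),
                        min_abundance = min_abundance)
  empty <- vals %>% filter(.data$unit != "n-species", is.na(.data$value))
  if (nrow(empty) > 0) {
    abort(sprintf(
      "Relative metrics are undefined for sample '%s' (no resolved taxa present).",
      empty$sample[1]))
  }
  reg %>%
    inner_join(vals, by = c("guild", "unit"),
               relationship = "many-to-many") %>%
    select("sample", "metric", "guild", "unit", "value") %>%
    arrange(.data$sample,
            match(.data$metric, index_metric_registry("10FI")$metric))
}

#' Species-accumulation curve over sampling campaigns
#'
#' Mean cumulative distinct-taxon count after 1..k campaigns, averaged over
#' random orderings of the campaigns (full random permutations, seeded). The
#' endpoint at k = number of campaigns equals the union richness for every
#' ordering.
#'
#' @param x A MOTU tibble whose samples are sampling campaigns.
#' @param n_perm Number of random campaign orderings (default 999).
#' @param seed Integer seed; permutation draws never touch global RNG state.
#' @param min_abundance Presence threshold as in [guild_metrics()].
#' @return A tibble of class `accum_curve` with columns `k`,
#'   `mean_richness`, `sd_richness`, and attributes `n_perm`, `seed`.
#' @export
#' @examples
#' x <- motu_table(data.frame(sample = c("c1", "c2"), a = c(1, 0), b = c(1, 1)),
#'                 wide = TRUE, method = "TEF", unit = "counts")
#' accumulation_curve(x, n_perm = 10, seed = 1)
accumulation_curve <- function(x, n_perm = 999, seed, min_abundance = 0) {
  validate_motu_table(x)
  if (n_perm < 1) abort("n_perm must be >= 1.")
  present <- filter(x, .data$abundance > min_abundance)
  campaigns <- unique(x$sample)
  k_max <- length(campaigns)
  if (k_max < 1) abort("Need at least one campaign.")
  taxa_by_campaign <- lapply(campaigns, function(s)
    unique(present$taxon[present$sample == s]))
  names(taxa_by_campaign) <- campaigns

  acc <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ord <- sample.int(k_max)
      seen <- character(0)
      vapply(ord, function(j) {
        seen <<- union(seen, taxa_by_campaign[[j]])
        length(seen)
      }, numeric(1))
    }, numeric(k_max))
  })
  acc <- matrix(acc, nrow = k_max)
  out <- tibble(
    k = seq_len(k_max),
    mean_richness = apply(acc, 1, mean),
    sd_richness = if (n_perm > 1) apply(acc, 1, sd) else rep(0, k_max)
  )
  structure(out, class = c("accum_curve", class(out)),
            n_perm = n_perm, seed = seed)
}

#' Plot a species-accumulation curve
#'
#' @param object An [accumulation_curve()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.accum_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$mean_richness)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_richness - .data$sd_richness,
      ymax = .data$mean_richness + .data$sd_richness), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Number of campaigns",
                  y = "Mean cumulative species richness")
}
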