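#' Side-by-side guild metrics for two sampling methods
#'
#' Convenience figure contrasting trait-guild metric values computed from
#' paired eDNA and electrofishing tables of the same stretches, one panel
#' per guild.
#'
#' @param edna,tef MOTU tibbles over the same samples.
#' @param traits Trait tibble.
#' @param unit Metric unit to display.
#' @param guilds Guilds to display (default the nine comparison guilds).
#' @return A ggplot object.
#' @export
plot_method_comparison <- function(edna, tef, traits,
                                   unit = "rel-individuals",
                                   guilds = comparison_guilds()) {
  vals <- bind_rows(
    guild_metrics(edna, traits, guilds, units = unit) %>%
      mutate(method = "eDNA"),
    guild_metrics(tef, traits, guilds, units = unit) %>%
      mutate(method = "TEF")
  )
  ggplot2::ggplot(vals, ggplot2::aes(x = .data$sample, y = .data$value,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~guild, scales = "free_y") +
    ggplot2::labs(x = NULL, y = unit, fill = NULL)
}
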