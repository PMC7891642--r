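#' Registered guild vocabularies
#'
#' Two families of species-trait guilds are used throughout the package. The
#' nine *comparison guilds* are the most dissimilar trait categories commonly
#' used by national fish-based assessment methods (trait lists sharing fewer
#' than 50% of species pairwise): benthic feeding (`BEN`), eurytopic (`EUR`),
#' insectivorous (`INS`), omnivorous (`OMN`), phytophilic (`PHY`),
#' potamodromous (`POT`), rheophilic (`RHE`), tolerant to pollution (`TOL`)
#' and pelagic (`PEL`). The *index guilds* are the guild-unit pairs entering
#' the predictive multimetric fish index: limnophilic reproduction habitat
#' (`LIM-rep`), stenothermal (`STEN`), omnivorous (`OMN-i`) and tolerant
#' (`TOL-i`) species counts; limnophilic (`LIM-rel`), oxyphilous (`OXY-rel`)
#' and intolerant (`INTOL-rel`) shares of species; oxyphilous (`OXY-ab`),
#' habitat-degradation intolerant (`HINTOL-ab`) and running-water spawning
#' (`RWSP-ab`) shares of individuals.
#'
#' @return A character vector of registered guild codes.
#' @export
#' @examples
#' guild_vocabulary()
guild_vocabulary <- function() {
  c(comparison_guilds(), index_guilds())
}

#' @rdname guild_vocabulary
#' @export
comparison_guilds <- function() {
  c("BEN", "EUR", "INS", "OMN", "PHY", "POT", "RHE", "TOL", "PEL")
}

#' @rdname guild_vocabulary
#' @export
index_guilds <- function() {
  c("LIM-rep", "STEN", "OMN-i", "TOL-i",
    "LIM-rel", "OXY-rel", "INTOL-rel",
    "OXY-ab", "HINTOL-ab", "RWSP-ab")
}

#' Metric units
#'
#' `n-species` counts guild members present; `rel-species` is that count
#' divided by the number of present taxa with a resolved trait profile;
#' `rel-individuals` is the guild's share of total abundance (reads for eDNA,
#' individuals for electrofishing).
#'
#' @return Character vector of unit codes.
#' @export
metric_units <- function() c("n-species", "rel-species", "rel-individuals")

#' Registry of the ten index metrics
#'
#' The predictive fish index uses ten functional metrics: four expressed in
#' number of species, three in relative number of species and three in
#' relative number of individuals. Each metric carries a disturbance
#' orientation: whether its value increases or decreases as anthropogenic
#' disturbance intensifies. The six-metric variant (`variant = "6FI"`) keeps
#' only the metrics expressed in relative abundance of species or
#' individuals, the ones that remain comparable between eDNA and
#' electrofishing samples.
#'
#' @param variant `"10FI"` (all ten metrics) or `"6FI"` (relative metrics
#'   only).
#' @return A tibble with columns `metric`, `guild`, `unit` and `orientation`.
#' @export
#' @examples
#' index_metric_registry("6FI")
index_metric_registry <- function(variant = c("10FI", "6FI")) {
  variant <- arg_match(variant)
  reg <- tibble(
    metric = c("lim_rep_nsp", "sten_nsp", "omn_nsp", "tol_nsp",
               "lim_rsp", "oxy_rsp", "intol_rsp",
               "oxy_rab", "hintol_rab", "rwsp_rab"),
    guild = c("LIM-rep", "STEN", "OMN-i", "TOL-i",
              "LIM-rel", "OXY-rel", "INTOL-rel",
              "OXY-ab", "HINTOL-ab", "RWSP-ab"),
    unit = c(rep("n-species", 4), rep("rel-species", 3),
             rep("rel-individuals", 3)),
    orientation = c("increases", "decreases", "increases", "increases",
                    "increases", "decreases", "decreases",
                    "decreases", "decreases", "decreases")
  )
  if (variant == "6FI") reg <- filter(reg, .data$unit != "n-species")
  reg
}

assert_known_guilds <- function(guilds, arg = "guild") {
  bad <- setdiff(guilds, guild_vocabulary())
  if (length(bad) > 0) {
    abort(sprintf("Unknown %s code(s): %s. See guild_vocabulary().",
                  arg, paste(bad, collapse = ", ")))
  }
  invisible(guilds)
}
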