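#' Build a species-trait table
#'
#' A trait table records guild memberships as a long tibble with columns
#' `taxon` and `guild`, one row per membership. A taxon that is deliberately
#' excluded from trait-based analyses (for instance a MOTU whose member
#' species have irreconcilable profiles) is recorded with `guild = NA`; it
#' still counts towards whole-assemblage richness but never towards guild
#' metrics, and it is never part of relative-species denominators.
#'
#' @param data A data frame with columns `taxon` and `guild` (long), or
#'   `taxon` and `guilds` where `guilds` packs codes separated by `;`.
#' @return A validated long tibble with columns `taxon`, `guild`.
#' @export
#' @examples
#' trait_table(data.frame(taxon = c("a", "a", "b"),
#'                        guild = c("BEN", "TOL", "PEL")))
trait_table <- function(data) {
  data <- as_tibble(data)
  if ("guilds" %in% names(data) && !"guild" %in% names(data)) {
    data <- data %>%
      mutate(guild = strsplit(ifelse(is.na(.data$guilds), "", .data$guilds),
                              ";", fixed = TRUE)) %>%
      select("taxon", "guild") %>%
      tidyr::unnest(cols = "guild", keep_empty = TRUE)
  }
  if (!all(c("taxon", "guild") %in% names(data))) {
    abort("trait_table() needs columns `taxon` and `guild` (or `guilds`).")
  }
  out <- distinct(tibble(taxon = as.character(data$taxon),
                         guild = as.character(data$guild)))
  assert_known_guilds(out$guild[!is.na(out$guild)])
  out
}

#' Taxa with a resolved trait profile
#'
#' @param traits A trait tibble.
#' @return Character vector of taxa carrying at least one guild.
#' @export
resolved_taxa <- function(traits) {
  unique(traits$taxon[!is.na(traits$guild)])
}

#' Taxa explicitly excluded from trait-based analyses
#'
#' @param traits A trait tibble.
#' @return Character vector of taxa marked excluded (`guild = NA` only).
#' @export
excluded_taxa <- function(traits) {
  setdiff(unique(traits$taxon), resolved_taxa(traits))
}

#' Check trait coverage of a MOTU table
#'
#' Every taxon appearing in a MOTU table that feeds guild metrics must have a
#' trait entry or an explicit excluded mark.
#'
#' @param x A MOTU tibble.
#' @param traits A trait tibble.
#' @return Invisibly `TRUE`; errors listing uncovered taxa otherwise.
#' @export
assert_trait_coverage <- function(x, traits) {
  missing_taxa <- setdiff(unique(x$taxon), unique(traits$taxon))
  if (length(missing_taxa) > 0) {
    abort(paste0("Taxa without a trait entry or excluded mark: ",
                 paste(missing_taxa, collapse = ", ")))
  }
  invisible(TRUE)
}
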