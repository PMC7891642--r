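review_unit_labels <- c(
  species_richness = "Species richness",
  relative_abundance = "Relative abundance",
  relative_biomass = "Relative biomass",
  density = "Density",
  biomass = "Biomass",
  expert_judgment = "Expert judgment"
)

trait_based_types <- c("Habitat guilds", "Migratory guilds",
                       "Perturbation tolerance", "Reproductive guilds",
                       "Trophic groups")

ednafish_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ednafish")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is mapped directly
    path <- system.file("inst", "extdata", file, package = "ednafish")
  }
  if (!nzchar(path)) abort(sprintf("Packaged fixture not found: %s", file))
  path
}

#' Review table of the 25 WFD-compliant national fish methods
#'
#' The packaged cross-classification of the 198 metrics used by the 25
#' intercalibrated national fish-based river assessment methods: 10 metric
#' types by 6 expression units. Cells are metric counts.
#'
#' @return A long tibble with columns `metric_type`, `unit`, `n` (60 cells,
#'   zeros included) carrying the full 10 x 6 grid.
#' @export
#' @examples
#' rv <- load_table1_fixture()
#' sum(rv$n) # 198
load_table1_fixture <- function() {
  wide <- readr::read_csv(ednafish_extdata("table1_wfd_metrics.csv"),
                          show_col_types = FALSE, progress = FALSE)
  out <- tidyr::pivot_longer(wide, -"metric_type", names_to = "unit",
                             values_to = "n")
  out$unit <- unname(review_unit_labels[out$unit])
  validate_review_table(out)
}

#' Validate a review table
#'
#' @param x A tibble with columns `metric_type`, `unit`, `n`.
#' @return `x` invisibly; errors on negative or non-integer counts.
#' @export
validate_review_table <- function(x) {
  need <- c("metric_type", "unit", "n")
  if (!all(need %in% names(x))) {
    abort("A review table needs columns metric_type, unit, n.")
  }
  if (any(x$n < 0) || any(x$n != round(x$n))) {
    abort("Review-table cells must be non-negative integers.")
  }
  x
}

#' Paired eDNA and electrofishing relative abundances for five Rhone stretches
#'
#' The packaged per-species relative per cent abundances detected by eDNA
#' metabarcoding and caught by traditional electrofishing (TEF) in river
#' stretches A-E of the Rhone main channel, together with the comparison-guild
#' profile of each MOTU. Blank cells in the printed table are absences and are
#' read as 0 (required to count detected taxa per stretch). Three MOTUs
#' (`Car_spp`, `Leu_spp`, `Cypr_1`) aggregate several morphological species
#' that the marker cannot separate; their TEF catches are printed per species
#' and summed into the MOTU here, with the species-level detail preserved.
#'
#' The TEF columns pool several sampling campaigns as printed; no
#' single-campaign span is asserted.
#'
#' @return A list with elements
#'   * `edna`: percent-unit MOTU tibble, 33 MOTUs x 5 stretches (`RS_A` ...
#'     `RS_E`),
#'   * `tef`: percent-unit MOTU tibble at MOTU level (species sub-rows summed),
#'   * `traits`: comparison-guild trait tibble for the 33 MOTUs,
#'   * `detail`: the table as printed, one row per printed line, with `role`
#'     (`motu` or `member`) and `member_of` flagging aggregation.
#' @export
#' @examples
#' fx <- load_table2_fixture()
#' dplyr::filter(fx$edna, taxon == "Bar_bab", sample == "RS_A")
load_table2_fixture <- function() {
  detail <- readr::read_csv(ednafish_extdata("table2_rhone_motus.csv"),
                            show_col_types = FALSE, progress = FALSE)
  stretches <- c("A", "B", "C", "D", "E")

  long <- detail %>%
    tidyr::pivot_longer(dplyr::matches("^[A-E]_(tef|edna)$"),
                        names_to = c("stretch", "method_col"),
                        names_sep = "_", values_to = "abundance") %>%
    mutate(abundance = ifelse(is.na(.data$abundance), 0, .data$abundance),
           sample = paste0("RS_", .data$stretch))

  edna <- long %>%
    filter(.data$method_col == "edna", .data$role == "motu") %>%
    select(sample = "sample", taxon = "motu", "abundance") %>%
    motu_table(method = "eDNA", unit = "percent")

  tef <- long %>%
    filter(.data$method_col == "tef") %>%
    mutate(taxon = ifelse(.data$role == "motu", .data$motu,
                          .data$member_of)) %>%
    group_by(.data$sample, .data$taxon) %>%
    summarise(abundance = sum(.data$abundance), .groups = "drop") %>%
    motu_table(method = "TEF", unit = "percent")

  traits <- detail %>%
    filter(.data$role == "motu") %>%
    select(taxon = "motu", "guilds") %>%
    trait_table()

  list(edna = edna, tef = tef, traits = traits, detail = detail)
}

#' Seasonal six-metric fish-index series for three Rhone-basin sites
#'
#' Packaged bimonthly (October 2015 to August 2016) index scores of the
#' six-metric eDNA fish index at the Ain, Jons and Tier monitoring sites,
#' with the class labels as printed. Note the printed labels at Jons are not
#' reproducible from any single monotone score threshold (0.65 is labelled
#' Good where 0.68 is Moderate); stability analyses in this package therefore
#' count departures from the modal class under a configured boundary.
#'
#' @return A tibble with columns `site`, `date`, `score`, `printed_class`.
#' @export
load_table3_fixture <- function() {
  readr::read_csv(ednafish_extdata("table3_seasonal_edna6fi.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Read a discard policy from YAML
#'
#' A discard policy is a list of taxon codes to remove before analysis, each
#' with a reason tag from `farmed-only`, `stocking`, `lentic-transport`,
#' `other`. An example basin-specific policy ships as
#' `system.file("extdata", "rhone_discards.yml", package = "ednafish")`.
#'
#' @param path Path to a YAML file: a sequence of `{taxon, reason}` maps.
#' @return A tibble with columns `taxon`, `reason`.
#' @export
read_discard_policy <- function(path) {
  raw <- yaml::read_yaml(path)
  pol <- tibble(
    taxon = vapply(raw, function(e) as.character(e$taxon), character(1)),
    reason = vapply(raw, function(e) as.character(e$reason), character(1))
  )
  discard_policy(pol$taxon, pol$reason)
}

#' Read per-type class boundaries from YAML
#'
#' @param path Path to a YAML mapping of type/site name to a
#'   `{high, good, moderate, poor}` map.
#' @param type Entry to read; falls back to `default` when absent.
#' @return A named numeric vector `c(high=, good=, moderate=, poor=)`.
#' @export
read_class_boundaries <- function(path, type = "default") {
  raw <- yaml::read_yaml(path)
  entry <- raw[[type]] %||% raw[["default"]]
  if (is.null(entry)) {
    abort(sprintf("No boundary entry for '%s' and no default in %s.",
                  type, path))
  }
  b <- c(high = entry$high, good = entry$good,
         moderate = entry$moderate, poor = entry$poor)
  validate_boundaries(b)
}
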