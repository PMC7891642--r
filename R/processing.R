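discard_reasons <- c("farmed-only", "stocking", "lentic-transport", "other")

#' Define a MOTU discard policy
#'
#' @param taxa Character vector of taxon codes to remove.
#' @param reason Reason tag per taxon, from `farmed-only`, `stocking`,
#'   `lentic-transport`, `other` (recycled if length 1).
#' @return A tibble with columns `taxon`, `reason`.
#' @export
#' @examples
#' discard_policy(c("Cypr_2", "Onc_myk"), c("farmed-only", "stocking"))
discard_policy <- function(taxa, reason = "other") {
  reason <- rep_len(as.character(reason), length(taxa))
  bad <- setdiff(reason, discard_reasons)
  if (length(bad) > 0) {
    abort(paste0("Unknown discard reason(s): ", paste(bad, collapse = ", "),
                 ". Use one of: ", paste(discard_reasons, collapse = ", ")))
  }
  tibble(taxon = as.character(taxa), reason = reason)
}

#' Remove discarded MOTUs from a table
#'
#' Drops the policy taxa from the table. Per cent rows are re-closed to 100
#' over the remaining taxa; count rows are left as is. Absent policy taxa are
#' no-ops. The removal log (which taxa were actually removed, with reasons)
#' is attached as attribute `"removed"` and reported via `message()`.
#' Applying the same policy twice is a no-op the second time.
#'
#' @param x A MOTU tibble.
#' @param policy A [discard_policy()] tibble.
#' @return The filtered MOTU tibble.
#' @export
apply_discards <- function(x, policy) {
  validate_motu_table(x)
  hit <- semi_join(policy, x, by = "taxon")
  out <- filter(x, !.data$taxon %in% policy$taxon)
  if (nrow(out) == 0 && nrow(x) > 0) {
    warn("All taxa were discarded; the table is empty.")
  }
  if (nrow(hit) > 0) {
    inform(paste0("Discarded ", nrow(hit), " taxon/taxa: ",
                  paste(hit$taxon, " (", hit$reason, ")",
                        sep = "", collapse = ", ")))
    if (nrow(out) > 0 && out$unit[1] == "percent") {
      out <- out %>%
        group_by(.data$sample) %>%
        mutate(abundance = if (sum(.data$abundance) > 0)
          100 * .data$abundance / sum(.data$abundance) else .data$abundance) %>%
        ungroup()
    }
  }
  attr(out, "removed") <- hit
  out
}

#' Resolve the trait profile of a multi-species MOTU
#'
#' A MOTU aggregating species the marker cannot separate inherits a trait
#' profile by rule: `uniform-profile` when all member species share the same
#' guild set; `dominant-95` when one member represents at least 95% (the
#' configurable `dominance` share) of the individuals caught for the MOTU's
#' members in the reference catch data, in which case that species' profile
#' is used; otherwise the MOTU is `excluded` from trait-based metrics.
#' Dominance shares are computed on individuals summed over all campaigns of
#' the supplied reference catch.
#'
#' @param motu MOTU code to resolve.
#' @param members Character vector of member species codes.
#' @param traits Trait tibble covering the member species.
#' @param reference_catch A count-unit TEF MOTU tibble with the member
#'   species as taxa; required only when profiles differ.
#' @param dominance Dominance threshold (default 0.95).
#' @return A list with `motu`, `members`, `rule` (one of `uniform-profile`,
#'   `dominant-95`, `excluded`), `profile` (character vector of guilds or
#'   `NULL`), and `dominant_share`.
#' @export
resolve_motu_traits <- function(motu, members, traits,
                                reference_catch = NULL, dominance = 0.95) {
  missing_sp <- setdiff(members, unique(traits$taxon))
  if (length(missing_sp) > 0) {
    abort(paste0("Member species missing from trait table: ",
                 paste(missing_sp, collapse = ", ")))
  }
  profiles <- lapply(members, function(sp)
    sort(traits$guild[traits$taxon == sp & !is.na(traits$guild)]))
  res <- list(motu = motu, members = members, rule = "excluded",
              profile = NULL, dominant_share = NA_real_)
  if (length(unique(profiles)) == 1) {
    res$rule <- "uniform-profile"
    res$profile <- profiles[[1]]
    return(res)
  }
  if (!is.null(reference_catch)) {
    catch <- reference_catch %>%
      filter(.data$taxon %in% members) %>%
      group_by(.data$taxon) %>%
      summarise(n = sum(.data$abundance), .groups = "drop")
    total <- sum(catch$n)
    if (total > 0) {
      shares <- catch$n / total
      res$dominant_share <- max(shares)
      if (res$dominant_share >= dominance) {
        dom <- catch$taxon[which.max(shares)]
        res$rule <- "dominant-95"
        res$profile <- profiles[[match(dom, members)]]
        res$dominant_species <- dom
      }
    }
  }
  res
}

#' Pool replicate samples by summing counts
#'
#' Sums read or individual counts within each replicate group, mirroring the
#' standard two-capsule eDNA sampling effort (reads are summed before any
#' conversion to proportions, preserving count semantics for model offsets).
#' Provenance (the pooled replicate identifiers) is attached as attribute
#' `"provenance"`.
#'
#' @param x A count-unit MOTU tibble.
#' @param grouping A data frame with columns `sample` (replicate id) and
#'   `group` (pooled sample id). Replicates absent from `grouping` are
#'   dropped.
#' @return A count-unit MOTU tibble with one sample per group.
#' @export
#' @examples
#' x <- motu_table(data.frame(sample = c("r1", "r2"), a = c(3, 5), b = c(1, 0)),
#'                 wide = TRUE, method = "eDNA", unit = "counts")
#' pool_replicates(x, data.frame(sample = c("r1", "r2"), group = "site1"))
pool_replicates <- function(x, grouping) {
  validate_motu_table(x)
  if (nrow(x) > 0 && x$unit[1] != "counts") {
    abort("pool_replicates() needs a count-unit table; percentages cannot be summed.")
  }
  grouping <- as_tibble(grouping)
  if (!all(c("sample", "group") %in% names(grouping))) {
    abort("`grouping` needs columns `sample` and `group`.")
  }
  grouping <- mutate(grouping, sample = as.character(.data$sample),
                     group = as.character(.data$group))
  pooled <- x %>%
    inner_join(grouping, by = "sample") %>%
    group_by(sample = .data$group, .data$taxon) %>%
    summarise(abundance = sum(.data$abundance), .groups = "drop") %>%
    mutate(method = x$method[1], unit = "counts")
  prov <- grouping %>% group_by(.data$group) %>%
    summarise(replicates = list(sort(.data$sample)), .groups = "drop")
  out <- validate_motu_table(pooled)
  attr(out, "provenance") <- prov
  out
}

#' Convert counts to per cent relative abundances
#'
#' Divides each sample row by its total and expresses the result in per cent,
#' rounded to `digits` decimals with largest-remainder closure so every row
#' sums to exactly 100 at the output precision. Uniformly rescaling a row's
#' counts leaves the result unchanged.
#'
#' @param x A count-unit MOTU tibble; every sample must have a positive total.
#' @param digits Output precision (decimals), default 2 as in printed tables.
#' @return A percent-unit MOTU tibble.
#' @export
#' @examples
#' x <- motu_table(data.frame(sample = "s", a = 1, b = 1, c = 1), wide = TRUE,
#'                 method = "eDNA", unit = "counts")
#' to_relative(x)
to_relative <- function(x, digits = 2) {
  validate_motu_table(x)
  if (nrow(x) > 0 && x$unit[1] != "counts") {
    abort("to_relative() expects a count-unit table.")
  }
  totals <- x %>% group_by(.data$sample) %>%
    summarise(total = sum(.data$abundance), .groups = "drop")
  zero <- filter(totals, .data$total <= 0)
  if (nrow(zero) > 0) {
    abort(sprintf("Sample '%s' has a zero total; cannot form proportions.",
                  zero$sample[1]))
  }
  x %>%
    group_by(.data$sample) %>%
    mutate(abundance = largest_remainder_round(
      100 * .data$abundance / sum(.data$abundance), digits = digits)) %>%
    ungroup() %>%
    mutate(unit = "percent")
}

#' Largest-remainder rounding to a fixed total
#'
#' Rounds `x` to `digits` decimals while preserving `sum(x)` (assumed to be a
#' whole multiple of the rounding quantum, e.g. 100 for percentages): values
#' are floored at the quantum and the remaining units are given to the
#' largest remainders, ties going to the earlier element.
#'
#' @param x Non-negative numeric vector.
#' @param digits Decimals to keep.
#' @return Rounded vector with the same sum as `x`.
#' @export
largest_remainder_round <- function(x, digits = 2) {
  q <- 10^digits
  scaled <- x * q
  base <- floor(scaled)
  deficit <- round(sum(scaled)) - sum(base)
  if (deficit > 0) {
    remainder <- scaled - base
    give <- order(-remainder, seq_along(x))[seq_len(deficit)]
    base[give] <- base[give] + 1
  }
  base / q
}
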