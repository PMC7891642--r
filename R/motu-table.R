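#' Build and validate a MOTU abundance table
#'
#' A MOTU table is a long tibble with one row per (sample, taxon) cell and
#' columns `sample`, `taxon`, `abundance`, `method` and `unit`. Samples are
#' water samples (eDNA) or fishing campaigns (TEF); taxa are MOTU or species
#' codes; abundances are read counts, individual counts or per cent relative
#' abundances. Sample identifiers are opaque composite strings (site, date,
#' replicate); their ordering is never semantic.
#'
#' @param data A data frame with columns `sample`, `taxon`, `abundance` (long
#'   format) or a wide data frame whose first column is `sample` and remaining
#'   columns are taxa.
#' @param method Sampling method, `"eDNA"` or `"TEF"`.
#' @param unit Abundance unit, `"counts"` or `"percent"`.
#' @param wide Set `TRUE` if `data` is in wide (samples x taxa) layout.
#' @return A validated long tibble with columns `sample`, `taxon`,
#'   `abundance`, `method`, `unit`.
#' @export
#' @examples
#' motu_table(
#'   data.frame(sample = c("s1", "s1", "s2", "s2"),
#'              taxon = c("a", "b", "a", "b"),
#'              abundance = c(10, 30, 5, 0)),
#'   method = "eDNA", unit = "counts"
#' )
motu_table <- function(data, method = c("eDNA", "TEF"),
                       unit = c("counts", "percent"), wide = FALSE) {
  method <- arg_match(method)
  unit <- arg_match(unit)
  data <- as_tibble(data)
  if (wide) {
    data <- tidyr::pivot_longer(data, -1, names_to = "taxon",
                                values_to = "abundance")
    names(data)[1] <- "sample"
  }
  need <- c("sample", "taxon", "abundance")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("motu_table() needs columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    sample = as.character(data$sample),
    taxon = as.character(data$taxon),
    abundance = as.numeric(data$abundance),
    method = method,
    unit = unit
  )
  validate_motu_table(out)
}

#' Validate a MOTU table
#'
#' Checks the MOTU-table contract: required columns, a single method and
#' unit, non-negative finite abundances, no duplicated (sample, taxon) cell,
#' and — for per cent tables — row sums of 100 within a tolerance of 0.5
#' (printed tables are rounded to two decimals).
#'
#' @param x A tibble as returned by [motu_table()].
#' @param percent_tol Allowed deviation of per cent row sums from 100.
#' @return `x`, invisibly valid (errors otherwise).
#' @export
validate_motu_table <- function(x, percent_tol = 0.5) {
  need <- c("sample", "taxon", "abundance", "method", "unit")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Not a MOTU table; missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (length(unique(x$method)) > 1) {
    abort("A MOTU table must have a single method; found mixed methods.")
  }
  if (length(unique(x$unit)) > 1) {
    abort("A MOTU table must have a single unit; found mixed units.")
  }
  bad <- which(!is.finite(x$abundance) | x$abundance < 0)
  if (length(bad) > 0) {
    i <- bad[1]
    abort(sprintf(
      "Invalid abundance %s at (sample '%s', taxon '%s').",
      format(x$abundance[i]), x$sample[i], x$taxon[i]))
  }
  dup <- duplicated(x[c("sample", "taxon")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("Duplicated cell (sample '%s', taxon '%s').",
                  x$sample[i], x$taxon[i]))
  }
  if (nrow(x) > 0 && x$unit[1] == "percent") {
    sums <- x %>% group_by(.data$sample) %>%
      summarise(total = sum(.data$abundance), .groups = "drop")
    off <- filter(sums, abs(.data$total - 100) > percent_tol)
    if (nrow(off) > 0) {
      abort(sprintf(
        "Percent rows must sum to 100 (+/- %g): sample '%s' sums to %.3f.",
        percent_tol, off$sample[1], off$total[1]))
    }
  }
  invisible(x)
}

#' Read a MOTU table from a delimited file
#'
#' Expects a header row of taxon codes and one row per sample, the first
#' column holding sample identifiers. The delimiter is inferred from the file
#' extension (`.csv` comma, `.tsv`/`.txt` tab); decimals use a point. Percent
#' rows that do not close to 100 raise a validation error; they are never
#' silently rescaled.
#'
#' @param path Path to a CSV or TSV file.
#' @inheritParams motu_table
#' @return A validated MOTU tibble.
#' @export
read_motu_table <- function(path, method = c("eDNA", "TEF"),
                            unit = c("counts", "percent")) {
  method <- arg_match(method)
  unit <- arg_match(unit, error_arg = "unit")
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  wide <- switch(ext,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    tsv = ,
    txt = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    abort(sprintf("Cannot infer delimiter from extension '.%s'.", ext))
  )
  motu_table(wide, method = method, unit = unit, wide = TRUE)
}

#' Write a MOTU table to a delimited file
#'
#' Writes the wide (samples x taxa) layout; the delimiter follows the file
#' extension. Counts round-trip exactly; per cent values round-trip to the
#' two decimals they are written with.
#'
#' @param x A MOTU tibble.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_motu_table <- function(x, path) {
  validate_motu_table(x)
  wide <- motu_wide(x)
  if (nrow(wide) > 0 && x$unit[1] == "percent") {
    wide <- mutate(wide, across(-1, ~ round(.x, 2)))
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = readr::write_csv(wide, path),
    tsv = ,
    txt = readr::write_tsv(wide, path),
    abort(sprintf("Cannot infer delimiter from extension '.%s'.", ext))
  )
  invisible(path)
}

#' Pivot a MOTU table to the wide samples-by-taxa layout
#'
#' @param x A MOTU tibble.
#' @param fill Value for absent (sample, taxon) cells.
#' @return A wide tibble, first column `sample`.
#' @export
motu_wide <- function(x, fill = 0) {
  tidyr::pivot_wider(
    select(x, "sample", "taxon", "abundance"),
    names_from = "taxon", values_from = "abundance", values_fill = fill
  )
}
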