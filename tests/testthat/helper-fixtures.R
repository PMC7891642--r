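# Small in-code fixtures shared across test files.

toy_counts <- function(method = "eDNA") {
  motu_table(
    data.frame(sample = c("s1", "s2"), a = c(10, 5), b = c(30, 0),
               c = c(60, 95)),
    wide = TRUE, method = method, unit = "counts"
  )
}

# trait table with disjoint guilds partitioning the toy taxa
disjoint_traits <- function() {
  trait_table(data.frame(taxon = c("a", "b", "c"),
                         guild = c("BEN", "PEL", "RHE")))
}

# quietly run code that emits informational messages
quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# independent brute force over the printed stretch table: per guild/stretch,
# count or sum over detail rows whose guild string contains the code
table2_bruteforce <- function(detail, stretch, guild,
                              unit = c("n-species", "rel-individuals",
                                       "rel-species")) {
  unit <- match.arg(unit)
  motus <- detail[detail$role == "motu", ]
  col <- paste0(stretch, "_edna")
  ab <- motus[[col]]
  ab[is.na(ab)] <- 0
  has_guild <- vapply(strsplit(motus$guilds, ";", fixed = TRUE),
                      function(g) guild %in% g, logical(1))
  present <- ab > 0
  switch(unit,
    "n-species" = sum(present & has_guild),
    "rel-species" = sum(present & has_guild) / sum(present),
    "rel-individuals" = sum(ab[has_guild]) / sum(ab)
  )
}
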