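test_that("discards remove policy taxa, re-close percent rows, and are idempotent", {
  fx <- load_table2_fixture()
  pol <- discard_policy("Abr_bra", "farmed-only")
  out <- quiet(apply_discards(fx$edna, pol))
  expect_false("Abr_bra" %in% out$taxon)
  sums <- tapply(out$abundance, out$sample, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  again <- quiet(apply_discards(out, pol))
  expect_equal(dplyr::select(again, sample, taxon, abundance),
               dplyr::select(out, sample, taxon, abundance),
               ignore_attr = TRUE)
  # empty policy is the identity; absent taxa are no-ops
  expect_equal(apply_discards(fx$edna, discard_policy(character(0))),
               fx$edna, ignore_attr = TRUE)
  expect_equal(quiet(apply_discards(fx$edna, discard_policy("not_here"))),
               fx$edna, ignore_attr = TRUE)
  # discarding everything empties the table with a warning
  x <- toy_counts()
  expect_warning(quiet2 <- apply_discards(x, discard_policy(c("a", "b", "c"))),
                 "empty")
  expect_equal(nrow(quiet2), 0)
})

test_that("MOTU trait resolution follows uniform, dominant and excluded rules", {
  traits <- trait_table(data.frame(
    taxon = c("sp1", "sp1", "sp2", "sp2", "sp3"),
    guild = c("BEN", "RHE", "BEN", "RHE", "PEL")))
  # all members share a profile
  r <- resolve_motu_traits("M1", c("sp1", "sp2"), traits)
  expect_equal(r$rule, "uniform-profile")
  expect_setequal(r$profile, c("BEN", "RHE"))
  # one member dominates the reference catch
  catch <- motu_table(data.frame(sample = "c1", sp1 = 96, sp3 = 4),
                      wide = TRUE, method = "TEF", unit = "counts")
  r <- resolve_motu_traits("M2", c("sp1", "sp3"), traits,
                           reference_catch = catch)
  expect_equal(r$rule, "dominant-95")
  expect_equal(r$dominant_species, "sp1")
  expect_setequal(r$profile, c("BEN", "RHE"))
  # a 60/40 split with differing profiles is excluded
  catch2 <- motu_table(data.frame(sample = "c1", sp1 = 60, sp3 = 40),
                       wide = TRUE, method = "TEF", unit = "counts")
  r <- resolve_motu_traits("M3", c("sp1", "sp3"), traits,
                           reference_catch = catch2)
  expect_equal(r$rule, "excluded")
  expect_null(r$profile)
  expect_equal(r$dominant_share, 0.6)
  # missing member species are named
  expect_error(resolve_motu_traits("M4", c("sp1", "ghost"), traits),
               "ghost")
})

test_that("replicate pooling sums counts and keeps provenance", {
  x <- motu_table(data.frame(sample = c("r1", "r2"), a = c(3, 3), b = c(1, 1)),
                  wide = TRUE, method = "eDNA", unit = "counts")
  pooled <- pool_replicates(x, data.frame(sample = c("r1", "r2"), group = "g"))
  expect_equal(sort(pooled$abundance), c(2, 6))
  expect_equal(attr(pooled, "provenance")$replicates[[1]], c("r1", "r2"))
  # single-replicate group passes counts through
  one <- pool_replicates(x, data.frame(sample = "r1", group = "g1"))
  expect_equal(motu_wide(one)[-1], motu_wide(x)[1, -1])
  # a chosen pair out of many replicates (hand-computed on a 3-taxon toy)
  reps <- motu_table(
    data.frame(sample = paste0("r", 1:10), a = 1:10, b = 10:1, c = rep(2, 10)),
    wide = TRUE, method = "eDNA", unit = "counts")
  pair <- pool_replicates(reps, data.frame(sample = c("r3", "r7"), group = "p"))
  w <- motu_wide(pair)
  expect_equal(c(w$a, w$b, w$c), c(3 + 7, 8 + 4, 2 + 2))
  # percent tables cannot be pooled
  expect_error(pool_replicates(to_relative(x),
                               data.frame(sample = "r1", group = "g")),
               "count-unit")
})

test_that("relative conversion closes rows to 100 by largest remainder", {
  x <- motu_table(data.frame(sample = "s", a = 25, b = 75), wide = TRUE,
                  method = "TEF", unit = "counts")
  expect_equal(to_relative(x)$abundance, c(25, 75))
  one <- motu_table(data.frame(sample = "s", a = 7), wide = TRUE,
                    method = "TEF", unit = "counts")
  expect_equal(to_relative(one)$abundance, 100)
  # (1,1,1): enumeration shows the only 2-decimal closure to 100 compatible
  # with largest-remainder (tie to the earlier element) is 33.34/33.33/33.33
  thirds <- motu_table(data.frame(sample = "s", a = 1, b = 1, c = 1),
                       wide = TRUE, method = "TEF", unit = "counts")
  expect_equal(to_relative(thirds)$abundance, c(33.34, 33.33, 33.33))
  expect_equal(sum(to_relative(thirds)$abundance), 100)
  # invariance to uniform scaling of a row
  y10 <- motu_table(data.frame(sample = "s", a = 10, b = 10, c = 10),
                    wide = TRUE, method = "TEF", unit = "counts")
  expect_equal(to_relative(y10)$abundance, to_relative(thirds)$abundance)
  # zero-total rows are named
  z <- motu_table(data.frame(sample = c("ok", "zero"), a = c(1, 0)),
                  wide = TRUE, method = "TEF", unit = "counts")
  expect_error(to_relative(z), "zero")
})

test_that("largest-remainder rounding preserves totals on random simplexes", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    p <- as.vector(stats::rmultinom(1, 1000, runif(n))) / 1000 * 100
    r <- largest_remainder_round(p, digits = 2)
    expect_equal(sum(r), 100)
    expect_true(all(abs(r - p) < 0.01 + 1e-9))
  }
})
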