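test_that("guild metrics handle single-taxon, empty-guild and known fixture cases", {
  one <- motu_table(data.frame(sample = "s", a = 42), wide = TRUE,
                    method = "eDNA", unit = "counts")
  tr <- trait_table(data.frame(taxon = "a", guild = "PEL"))
  expect_equal(guild_metric(one, "s", "PEL", "rel-individuals", tr), 1)
  expect_equal(guild_metric(one, "s", "BEN", "n-species", tr), 0)
  expect_error(guild_metrics(one, tr, guilds = "NOPE"), "Unknown guild")

  fx <- load_table2_fixture()
  # potamodromous species detected by eDNA in stretch A: Bar_bab, Eso_luc,
  # Sal_tru, Squ_cep, Thy_thy, Leu_spp, Cypr_1
  expect_equal(guild_metric(fx$edna, "RS_A", "POT", "n-species", fx$traits), 7)
})

test_that("guild metrics agree with a spreadsheet-style brute force on the fixture", {
  fx <- load_table2_fixture()
  vals <- guild_metrics(fx$edna, fx$traits)
  for (g in comparison_guilds()) {
    for (s in c("A", "B", "C", "D", "E")) {
      for (u in c("n-species", "rel-species", "rel-individuals")) {
        got <- vals$value[vals$sample == paste0("RS_", s) &
                            vals$guild == g & vals$unit == u]
        expect_equal(got, table2_bruteforce(fx$detail, s, g, u),
                     tolerance = 1e-12,
                     label = paste(g, s, u))
      }
    }
  }
})

test_that("relative-individual metrics over a disjoint guild partition sum to 1", {
  x <- toy_counts()
  vals <- guild_metrics(x, disjoint_traits(), units = "rel-individuals")
  sums <- tapply(vals$value, vals$sample, sum)
  expect_equal(as.numeric(sums), c(1, 1))
})

test_that("guild richness is monotone under adding taxa", {
  tr <- trait_table(data.frame(taxon = c("a", "b", "c"), guild = "BEN"))
  base <- motu_table(data.frame(sample = "s", a = 1), wide = TRUE,
                     method = "eDNA", unit = "counts")
  grown <- motu_table(data.frame(sample = "s", a = 1, b = 2, c = 3),
                      wide = TRUE, method = "eDNA", unit = "counts")
  expect_lte(guild_metric(base, "s", "BEN", "n-species", tr),
             guild_metric(grown, "s", "BEN", "n-species", tr))
})

test_that("index metric vector has the registry order and a six-metric subset", {
  pool <- synthetic_species_pool()
  fx <- load_table2_fixture()
  mv <- quiet(index_metric_vector(fx$edna, pool$traits, variant = "10FI"))
  expect_equal(unique(mv$metric[mv$sample == "RS_A"]),
               index_metric_registry("10FI")$metric)
  m6 <- quiet(index_metric_vector(fx$edna, pool$traits, variant = "6FI"))
  expect_equal(nrow(dplyr::filter(m6, sample == "RS_A")), 6)
  expect_false(any(m6$unit == "n-species"))
  # saturation: every taxon tolerant means the tolerant count equals richness
  x <- toy_counts()
  tr_all <- trait_table(data.frame(taxon = c("a", "b", "c"), guild = "TOL-i"))
  tol <- guild_metrics(x, tr_all, guilds = "TOL-i", units = "n-species")
  expect_equal(tol$value[tol$sample == "s1"], 3)
  # an empty sample leaves relative metrics undefined
  empty <- motu_table(data.frame(sample = "s", Rut_rut = 0), wide = TRUE,
                      method = "eDNA", unit = "counts")
  expect_error(quiet(index_metric_vector(empty, pool$traits)), "undefined")
  # a trait table without the index guilds is rejected with the gaps listed
  expect_error(index_metric_vector(fx$edna, fx$traits), "STEN")
})

test_that("accumulation curve matches exhaustive enumeration and vegan", {
  camp <- motu_table(
    data.frame(sample = c("c1", "c2", "c3"),
               a = c(1, 0, 0), b = c(1, 1, 0), c = c(0, 1, 0), d = c(0, 0, 1)),
    wide = TRUE, method = "TEF", unit = "counts")
  sets <- list(c1 = c("a", "b"), c2 = c("b", "c"), c3 = "d")
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  exhaustive <- sapply(1:3, function(k) {
    mean(sapply(perms, function(p)
      length(unique(unlist(sets[p[seq_len(k)]])))))
  })
  ac <- accumulation_curve(camp, n_perm = 600, seed = 9)
  expect_equal(ac$mean_richness[3], exhaustive[3])     # endpoint is exact
  expect_equal(ac$mean_richness, exhaustive, tolerance = 0.05)
  expect_true(all(diff(ac$mean_richness) >= 0))
  # single campaign: the curve is that campaign's richness
  ac1 <- accumulation_curve(dplyr::filter(camp, sample == "c1"),
                            n_perm = 5, seed = 1)
  expect_equal(ac1$mean_richness, 2)

  set.seed(31)
  wide <- matrix(rpois(6 * 15, 0.8), nrow = 6)
  colnames(wide) <- paste0("t", 1:15)
  camp2 <- motu_table(
    data.frame(sample = paste0("c", 1:6), wide, check.names = FALSE),
    wide = TRUE, method = "TEF", unit = "counts")
  exact <- vegan::specaccum(wide, method = "exact")$richness
  ac2 <- accumulation_curve(camp2, n_perm = 1500, seed = 7)
  expect_equal(ac2$mean_richness, exact, tolerance = 0.05)
})

test_that("two accumulation runs with one seed are identical", {
  camp <- toy_counts()
  a <- accumulation_curve(camp, n_perm = 50, seed = 123)
  b <- accumulation_curve(camp, n_perm = 50, seed = 123)
  expect_equal(a, b)
})
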