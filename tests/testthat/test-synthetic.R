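test_that("generators are deterministic under a fixed seed", {
  a <- generate_reference_sites(60, seed = 4)
  b <- generate_reference_sites(60, seed = 4)
  expect_equal(a$env, b$env)
  expect_equal(a$metrics, b$metrics)
  expect_equal(a$communities, b$communities)
  com <- dplyr::filter(a$communities, site == "site_1")
  e1 <- simulate_edna(com, sampling_config(), seed = 10)
  e2 <- simulate_edna(com, sampling_config(), seed = 10)
  expect_equal(e1, e2)
  expect_error(generate_reference_sites(10, seed = 1), "n >= 50")
})

test_that("generated tables pass the package validators", {
  ref <- generate_reference_sites(60, seed = 12)
  expect_silent(validate_env_descriptors(ref$env))
  shares <- tapply(ref$communities$share, ref$communities$site, sum)
  expect_true(all(abs(shares - 1) < 1e-9))
  com <- dplyr::filter(ref$communities, site %in% paste0("site_", 1:3))
  expect_silent(validate_motu_table(simulate_edna(com, sampling_config(), seed = 2)))
  expect_silent(validate_motu_table(
    simulate_tef(com, sampling_config(), seed = 2)))
  reg <- index_metric_registry("10FI")
  counts <- as.matrix(ref$metrics[reg$metric[reg$unit == "n-species"]])
  expect_true(all(counts >= 0 & counts == round(counts)))
  props <- as.matrix(ref$metrics[reg$metric[reg$unit != "n-species"]])
  expect_true(all(props > 0 & props < 1))
})

test_that("disturbance is the identity at d = 0 and inflates tolerant shares at d = 1", {
  pool <- synthetic_species_pool()
  ref <- generate_reference_sites(60, seed = 13, pool = pool)
  com <- dplyr::filter(ref$communities, site %in% paste0("site_", 1:10))
  expect_equal(apply_disturbance(com, 0, pool$traits), com)
  hit <- apply_disturbance(com, 1, pool$traits)
  tol_share <- function(cm) {
    m <- guild_metrics(
      motu_table(dplyr::transmute(cm, sample = site, taxon,
                                  abundance = share * 1e6),
                 method = "eDNA", unit = "counts"),
      pool$traits, guilds = "TOL", units = "rel-individuals")
    setNames(m$value, m$sample)
  }
  expect_true(all(tol_share(hit) > tol_share(com)))
  expect_error(apply_disturbance(com, 1.5, pool$traits), "0, 1")
})

test_that("unbiased high-effort sampling converges to the truth shares", {
  pool <- synthetic_species_pool()
  ref <- generate_reference_sites(60, seed = 14, pool = pool)
  com <- dplyr::filter(ref$communities, site == "site_2")
  null_cfg <- sampling_config(pelagic_boost = 1, benthic_penalty = 1,
                              tef_effort_min = 2e5,
                              edna_depth = 1e6, edna_overdispersion = 0,
                              edna_replicates = 1)
  tef <- simulate_tef(com, null_cfg, seed = 3, traits = pool$traits)
  tef_shares <- tef$abundance / sum(tef$abundance)
  expect_true(all(abs(tef_shares - com$share) < 0.005))
  ed <- simulate_edna(com, null_cfg, seed = 4)
  ed_shares <- ed$abundance / sum(ed$abundance)
  expect_true(all(abs(ed_shares - com$share) < 0.005))
})

test_that("degenerate sampling configurations warn and return empty samples", {
  pool <- synthetic_species_pool()
  ref <- generate_reference_sites(60, seed = 15, pool = pool)
  com <- dplyr::filter(ref$communities, site == "site_1")
  expect_warning(z <- simulate_tef(com, sampling_config(tef_effort_min = 0),
                                   seed = 1, traits = pool$traits),
                 "effort")
  expect_equal(sum(z$abundance), 0)
  expect_warning(ze <- simulate_edna(com, sampling_config(edna_depth = 0),
                                     seed = 1),
                 "depth")
  expect_equal(sum(ze$abundance), 0)
  expect_error(sampling_config(pelagic_boost = 0), "positive")
})

test_that("shoreline bias inflates the pelagic share and deflates the benthic share", {
  pool <- synthetic_species_pool()
  ref <- generate_reference_sites(60, seed = 16, pool = pool)
  com <- dplyr::filter(ref$communities, site == "site_3")
  truth <- motu_table(dplyr::transmute(com, sample = site, taxon,
                                       abundance = share * 1e6),
                      method = "TEF", unit = "counts")
  tm <- guild_metrics(truth, pool$traits, guilds = c("PEL", "BEN"),
                      units = "rel-individuals")
  t_pel <- tm$value[tm$guild == "PEL"]
  t_ben <- tm$value[tm$guild == "BEN"]
  hits <- vapply(1:50, function(s) {
    tef <- simulate_tef(com, sampling_config(), seed = 500 + s,
                        traits = pool$traits)
    m <- guild_metrics(tef, pool$traits, guilds = c("PEL", "BEN"),
                       units = "rel-individuals")
    c(m$value[m$guild == "PEL"] > t_pel, m$value[m$guild == "BEN"] < t_ben)
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.95)
  expect_gte(mean(hits[2, ]), 0.95)
})
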