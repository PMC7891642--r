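test_that("EQR follows the oriented probability transform of the link residual", {
  # exact agreement scores 0.5 whatever the orientation
  expect_equal(compute_eqr(0.2, 0.2, 0.5, "decreases", "rel-individuals"), 0.5)
  expect_equal(compute_eqr(0.2, 0.2, 0.5, "increases", "rel-individuals"), 0.5)
  expect_equal(compute_eqr(4, 4, 0.3, "decreases", "n-species"), 0.5)
  # three-sigma departure below expectation hits the 0.001 floor region
  sg <- 0.6
  obs <- plogis(qlogis(0.3) - 3 * sg)
  e <- compute_eqr(obs, 0.3, sg, "decreases", "rel-individuals")
  expect_equal(e, max(pnorm(-3), 0.001), tolerance = 1e-6)
  # orientation symmetry: increases mirrors decreases around 0.5
  e_dec <- compute_eqr(obs, 0.3, sg, "decreases", "rel-individuals")
  e_inc <- compute_eqr(obs, 0.3, sg, "increases", "rel-individuals")
  expect_equal(e_dec + e_inc, 1, tolerance = 1e-6)
  # monotone in the observed value (and reversed for increases)
  grid <- seq(0.01, 0.99, by = 0.01)
  eqr_dec <- compute_eqr(grid, 0.4, sg, "decreases", "rel-species")
  eqr_inc <- compute_eqr(grid, 0.4, sg, "increases", "rel-species")
  expect_true(all(diff(eqr_dec) >= 0))
  expect_true(all(diff(eqr_inc) <= 0))
  expect_true(all(eqr_dec >= 0.001 & eqr_dec <= 0.999))
  expect_error(compute_eqr(1.2, 0.4, sg, "decreases", "rel-species"), "0, 1")
})

test_that("index aggregation averages the k lowest EQRs deterministically", {
  expect_equal(aggregate_index(c(a = 0.2, b = 0.4, c = 0.6, d = 0.8), k = 2), 0.3)
  expect_equal(aggregate_index(c(a = 0.9, b = 0.1, c = 0.5), k = 1), 0.1)
  expect_equal(aggregate_index(rep(0.37, 6)), 0.37)
  # default k is the lowest half (3 of 6, 5 of 10)
  e6 <- setNames(seq(0.1, 0.6, by = 0.1), letters[1:6])
  expect_equal(aggregate_index(e6), mean(c(0.1, 0.2, 0.3)))
  e10 <- setNames(seq(0.05, 0.5, by = 0.05), letters[1:10])
  expect_equal(aggregate_index(e10), mean(e10[1:5]))
  # ties at the cut resolve by metric name, reproducibly
  tied <- c(z = 0.2, a = 0.2, m = 0.9)
  expect_equal(aggregate_index(tied, k = 2), 0.2)
  expect_error(aggregate_index(numeric(0)), "empty")
})

test_that("classification uses closed lower bounds and a good/degraded dichotomy", {
  b <- default_boundaries()
  expect_equal(as.character(classify_status(1, b)$class), "High")
  expect_equal(as.character(classify_status(0.6, b)$class), "Good")
  expect_equal(as.character(classify_status(0.59, b)$class), "Moderate")
  expect_equal(classify_status(0.59, b)$dichotomy, "degraded")
  expect_equal(as.character(classify_status(0.05, b)$class), "Bad")
  grid <- classify_status(seq(0, 1, by = 0.01), b)
  expect_false(any(is.na(grid$class)))
  expect_equal(grid$dichotomy == "good",
               as.character(grid$class) %in% c("Good", "High"))
  expect_error(classify_status(0.5, c(high = 0.4, good = 0.6,
                                      moderate = 0.3, poor = 0.1)),
               "decreasing")
})

test_that("reference fitting enforces its preconditions and flags degeneracy", {
  env <- sample_env_descriptors(5, seed = 1)
  dat <- dplyr::bind_cols(env, as.data.frame(
    setNames(as.list(rep(1, 10)), index_metric_registry("10FI")$metric)))
  expect_error(fit_reference_models(dat), "Under-determined")
  # constant metric across sites is flagged degenerate
  ref <- generate_reference_sites(150, seed = 3)
  dat2 <- dplyr::left_join(ref$env, ref$metrics, by = "site")
  dat2$oxy_rab <- 0.25
  # the constant metric also triggers lm's perfect-fit warning; collect both
  w <- capture_warnings(m <- fit_reference_models(dat2))
  expect_match(w, "Degenerate", all = FALSE)
  expect_true(glance(m)$degenerate[glance(m)$metric == "oxy_rab"])
  # non-integer counts rejected for count metrics
  dat3 <- dplyr::left_join(ref$env, ref$metrics, by = "site")
  dat3$sten_nsp <- dat3$sten_nsp + 0.5
  expect_error(fit_reference_models(dat3), "integer")
})

test_that("fitting recovers the generating coefficients on synthetic reference sites", {
  beta <- default_reference_coefficients()
  ref <- generate_reference_sites(500, beta = beta, seed = 21)
  dat <- dplyr::left_join(ref$env, ref$metrics, by = "site")
  m <- fit_reference_models(dat)
  td <- tidy(m)
  truth <- tibble::tibble(
    metric = rep(colnames(beta), each = nrow(beta)),
    term = rep(rownames(beta), ncol(beta)),
    true = as.vector(beta))
  cmp <- dplyr::inner_join(td, truth, by = c("metric", "term"))
  expect_equal(nrow(cmp), 110)
  expect_gte(mean(abs(cmp$estimate - cmp$true) <= 2 * cmp$std_error), 0.9)
})

test_that("the assessment is invariant to uniform read-depth scaling (6FI)", {
  pool <- synthetic_species_pool()
  ref <- generate_reference_sites(150, seed = 5, pool = pool)
  obs <- quiet(observe_edna_metrics(ref$communities, pool$traits,
                                    sampling_config(), seed = 6))
  dat <- dplyr::left_join(ref$env, obs$metrics, by = "site")
  models <- fit_reference_models(dat)
  sub <- dplyr::filter(obs$pooled, sample %in% paste0("site_", 1:5))
  env5 <- dplyr::filter(ref$env, site %in% paste0("site_", 1:5))
  a1 <- quiet(edna_fish_index(sub, pool$traits, models, env5, variant = "6FI"))
  scaled <- dplyr::mutate(sub, abundance = abundance * 7)
  a2 <- quiet(edna_fish_index(scaled, pool$traits, models, env5, variant = "6FI"))
  expect_equal(a1$score, a2$score)
  expect_true(all(a1$score >= 0 & a1$score <= 1))
  # the 6FI audit trail holds exactly six metrics, none a species count
  aud <- a1$audit[[1]]
  expect_equal(nrow(aud), 6)
  expect_false(any(aud$unit == "n-species"))
})

test_that("boundary calibration sets decreasing quantile-based boundaries", {
  set.seed(8)
  scores <- runif(400, 0.05, 0.9)
  b <- calibrate_class_boundaries(scores)
  expect_equal(unname(b["high"]), unname(quantile(scores, 0.25)))
  expect_equal(unname(b["good"]), unname(quantile(scores, 0.01)))
  expect_true(all(diff(b) < 0))
  expect_error(calibrate_class_boundaries(runif(5)), "at least 20")
})
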