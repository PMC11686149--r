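test_that("sim_params validates its ranges", {
  expect_error(sim_params(n_sites = 1), "n_sites")
  expect_error(sim_params(n_sources = 1), "n_sources")
  expect_error(sim_params(exact_dup_rate = 1), "exact_dup_rate")
  expect_error(sim_params(dogs_per_capita_halfsat = 0), "halfsat")
  expect_error(sim_params(microchip_coverage = 1.2), "microchip_coverage")
  expect_error(generate_geography(sim_params(n_sites = 2, seed = 1)), NA)
})

test_that("generation is deterministic under a fixed seed", {
  p <- sim_params(n_sites = 8, n_sources = 3, seed = 123)
  g1 <- generate_geography(p); g2 <- generate_geography(p)
  expect_identical(g1, g2)
  t1 <- simulate_truth(g1, p); t2 <- simulate_truth(g2, p)
  expect_identical(t1$N, t2$N)
  expect_identical(t1$roster, t2$roster)
  s1 <- emit_source_tables(t1, p); s2 <- emit_source_tables(t2, p)
  expect_identical(s1$tables, s2$tables)
})

test_that("geography has unique codes, positive populations, >=2 regions and countries", {
  geo <- generate_geography(sim_params(n_sites = 124, seed = 5))
  expect_equal(nrow(geo), 124)
  expect_false(any(duplicated(geo$area)))
  expect_true(all(nchar(geo$area) %in% 1:2))
  expect_true(all(geo$human_population > 0))
  expect_gte(length(unique(geo$region)), 2)
  expect_gte(length(unique(geo$country)), 2)
})

test_that("dogs-per-capita curve saturates at the asymptote", {
  expect_equal(dogs_per_capita_curve(1e12, 0.25, 1000), 0.25, tolerance = 1e-8)
  expect_lt(dogs_per_capita_curve(1000, 0.25, 1000), 0.25)  # halfway at halfsat
  expect_equal(dogs_per_capita_curve(1000, 0.25, 1000), 0.125)
})

test_that("saturated detection intercepts give p above 0.999 everywhere", {
  p <- sim_params(n_sites = 6, n_sources = 3, alpha_mean = 10, alpha_sd = 0,
                  beta_mean = 0, beta_sd = 0, seed = 2)
  tr <- simulate_truth(generate_geography(p), p)
  expect_true(all(tr$p > 0.999))
})

test_that("site abundances are Poisson draws around lambda", {
  p <- sim_params(n_sites = 200, n_sources = 2, seed = 31)
  tr <- simulate_truth(generate_geography(p), p)
  se <- sqrt(sum(tr$lambda)) / length(tr$lambda)
  expect_lt(abs(mean(tr$N) - mean(tr$lambda)), 3 * se)
})

test_that("perfect detection with no noise reproduces the roster exactly", {
  p <- sim_params(n_sites = 4, n_sources = 3, alpha_mean = 15, alpha_sd = 0,
                  beta_mean = 0, beta_sd = 0, exact_dup_rate = 0,
                  missing_field_rates = c(), breed_typo_rate = 0,
                  microchip_coverage = 1, human_pop_log_mean = log(300),
                  seed = 9)
  tr <- simulate_truth(generate_geography(p), p)
  st <- emit_source_tables(tr, p)
  comb <- combine_sources(st)
  expect_equal(nrow(comb), p$n_sources * sum(tr$N))
  # mean detections per dog equals the number of sources
  expect_equal(nrow(comb) / data.table::uniqueN(comb$true_id), p$n_sources)
  # fields match roster values exactly
  m <- merge(comb, tr$roster, by = "true_id", suffixes = c("", ".ros"))
  expect_true(all(m$sex == m$sex.ros))
  expect_true(all(m$dob == m$dob.ros))
  expect_true(all(m$postcode_area == m$area))
  expect_true(all(m$chip_suffix == m$chip_suffix.ros))
  expect_true(all(m$breed_raw == ifelse(is.na(m$cross_text),
                                        m$breed_canonical, m$cross_text)))
})

test_that("distinct hidden labels never exceed the true population", {
  for (s in c(3, 14)) {
    p <- sim_params(n_sites = 10, n_sources = 4, seed = s,
                    human_pop_log_mean = log(400))
    tr <- simulate_truth(generate_geography(p), p)
    comb <- combine_sources(emit_source_tables(tr, p))
    expect_lte(data.table::uniqueN(comb$true_id), sum(tr$N))
  }
})

test_that("empirical per-source detection fractions converge to p at large N", {
  p <- sim_params(n_sites = 2, n_sources = 3,
                  human_pop_log_mean = log(1e5), human_pop_log_sd = 0.01,
                  seed = 17)
  tr <- simulate_truth(generate_geography(p), p)
  expect_true(all(tr$N >= 1e4))
  det_frac <- colSums(tr$detections[tr$roster$site_idx == 1, ]) / tr$N[1]
  tol <- 4 * sqrt(tr$p[1, ] * (1 - tr$p[1, ]) / tr$N[1])
  expect_true(all(abs(det_frac - tr$p[1, ]) < tol))
})

test_that("default calibration yields about 2.8 detections per detected dog", {
  ratios <- vapply(1:6, function(s) {
    p <- sim_params(seed = s)
    tr <- simulate_truth(generate_geography(p), p)
    det <- rowSums(tr$detections)
    mean(det[det > 0])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2.8), 0.2)
})

test_that("invalid missingness rates are rejected at emission", {
  w <- small_world()
  p <- w$params
  p$missing_field_rates <- c(sex = 1.2)
  expect_error(emit_source_tables(w$truth, p), "missing_field_rates")
})
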