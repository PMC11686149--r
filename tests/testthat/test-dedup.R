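test_that("phase 1 collapses byte-identical rows only above the completeness bar", {
  # two identical rows with 12+ populated fields collapse
  r <- make_records(list(record_id = "R001", chip_suffix = "111111"),
                    list(record_id = "R001", chip_suffix = "111111"),
                    list(record_id = "R003", chip_suffix = "222222"))
  lk <- dedup_records(r, phases = "exact")
  expect_equal(unname(lk$phase_counts["exact"]), 1L)
  expect_equal(lk$n_clusters, 2L)

  # identical rows with only 9 populated fields are left alone
  sparse <- list(record_id = "R001", breed_raw = NA_character_,
                 crossbred_flag = NA_character_, dob = NA_character_,
                 name_prefix = NA_character_, longevity = NULL,
                 age_group = NA_character_, region = NA_character_,
                 country = NA_character_, purebred_flag = NA_character_)
  sparse$longevity <- NA_real_
  r2 <- make_records(sparse, sparse)
  state <- dogpop:::init_linkage_state(r2)
  expect_true(all(state$work$nonmiss <= 10))
  lk2 <- dedup_records(r2, phases = "exact")
  expect_equal(unname(lk2$phase_counts["exact"]), 0L)
})

test_that("phase 1 removes exactly the injected exact duplicates", {
  w <- small_world()
  lk <- dedup_records(w$clean, phases = "exact")
  injected <- nrow(w$comb) -
    nrow(unique(w$comb[, dogpop:::SCHEMA_FIELDS, with = FALSE]))
  expect_equal(unname(lk$phase_counts["exact"]), injected)
})

test_that("phase 2 merges on shared chips unless sex or DOB conflict", {
  r <- make_records(
    list(record_id = "A1", source_id = "SRC01", chip_suffix = "123456"),
    list(record_id = "A2", source_id = "SRC02", chip_suffix = "123456"),
    list(record_id = "B1", source_id = "SRC01", chip_suffix = "654321",
         sex = "M"),
    list(record_id = "B2", source_id = "SRC02", chip_suffix = "654321",
         sex = "F"),
    list(record_id = "C1", source_id = "SRC03"))
  lk <- dedup_records(r, phases = c("exact", "microchip"))
  expect_equal(unname(lk$phase_counts["microchip"]), 1L)
  expect_equal(lk$conflicts$microchip, 1L)
  cl <- lk$clusters
  expect_equal(cl[record_id == "A1", cluster_id],
               cl[record_id == "A2", cluster_id])
  expect_false(cl[record_id == "B1", cluster_id] ==
                 cl[record_id == "B2", cluster_id])
  # chipless record untouched: a singleton cluster
  expect_equal(sum(cl$cluster_id == cl[record_id == "C1", cluster_id]), 1L)
})

test_that("phase 3 merges on the key quadruple within a postcode-area block", {
  r <- make_records(
    list(record_id = "A1", source_id = "SRC01", postcode_area = "AB"),
    list(record_id = "A2", source_id = "SRC02", postcode_area = "AB"),
    list(record_id = "A3", source_id = "SRC03", postcode_area = "CD"),
    list(record_id = "D1", source_id = "SRC01", dob = NA_character_,
         postcode_area = "AB"))
  lk <- dedup_records(r, phases = c("exact", "keys"))
  cl <- lk$clusters
  expect_equal(cl[record_id == "A1", cluster_id],
               cl[record_id == "A2", cluster_id])
  # same quadruple, different area: blocked
  expect_false(cl[record_id == "A3", cluster_id] ==
                 cl[record_id == "A1", cluster_id])
  # missing key: deferred from phase 3, still a singleton
  expect_equal(sum(cl$cluster_id == cl[record_id == "D1", cluster_id]), 1L)
})

test_that("phase 4 merges three-of-four keys and counts unresolved records", {
  r <- make_records(
    list(record_id = "A1", source_id = "SRC01"),
    list(record_id = "A2", source_id = "SRC02", dob = NA_character_),
    list(record_id = "U1", source_id = "SRC03", dob = NA_character_,
         sex = NA_character_, name_prefix = "ZZZ"))
  lk <- dedup_records(r)
  cl <- lk$clusters
  expect_equal(cl[record_id == "A1", cluster_id],
               cl[record_id == "A2", cluster_id])
  # two missing keys: singleton, counted unresolved
  expect_equal(sum(cl$cluster_id == cl[record_id == "U1", cluster_id]), 1L)
  expect_equal(lk$unresolved_fraction, 1 / 3)
})

test_that("phase 4 does not merge against conflicting chip evidence", {
  r <- make_records(
    list(record_id = "A1", source_id = "SRC01", chip_suffix = "111111"),
    list(record_id = "A2", source_id = "SRC02", dob = NA_character_,
         chip_suffix = "999999"))
  lk <- dedup_records(r)
  expect_equal(lk$n_clusters, 2L)
})

test_that("deduplication is monotone and order-invariant", {
  p <- sim_params(n_sites = 8, n_sources = 4, exact_dup_rate = 0, seed = 21,
                  human_pop_log_mean = log(400))
  tr <- simulate_truth(generate_geography(p), p)
  st <- emit_source_tables(tr, p)
  cl <- clean_records(st, generate_geography(p))
  lk <- dedup_records(cl)
  expect_lte(lk$n_clusters, lk$n_records)
  expect_equal(sum(lk$phase_counts), lk$n_records - lk$n_clusters)

  # permuted input yields the same partition (as record-id sets)
  perm <- cl[sample.int(nrow(cl))]
  perm[, .row := seq_len(.N)]
  lk2 <- dedup_records(perm)
  part <- function(x) {
    sets <- split(x$clusters$record_id, x$clusters$cluster_id)
    sort(vapply(sets, function(s) paste(sort(s), collapse = "|"), ""))
  }
  expect_equal(unname(part(lk)), unname(part(lk2)))
})

test_that("the count matrix attributes individuals to every source that saw them", {
  r <- make_records(
    list(record_id = "A1", source_id = "SRC01", chip_suffix = "123456"),
    list(record_id = "A2", source_id = "SRC02", chip_suffix = "123456"),
    list(record_id = "A3", source_id = "SRC03", chip_suffix = "123456"))
  lk <- dedup_records(r)
  expect_equal(lk$n_clusters, 1L)
  y <- build_count_matrix(lk, toy_geo())
  expect_equal(sum(y["AB", ]), 3)
  expect_equal(unname(y["AB", c("SRC01", "SRC02", "SRC03")]), c(1L, 1L, 1L))
  # unknown area is an error naming the offending code
  bad_geo <- toy_geo()[toy_geo()$area != "AB", ]
  expect_error(build_count_matrix(lk, bad_geo), "AB")
})

test_that("perfect detection with no noise saturates the count matrix", {
  p <- sim_params(n_sites = 4, n_sources = 3, alpha_mean = 15, alpha_sd = 0,
                  beta_mean = 0, beta_sd = 0, exact_dup_rate = 0,
                  missing_field_rates = c(), breed_typo_rate = 0,
                  microchip_coverage = 1, human_pop_log_mean = log(300),
                  seed = 9)
  geo <- generate_geography(p)
  tr <- simulate_truth(geo, p)
  cl <- clean_records(emit_source_tables(tr, p), geo)
  lk <- dedup_records(cl)
  y <- build_count_matrix(lk, geo)
  expect_equal(unname(y[geo$area, ]),
               matrix(tr$N, nrow(geo), p$n_sources), ignore_attr = TRUE)
})

test_that("per-source mode counts records surviving phase 1", {
  w <- small_world()
  lk <- dedup_records(w$clean)
  y1 <- build_count_matrix(lk, w$geo, mode = "per-source")
  expect_equal(sum(y1), lk$n_records - unname(lk$phase_counts["exact"]))
  y2 <- build_count_matrix(lk, w$geo)
  # attributed counts each individual once per source, so never more mass
  expect_lte(sum(y2), sum(y1))
})

test_that("linkage metrics are near-perfect on the small synthetic world", {
  w <- small_world()
  lk <- dedup_records(w$clean)
  m <- linkage_metrics(lk, w$comb)
  expect_gte(m$precision, 0.99)
  expect_gte(m$recall, 0.95)
})
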