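test_that("breed normalisation resolves crosses, case, and near-misses", {
  expect_equal(normalize_breed("Cocker Spaniel X Poodle", "Y"),
               data.frame(breed_canonical = "Cockerpoo",
                          lineage = "crossbred"))
  expect_equal(normalize_breed("labrador retriever", "N")$breed_canonical,
               "Labrador Retriever")
  expect_equal(normalize_breed("labrador retriever", "N")$lineage, "purebred")
  # single-character misspelling resolves through the edit-distance-1 match
  expect_equal(normalize_breed("Labrodor Retriever", "N")$breed_canonical,
               "Labrador Retriever")
  # alias collapsing
  expect_equal(normalize_breed("Alsatian", "N")$breed_canonical,
               "German Shepherd")
  # cross/type suffix
  r <- normalize_breed("Border Collie Cross", "Y")
  expect_equal(r$breed_canonical, "Border Collie cross/type")
  expect_equal(r$lineage, "crossbred")
  # more than two parental breeds -> Mix Breed
  expect_equal(normalize_breed("Poodle x Pug x Beagle", "Y")$breed_canonical,
               "Mix Breed")
  # unknown lineage -> Mix Breed; claimed-pure gibberish -> Unclassified
  expect_equal(normalize_breed("zzzzqqq", "unknown")$lineage, "mixbreed")
  expect_equal(normalize_breed("zzzzqqq", "N")$breed_canonical, "Unclassified")
})

test_that("breed normalisation is idempotent on canonical names", {
  attrs <- breed_attributes()
  again <- normalize_breed(attrs$breed, "N")
  expect_equal(again$breed_canonical, attrs$breed)
  crosses <- named_crosses()
  expect_equal(normalize_breed(crosses$cross, "Y")$breed_canonical,
               crosses$cross)
  expect_equal(normalize_breed("Mix Breed", "Y")$breed_canonical, "Mix Breed")
})

test_that("decimal age uses mid-month DOB and the right endpoint", {
  expect_equal(compute_age("2019-06", "alive", NA, as.Date("2019-06-15")), 0)
  # calendar oracle: 2007-01-15 .. 2019-12-31
  oracle <- as.numeric(as.Date("2019-12-31") - as.Date("2007-01-15")) / 365.25
  expect_equal(compute_age("2007-01", "alive", NA, as.Date("2019-12-31")),
               oracle)
  expect_equal(round(oracle, 2), 12.96)
  # dead dogs age to their termination date
  expect_equal(compute_age("2015-06", "dead", "2018-06-15",
                           as.Date("2019-12-31")), 3, tolerance = 0.01)
  expect_error(compute_age("2020-01", "alive", NA, as.Date("2019-12-31")),
               "malformed")
})

test_that("age groups use half-open intervals with inclusive lower bounds", {
  expect_equal(assign_age_group(0.49), "puppy")
  expect_equal(assign_age_group(0.5), "juvenile")
  expect_equal(assign_age_group(7.0), "senior")
  expect_equal(assign_age_group(11.999), "senior")
  expect_equal(assign_age_group(12.0), "geriatric")
  expect_error(assign_age_group(-1), "non-negative")
  # boundaries partition [0, 18.3]: every age maps to exactly one group
  ages <- seq(0, 18.3, by = 0.01)
  gs <- assign_age_group(ages)
  expect_false(anyNA(gs))
  expect_setequal(unique(gs), c("puppy", "juvenile", "young_adult",
                                "mature_adult", "senior", "geriatric"))
})

test_that("morphology lookup covers purebreds and falls back to unclassified", {
  expect_equal(annotate_morphology("Pug", "purebred"),
               data.frame(body_size = "small",
                          cephalic_index = "brachycephalic"))
  # multi-size pooled breed: size cannot be classified
  expect_equal(annotate_morphology("Poodle", "purebred"),
               data.frame(body_size = "unclassified",
                          cephalic_index = "mesocephalic"))
  expect_equal(annotate_morphology("Mix Breed", "mixbreed"),
               data.frame(body_size = "unclassified",
                          cephalic_index = "unclassified"))
})

test_that("inclusion filters drop in rule order and the report balances", {
  recs <- make_records(
    list(sex = NA_character_),                       # incomplete sex
    list(crossbred_flag = NA_character_),            # incomplete crossbred
    list(status = NA_character_),                    # incomplete status
    list(dob = "2001-01"),                           # age 18.31 > cap
    list(dob = "2001-02"),                           # age 18.23, kept
    list(status = "dead", termination_date = "2018-06-30", dob = "2010-01"),
    list()                                           # clean row
  )
  recs$age_years <- compute_age(recs$dob, recs$status, recs$termination_date,
                                as.Date("2019-05-15"))
  out <- apply_filters(recs, reference_date = as.Date("2019-05-15"))
  rep <- out$report
  expect_equal(rep$dropped$incomplete_sex, 1)
  expect_equal(rep$dropped$incomplete_crossbred, 1)
  expect_equal(rep$dropped$incomplete_status, 1)
  expect_equal(rep$dropped$age_cap, 1)
  expect_equal(rep$dropped$not_alive_in_study_year, 1)
  expect_equal(sum(unlist(rep$dropped)), rep$input - rep$output)
  expect_true("2001-02" %in% out$records$dob)

  empty <- apply_filters(recs[0])
  expect_equal(empty$report$output, 0)
  expect_equal(sum(unlist(empty$report$dropped)), 0)
})

test_that("the 18.3-year age cap is a sharp boundary", {
  recs <- make_records(list(), list())
  recs$age_years <- c(18.30, 18.31)
  out <- apply_filters(recs)
  expect_equal(out$report$dropped$age_cap, 1)
  expect_equal(out$records$age_years, 18.30)
})

test_that("cleaning annotates and survives malformed DOBs", {
  w <- small_world()
  cl <- w$clean
  expect_true(all(c("breed_canonical", "lineage", "age_years", "age_group",
                    "body_size", "cephalic_index", "region", "country")
                  %in% names(cl)))
  expect_true(all(cl$region == w$geo$region[match(cl$postcode_area,
                                                  w$geo$area)]))
  # a future DOB is counted, not fatal
  bad <- w$comb[1:3]
  bad$dob[2] <- "2031-01"
  cl2 <- clean_records(bad, w$geo)
  expect_equal(attr(cl2, "clean_report")$malformed_dob, 1)
  expect_true(is.na(cl2$age_years[2]))
})
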