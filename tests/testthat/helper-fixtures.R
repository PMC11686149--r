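# Shared fixtures, generated in code and cached for the test run.

.fx <- new.env(parent = emptyenv())

# A small synthetic world (20 sites x 5 sources) with default noise.
small_world <- function() {
  if (is.null(.fx$small)) {
    p <- sim_params(n_sites = 20, n_sources = 5, seed = 7)
    geo <- generate_geography(p)
    truth <- simulate_truth(geo, p)
    st <- emit_source_tables(truth, p)
    comb <- combine_sources(st)
    cl <- clean_records(st, geo)
    .fx$small <- list(params = p, geo = geo, truth = truth, st = st,
                      comb = comb, clean = cl)
  }
  .fx$small
}

# Build schema-complete records from partial field specs; unspecified fields
# are filled with plausible defaults so rows clear the >10/18 completeness
# bar unless a test overrides them to NA.
make_records <- function(...) {
  rows <- list(...)
  defaults <- list(
    record_id = NA_character_, source_id = "SRC01",
    breed_raw = "Labrador Retriever", crossbred_flag = "N", sex = "M",
    dob = "2015-06", postcode_area = "AB", name_prefix = "REX",
    chip_suffix = NA_character_, chip_suffix_2 = NA_character_,
    status = "alive", termination_date = NA_character_,
    longevity = 4.5, age_group = "mature_adult", region = "Region 01",
    country = "England", purebred_flag = "Y",
    crossbred_description = NA_character_)
  out <- lapply(seq_along(rows), function(i) {
    r <- utils::modifyList(defaults, rows[[i]], keep.null = TRUE)
    if (is.na(r$record_id)) r$record_id <- sprintf("R%03d", i)
    r
  })
  dt <- data.table::rbindlist(lapply(out, function(r)
    data.table::as.data.table(r)), use.names = TRUE)
  dt[, .row := seq_len(.N)]
  nb <- normalize_breed(dt$breed_raw, dt$crossbred_flag)
  dt[, breed_canonical := nb$breed_canonical]
  dt[]
}

# Independent brute-force oracle for the marginalised site likelihood.
brute_site_loglik <- function(y, lambda, p, K) {
  N <- max(y):K
  log(sum(vapply(N, function(n)
    dpois(n, lambda) * prod(dbinom(y, n, p)), numeric(1))))
}

# A tiny geography for constructed-record tests.
toy_geo <- function() {
  g <- data.frame(area = c("AB", "CD", "EF", "GH"),
                  region = c("Region 01", "Region 01", "Region 02", "Region 02"),
                  country = c("England", "England", "Scotland", "Scotland"),
                  human_population = c(1000, 2000, 1500, 800))
  class(g) <- c("geography_map", "data.frame")
  g
}

# Minimal posterior_draws object with specified N draws (sites as columns).
fake_draws <- function(Nmats, site_ids) {
  chains <- lapply(Nmats, function(m) {
    colnames(m) <- paste0("N[", site_ids, "]")
    m
  })
  structure(list(chains = chains, site_ids = site_ids,
                 source_ids = "SRC01"), class = "posterior_draws")
}
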