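#' Parameters for the synthetic multi-source registry generator
#'
#' Bundles and validates every knob of the generator. The defaults describe a
#' scaled-down but structurally faithful registry landscape: 124 postcode-area
#' sites observed by 18 sources, per-source detection on the logit scale with
#' source-level intercepts and human-population slopes, cross-source
#' duplication averaging about 2.8 detections per detected dog, an injected
#' exact-duplicate share of 28.7% of raw rows, microchips reported for 50.3%
#' of dogs, and field missingness calibrated so about 6.2% of records lack at
#' least one of the four deduplication key variables (breed, sex, DOB, name
#' prefix).
#'
#' @param n_sites number of postcode-area sites (>= 2).
#' @param n_sources number of data sources / sampling occasions (>= 2).
#' @param human_pop_log_mean,human_pop_log_sd log-scale mean and sd of
#'   site human populations (persons), drawn log-normally.
#' @param dogs_per_capita_asymptote saturation level `a` of dogs per person as
#'   human population grows; in (0, 1].
#' @param dogs_per_capita_halfsat human population (persons) at which the
#'   per-capita rate reaches a/2.
#' @param alpha_mean,alpha_sd source detection intercepts, logit scale.
#' @param beta_mean,beta_sd source detection slopes on the standardized human
#'   population covariate, logit scale.
#' @param exact_dup_rate share of the emitted raw table made up of injected
#'   byte-identical duplicate rows; in [0, 1).
#' @param missing_field_rates named vector of per-row missingness rates by
#'   schema field. Unnamed fields default to 0.
#' @param breed_typo_rate per-row probability that the breed free-text is
#'   perturbed (single-character edit or alias substitution); in [0, 1).
#' @param microchip_coverage fraction of dogs carrying a reported microchip
#'   suffix; in [0, 1].
#' @param dead_fraction fraction of dogs recorded as dead with a termination
#'   date inside the study year.
#' @param seed integer root seed; all generator randomness derives from it.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_sites = 124L,
                       n_sources = 18L,
                       human_pop_log_mean = log(1000),
                       human_pop_log_sd = 0.7,
                       dogs_per_capita_asymptote = 0.25,
                       dogs_per_capita_halfsat = 1000,
                       alpha_mean = -1.68,
                       alpha_sd = 0.6,
                       beta_mean = -0.3,
                       beta_sd = 0.15,
                       exact_dup_rate = 0.287,
                       missing_field_rates = c(
                         breed_raw = 0.010, crossbred_flag = 0.020,
                         sex = 0.010, dob = 0.020, name_prefix = 0.024,
                         status = 0.015, longevity = 0.30, age_group = 0.30,
                         region = 0.10, country = 0.10, purebred_flag = 0.05
                       ),
                       breed_typo_rate = 0.05,
                       microchip_coverage = 0.503,
                       dead_fraction = 0.08,
                       seed = 1L) {
  n_sites <- as.integer(n_sites)
  n_sources <- as.integer(n_sources)
  if (is.na(n_sites) || n_sites < 2L)
    stop("invalid parameter: n_sites must be an integer >= 2")
  if (is.na(n_sources) || n_sources < 2L)
    stop("invalid parameter: n_sources must be an integer >= 2")
  if (dogs_per_capita_asymptote <= 0 || dogs_per_capita_asymptote > 1)
    stop("invalid parameter: dogs_per_capita_asymptote must be in (0, 1]")
  if (dogs_per_capita_halfsat <= 0)
    stop("invalid parameter: dogs_per_capita_halfsat must be > 0")
  if (exact_dup_rate < 0 || exact_dup_rate >= 1)
    stop("invalid parameter: exact_dup_rate must be in [0, 1)")
  if (breed_typo_rate < 0 || breed_typo_rate >= 1)
    stop("invalid parameter: breed_typo_rate must be in [0, 1)")
  if (microchip_coverage < 0 || microchip_coverage > 1)
    stop("invalid parameter: microchip_coverage must be in [0, 1]")
  if (length(missing_field_rates) &&
      (any(missing_field_rates < 0) || any(missing_field_rates >= 1)))
    stop("invalid parameter: missing_field_rates must be in [0, 1)")
  if (dead_fraction < 0 || dead_fraction >= 1)
    stop("invalid parameter: dead_fraction must be in [0, 1)")
  structure(list(
    n_sites = n_sites, n_sources = n_sources,
    human_pop_log_mean = human_pop_log_mean,
    human_pop_log_sd = human_pop_log_sd,
    dogs_per_capita_asymptote = dogs_per_capita_asymptote,
    dogs_per_capita_halfsat = dogs_per_capita_halfsat,
    alpha_mean = alpha_mean, alpha_sd = alpha_sd,
    beta_mean = beta_mean, beta_sd = beta_sd,
    exact_dup_rate = exact_dup_rate,
    missing_field_rates = missing_field_rates,
    breed_typo_rate = breed_typo_rate,
    microchip_coverage = microchip_coverage,
    dead_fraction = dead_fraction,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>", x$n_sites, "sites x", x$n_sources, "sources, seed",
      x$seed, "\n")
  invisible(x)
}

UK_COUNTRIES <- c("England", "Scotland", "Wales", "Northern Ireland")

#' Generate a synthetic geography lookup
#'
#' Creates `n_sites` postcode areas with unique 1-2 character alphabetic
#' codes, log-normally distributed human populations, and a deterministic
#' round-robin partition of areas into regions and regions into countries
#' (at least 2 of each).
#'
#' @param params a [sim_params()] object.
#' @return a `geography_map`: data.frame with columns `area`, `region`,
#'   `country`, `human_population`.
#' @export
generate_geography <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_sites
  codes <- c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))
  if (n > length(codes)) stop("invalid parameter: too many sites for 2-char codes")
  n_regions <- max(2L, min(24L, as.integer(ceiling(n / 6))))
  n_countries <- if (n_regions >= 4L) 4L else 2L
  region_id <- ((seq_len(n) - 1L) %% n_regions) + 1L
  region <- sprintf("Region %02d", region_id)
  country <- UK_COUNTRIES[((region_id - 1L) %% n_countries) + 1L]
  h <- with_seed(derive_seed(params$seed, 1L),
                 rlnorm(n, params$human_pop_log_mean, params$human_pop_log_sd))
  geo <- data.frame(area = codes[seq_len(n)], region = region,
                    country = country, human_population = h,
                    stringsAsFactors = FALSE)
  class(geo) <- c("geography_map", "data.frame")
  geo
}

#' Expected dogs per person as a function of human population
#'
#' Saturating (Michaelis-Menten-shaped) per-capita ownership curve:
#' `d(h) = a * h / (halfsat + h)`, which tends to the asymptote `a` as
#' `h` grows. Site-level expected abundance is `lambda = h * d(h)`.
#'
#' @param h human population (persons).
#' @param asymptote saturation level `a`.
#' @param halfsat half-saturation population.
#' @return dogs-per-person rate, same length as `h`.
#' @export
dogs_per_capita_curve <- function(h, asymptote, halfsat) {
  asymptote * h / (halfsat + h)
}

#' Simulate the latent true state of the dog population
#'
#' Draws site abundances `N_i ~ Poisson(lambda_i)` with
#' `lambda_i = h_i * d(h_i)` from the saturating per-capita curve, source
#' detection parameters `alpha_j, beta_j`, detection probabilities
#' `p_ij = plogis(alpha_j + beta_j * z(h_i))` (where `z` is the same
#' standardisation the model module uses), and a full roster of individual
#' dogs with demographic attributes drawn from the packaged categorical
#' tables, plus per-source Bernoulli detection flags.
#'
#' @param geo a `geography_map`.
#' @param params a [sim_params()] object.
#' @param reference_date date the data are notionally received (end of the
#'   study year).
#' @return an object of class `true_state`: list with `lambda`, `N`, `p`
#'   (sites x sources), `alpha`, `beta`, `z`, `roster` (one row per true dog),
#'   `geo`, `reference_date`.
#' @export
simulate_truth <- function(geo, params = sim_params(),
                           reference_date = as.Date("2019-12-31")) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.data.frame(geo) || nrow(geo) == 0)
    stop("geo must be a nonempty geography_map")
  with_seed(derive_seed(params$seed, 2L), {
    h <- geo$human_population
    z <- standardize_covariate(h)
    lambda <- h * dogs_per_capita_curve(h, params$dogs_per_capita_asymptote,
                                        params$dogs_per_capita_halfsat)
    N <- rpois(length(lambda), lambda)
    alpha <- rnorm(params$n_sources, params$alpha_mean, params$alpha_sd)
    beta <- rnorm(params$n_sources, params$beta_mean, params$beta_sd)
    p <- plogis(outer(as.numeric(z), beta) +
                  matrix(alpha, length(h), params$n_sources, byrow = TRUE))
    roster <- make_roster(geo, N, params, reference_date)
    det <- matrix(runif(nrow(roster) * params$n_sources) <
                    p[roster$site_idx, , drop = FALSE],
                  nrow = nrow(roster))
    out <- list(lambda = lambda, N = N, p = p, alpha = alpha, beta = beta,
                z = z, roster = roster, detections = det, geo = geo,
                reference_date = reference_date, params = params)
    class(out) <- "true_state"
    out
  })
}

#' @export
print.true_state <- function(x, ...) {
  cat("<true_state>", sum(x$N), "dogs over", length(x$N), "sites,",
      ncol(x$p), "sources\n")
  invisible(x)
}

# Draw the roster of individual dogs: breed/lineage, sex, DOB, name, chips,
# status. Attribute frequencies follow the packaged popularity tables and the
# national age/sex/lineage proportions the generator emulates.
make_roster <- function(geo, N, params, reference_date) {
  n <- sum(N)
  attrs <- breed_attributes()
  crosses <- named_crosses()
  site_idx <- rep(seq_along(N), N)

  lineage <- sample(c("purebred", "crossbred"), n, TRUE, prob = c(0.858, 0.142))
  breed_canonical <- character(n)
  cross_text <- rep(NA_character_, n)
  pure <- lineage == "purebred"
  breed_canonical[pure] <- sample(attrs$breed, sum(pure), TRUE, prob = attrs$weight)
  ncross <- sum(!pure)
  if (ncross) {
    kind <- sample(c("mix", "named", "crosstype"), ncross, TRUE,
                   prob = c(0.393, 0.152, 0.455))
    bc <- character(ncross); ct <- rep(NA_character_, ncross)
    bc[kind == "mix"] <- "Mix Breed"
    ct[kind == "mix"] <- "Mix Breed"
    kn <- sum(kind == "named")
    if (kn) {
      ci <- sample.int(nrow(crosses), kn, TRUE, prob = crosses$weight)
      bc[kind == "named"] <- crosses$cross[ci]
      ct[kind == "named"] <- ifelse(runif(kn) < 0.5, crosses$cross[ci],
                                    paste(crosses$parent1[ci], "X",
                                          crosses$parent2[ci]))
    }
    kc <- sum(kind == "crosstype")
    if (kc) {
      par <- sample(attrs$breed, kc, TRUE, prob = attrs$weight)
      bc[kind == "crosstype"] <- paste(par, "cross/type")
      ct[kind == "crosstype"] <- paste(par, ifelse(runif(kc) < 0.5,
                                                   "Cross", "Type"))
    }
    breed_canonical[!pure] <- bc
    cross_text[!pure] <- ct
    lineage[!pure][bc == "Mix Breed"] <- "mixbreed"
  }

  sex <- sample(c("M", "F"), n, TRUE, prob = c(0.51, 0.49))
  grp_probs <- c(0.009, 0.027, 0.085, 0.389, 0.332, 0.158)
  grp_lo <- c(0.05, 0.5, 1, 2, 7, 12)
  grp_hi <- c(0.5, 1, 2, 7, 12, 16.5)
  gi <- sample.int(6L, n, TRUE, prob = grp_probs)
  age <- runif(n, grp_lo[gi], grp_hi[gi])
  status <- ifelse(runif(n) < params$dead_fraction, "dead", "alive")
  dead <- status == "dead"
  term <- rep(as.Date(NA), n)
  term[dead] <- reference_date -
    floor(runif(sum(dead), 0, pmin(350, age[dead] * 365.25 * 0.5)))
  end_date <- reference_date
  dob_date <- (if (any(dead)) {
    ed <- rep(reference_date, n); ed[dead] <- term[dead]; ed
  } else rep(reference_date, n)) - round(age * 365.25)
  dob <- format(dob_date, "%Y-%m")

  name <- sample(dog_names(), n, TRUE)
  name_prefix <- toupper(substr(name, 1, 3))
  has_chip <- runif(n) < params$microchip_coverage
  chip <- rep(NA_character_, n)
  chip[has_chip] <- sprintf("%06d", sample.int(1e6, sum(has_chip), TRUE) - 1L)
  chip2 <- rep(NA_character_, n)
  second <- has_chip & runif(n) < 0.0002
  if (any(second))
    chip2[second] <- sprintf("%06d", sample.int(1e6, sum(second), TRUE) - 1L)

  data.table::data.table(
    true_id = sprintf("D%07d", seq_len(n)), site_idx = site_idx,
    area = geo$area[site_idx], breed_canonical = breed_canonical,
    lineage = lineage, cross_text = cross_text, sex = sex,
    age_years = age, dob = dob, status = status,
    termination_date = as.character(term), name = name,
    name_prefix = name_prefix, chip_suffix = chip, chip_suffix_2 = chip2
  )
}

#' Emit noisy per-source record tables with ground-truth labels
#'
#' Builds one record table per source containing exactly the detected
#' individuals, then injects noise: byte-identical duplicate rows (an
#' `exact_dup_rate` share of the raw table), per-field deletion at
#' `missing_field_rates`, breed free-text perturbation (single-character
#' edits and alias substitutions) at `breed_typo_rate`. Every row keeps a
#' hidden `true_id` label (not part of the 18-field schema; ignored by
#' deduplication) for scoring.
#'
#' @param truth a `true_state` from [simulate_truth()].
#' @param params the [sim_params()] used to build it.
#' @return object of class `source_tables`: list with `tables` (named list of
#'   data.tables, one per source), `geo`, `params`.
#' @export
emit_source_tables <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "true_state"))
  rates <- params$missing_field_rates
  if (length(rates) && (any(rates < 0) || any(rates >= 1)))
    stop("invalid parameter: missing_field_rates must be in [0, 1)")
  with_seed(derive_seed(params$seed, 3L), {
    ros <- truth$roster
    geo <- truth$geo
    tabs <- vector("list", params$n_sources)
    names(tabs) <- sprintf("SRC%02d", seq_len(params$n_sources))
    for (j in seq_len(params$n_sources)) {
      idx <- which(truth$detections[, j])
      d <- ros[idx]
      tab <- data.table::data.table(
        record_id = sprintf("S%02d-R%06d", j, seq_along(idx)),
        source_id = names(tabs)[j],
        breed_raw = emit_breed_text(d, params$breed_typo_rate),
        crossbred_flag = ifelse(d$lineage == "purebred", "N", "Y"),
        sex = d$sex, dob = d$dob, postcode_area = d$area,
        name_prefix = d$name_prefix, chip_suffix = d$chip_suffix,
        chip_suffix_2 = d$chip_suffix_2, status = d$status,
        termination_date = d$termination_date,
        longevity = round(d$age_years, 2),
        age_group = assign_age_group(pmin(d$age_years, AGE_CAP_YEARS)),
        region = geo$region[d$site_idx], country = geo$country[d$site_idx],
        purebred_flag = ifelse(d$lineage == "purebred", "Y", "N"),
        crossbred_description = d$cross_text,
        true_id = d$true_id
      )
      # field deletion
      for (f in names(rates)) {
        if (rates[[f]] <= 0 || !f %in% names(tab)) next
        hit <- runif(nrow(tab)) < rates[[f]]
        if (any(hit)) data.table::set(tab, which(hit), f,
                                      if (is.numeric(tab[[f]])) NA_real_ else NA_character_)
      }
      tabs[[j]] <- tab
    }
    # inject byte-identical duplicate rows so they form exact_dup_rate of the
    # final raw table
    if (params$exact_dup_rate > 0) {
      r <- params$exact_dup_rate
      for (j in seq_along(tabs)) {
        R <- nrow(tabs[[j]])
        ndup <- round(R * r / (1 - r))
        if (ndup > 0) {
          dup <- tabs[[j]][sample.int(R, ndup, replace = TRUE)]
          tabs[[j]] <- data.table::rbindlist(list(tabs[[j]], dup))
        }
      }
    }
    structure(list(tables = tabs, geo = geo, params = params),
              class = "source_tables")
  })
}

#' @export
print.source_tables <- function(x, ...) {
  cat("<source_tables>", length(x$tables), "sources,",
      sum(vapply(x$tables, nrow, 0L)), "rows\n")
  invisible(x)
}

# Per-row breed free text: canonical name, an alias spelling, or a
# single-character typo; case jitter on top.
emit_breed_text <- function(d, typo_rate) {
  txt <- ifelse(is.na(d$cross_text), d$breed_canonical, d$cross_text)
  n <- length(txt)
  if (typo_rate > 0) {
    ali <- breed_aliases()
    hit <- which(runif(n) < typo_rate)
    for (i in hit) {
      if (runif(1) < 0.4 && d$lineage[i] == "purebred" &&
          d$breed_canonical[i] %in% ali$breed) {
        cand <- ali$alias[ali$breed == d$breed_canonical[i]]
        txt[i] <- cand[sample.int(length(cand), 1L)]
      } else {
        txt[i] <- typo_one_char(txt[i])
      }
    }
  }
  if (typo_rate > 0) {
    # case jitter rides with the typo noise switch so that a noise-free
    # emission reproduces roster fields exactly
    low <- runif(n) < 0.2
    txt[low] <- tolower(txt[low])
  }
  txt
}

# Single-character substitution, deletion, or transposition.
typo_one_char <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 4) return(s)
  pos <- sample(2:(length(ch) - 1), 1L)
  op <- sample(3L, 1L)
  if (op == 1L) ch[pos] <- sample(letters, 1L)
  else if (op == 2L) ch <- ch[-pos]
  else { tmp <- ch[pos]; ch[pos] <- ch[pos + 1L]; ch[pos + 1L] <- tmp }
  paste(ch, collapse = "")
}

#' Stack per-source tables into one record table
#'
#' Adds a unique row key `.row` used by deduplication to track survivorship.
#'
#' @param st a `source_tables` object (or a list of data.frames).
#' @return a single data.table.
#' @export
combine_sources <- function(st) {
  tabs <- if (inherits(st, "source_tables")) st$tables else st
  dt <- data.table::rbindlist(lapply(tabs, data.table::as.data.table),
                              use.names = TRUE, fill = TRUE)
  dt[, .row := seq_len(.N)]
  dt[]
}

#' Write generator outputs to disk
#'
#' One CSV per source (UTF-8, header row, `YYYY-MM` partial dates for DOB), a
#' geography CSV, and a JSON ground-truth linkage file mapping record ids to
#' hidden individual labels.
#'
#' @param st a `source_tables` object.
#' @param dir output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
write_source_tables <- function(st, dir) {
  stopifnot(inherits(st, "source_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(st$tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    write.csv(st$tables[[nm]][, !"true_id"], f, row.names = FALSE, na = "")
    files <- c(files, f)
  }
  gf <- file.path(dir, "geography.csv")
  write.csv(as.data.frame(st$geo), gf, row.names = FALSE)
  truth <- data.table::rbindlist(
    lapply(st$tables, function(t) t[, .(record_id, source_id, true_id)]))
  tf <- file.path(dir, "truth_labels.json")
  jsonlite::write_json(truth, tf, dataframe = "columns")
  invisible(c(files, gf, tf))
}
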