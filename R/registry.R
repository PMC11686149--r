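# Record cleaning: breed normalisation, age computation, demographic
# annotation, geography assignment, and the inclusion filters.

# Build the lookup pool for breed matching: canonical purebreds, their
# aliases, named crosses (plus their "parent x parent" spellings), and
# cross/type forms. Keys are lower-case, whitespace-squished.
breed_match_pool <- function() {
  if (!is.null(.dogpop_cache$breed_pool)) return(.dogpop_cache$breed_pool)
  attrs <- breed_attributes()
  ali <- breed_aliases()
  crosses <- named_crosses()
  pool <- rbind(
    data.frame(key = tolower(attrs$breed), canonical = attrs$breed,
               lineage = "purebred", stringsAsFactors = FALSE),
    data.frame(key = tolower(ali$alias), canonical = ali$breed,
               lineage = "purebred", stringsAsFactors = FALSE),
    data.frame(key = tolower(crosses$cross), canonical = crosses$cross,
               lineage = "crossbred", stringsAsFactors = FALSE),
    data.frame(key = tolower(paste(crosses$parent1, "x", crosses$parent2)),
               canonical = crosses$cross, lineage = "crossbred",
               stringsAsFactors = FALSE),
    data.frame(key = tolower(paste(crosses$parent2, "x", crosses$parent1)),
               canonical = crosses$cross, lineage = "crossbred",
               stringsAsFactors = FALSE),
    data.frame(key = c(tolower(paste(attrs$breed, "cross")),
                       tolower(paste(attrs$breed, "type"))),
               canonical = rep(paste(attrs$breed, "cross/type"), 2),
               lineage = "crossbred", stringsAsFactors = FALSE),
    data.frame(key = c("mix breed", "mixed breed", "mix", "mongrel",
                       "crossbreed", "cross breed", "cross"),
               canonical = "Mix Breed", lineage = "mixbreed",
               stringsAsFactors = FALSE)
  )
  pool <- pool[!duplicated(pool$key), ]
  .dogpop_cache$breed_pool <- pool
  pool
}

squish <- function(x) gsub("\\s+", " ", trimws(x))

#' Normalise breed free text to a canonical breed and lineage class
#'
#' Case- and whitespace-insensitive lookup against the packaged alias table.
#' Patterns `"X x Y"`, `"X Cross"`, `"X Type"` are classified crossbred with
#' canonical `"X x Y"` (or the recognised cross name, e.g. Cockerpoo for
#' Cocker Spaniel X Poodle) or `"X cross/type"`. Unknown lineage or more than
#' two parental breeds yields `"Mix Breed"`. Otherwise-unmatched text is
#' matched to the nearest alias within edit distance 1; failing that it is
#' left `"Unclassified"`. Always returns; unmatched is a value, not an error.
#'
#' @param breed_raw character vector of breed free text (may be empty/NA).
#' @param crossbred_flag `"Y"`, `"N"`, or `"unknown"`/NA, recycled.
#' @return data.frame with columns `breed_canonical` and `lineage`
#'   (`purebred`, `crossbred`, `mixbreed`).
#' @export
#' @examples
#' normalize_breed("Cocker Spaniel X Poodle", "Y")
#' normalize_breed("labrador retriever", "N")
normalize_breed <- function(breed_raw, crossbred_flag = "unknown") {
  n <- max(length(breed_raw), length(crossbred_flag))
  breed_raw <- rep_len(as.character(breed_raw), n)
  crossbred_flag <- rep_len(as.character(crossbred_flag), n)
  key <- tolower(squish(breed_raw))
  flag <- ifelse(is.na(crossbred_flag), "unknown", crossbred_flag)

  # work on unique (key, flag) pairs
  uk <- unique(data.frame(key = key, flag = flag, stringsAsFactors = FALSE))
  res <- t(mapply(normalize_breed_one, uk$key, uk$flag, USE.NAMES = FALSE))
  idx <- match(paste(key, flag, sep = "\r"), paste(uk$key, uk$flag, sep = "\r"))
  data.frame(breed_canonical = res[idx, 1], lineage = res[idx, 2],
             stringsAsFactors = FALSE)
}

normalize_breed_one <- function(key, flag) {
  pool <- breed_match_pool()
  unmatched <- function() {
    if (flag == "N") c("Unclassified", "purebred")
    else c("Mix Breed", "mixbreed")
  }
  if (is.na(key) || !nzchar(key)) return(unmatched())

  hit <- match(key, pool$key)
  if (!is.na(hit)) return(c(pool$canonical[hit], pool$lineage[hit]))

  # "X x Y" parental pattern
  parts <- strsplit(key, "\\s+x\\s+")[[1]]
  if (length(parts) > 2) return(c("Mix Breed", "mixbreed"))
  if (length(parts) == 2) {
    p1 <- match_purebred(parts[1]); p2 <- match_purebred(parts[2])
    if (is.na(p1) || is.na(p2)) return(c("Mix Breed", "mixbreed"))
    crosses <- named_crosses()
    ci <- which((crosses$parent1 == p1 & crosses$parent2 == p2) |
                  (crosses$parent1 == p2 & crosses$parent2 == p1))
    if (length(ci)) return(c(crosses$cross[ci[1]], "crossbred"))
    return(c(paste(p1, "x", p2), "crossbred"))
  }

  # "X cross" / "X type" suffix
  m <- regmatches(key, regexec("^(.*)\\s+(cross|type|cross/type)$", key))[[1]]
  if (length(m) == 3) {
    base <- match_purebred(m[2])
    if (!is.na(base)) return(c(paste(base, "cross/type"), "crossbred"))
    return(c("Mix Breed", "mixbreed"))
  }

  # nearest alias within edit distance 1 (ties -> first pool entry)
  d <- utils::adist(key, pool$key)[1, ]
  if (min(d) <= 1) {
    hit <- which.min(d)
    return(c(pool$canonical[hit], pool$lineage[hit]))
  }
  unmatched()
}

# exact/alias/edit-1 purebred match for a lower-case fragment; NA if none.
match_purebred <- function(key) {
  pool <- breed_match_pool()
  pure <- pool[pool$lineage == "purebred", ]
  hit <- match(key, pure$key)
  if (!is.na(hit)) return(pure$canonical[hit])
  d <- utils::adist(key, pure$key)[1, ]
  if (min(d) <= 1) return(pure$canonical[which.min(d)])
  NA_character_
}

#' Decimal age in years from a month-resolution date of birth
#'
#' Month-resolution DOBs are resolved to the 15th of the month (the unbiased
#' within-month expectation). The age endpoint is the termination date for
#' dead dogs and the reference date (when the data were received) otherwise.
#'
#' @param dob character `"YYYY-MM"` (or a full `"YYYY-MM-DD"` date).
#' @param status `"alive"` or `"dead"`, recycled.
#' @param termination_date death/termination date (Date or `"YYYY-MM-DD"`),
#'   may be NA.
#' @param reference_date date the data were received.
#' @return numeric vector of non-negative decimal years; NA where `dob` is NA.
#' @export
#' @examples
#' compute_age("2019-06", "alive", NA, as.Date("2019-06-15"))
compute_age <- function(dob, status, termination_date,
                        reference_date = as.Date("2019-12-31")) {
  n <- max(length(dob), length(status), length(termination_date))
  dob <- rep_len(as.character(dob), n)
  status <- rep_len(as.character(status), n)
  term <- rep_len(as.Date(as.character(termination_date)), n)
  start <- as.Date(ifelse(is.na(dob) | nchar(dob) >= 10, dob,
                          paste0(dob, "-15")))
  end <- rep(as.Date(reference_date), n)
  use_term <- !is.na(status) & status == "dead" & !is.na(term)
  end[use_term] <- term[use_term]
  bad <- !is.na(start) & start > end
  if (any(bad))
    stop("malformed record: date of birth after the age endpoint (",
         sum(bad), " record(s))")
  as.numeric(end - start) / 365.25
}

#' Assign a developmental age group
#'
#' Six half-open intervals (lower bound inclusive): puppies 0 to <6 months,
#' juveniles 6 to <12 months, young adults 12 to <24 months, mature adults
#' 2 to <7 years, seniors 7 to <12 years, geriatrics >=12 years.
#'
#' @param age_years non-negative numeric vector; NAs pass through.
#' @return character vector of age group labels.
#' @export
assign_age_group <- function(age_years) {
  if (any(age_years < 0, na.rm = TRUE))
    stop("invalid parameter: age_years must be non-negative")
  as.character(cut(age_years, breaks = c(0, 0.5, 1, 2, 7, 12, Inf),
                   labels = AGE_GROUPS, right = FALSE))
}

#' Annotate body size and cephalic index
#'
#' Table lookup on the packaged breed-attribute table. Crossbreds, mix
#' breeds, and unlisted breeds are `unclassified`; breeds pooling multiple
#' sizes into one category (e.g. Poodle) carry `unclassified` size.
#'
#' @param breed_canonical canonical breed names.
#' @param lineage lineage classes from [normalize_breed()].
#' @return data.frame with columns `body_size` and `cephalic_index`.
#' @export
annotate_morphology <- function(breed_canonical, lineage = "purebred") {
  n <- max(length(breed_canonical), length(lineage))
  breed_canonical <- rep_len(breed_canonical, n)
  lineage <- rep_len(lineage, n)
  attrs <- breed_attributes()
  i <- match(breed_canonical, attrs$breed)
  i[lineage != "purebred"] <- NA
  size <- ifelse(is.na(i), "unclassified", attrs$size[i])
  ceph <- ifelse(is.na(i), "unclassified", attrs$cephalic[i])
  data.frame(body_size = size, cephalic_index = ceph, stringsAsFactors = FALSE)
}

#' Clean and annotate raw registry records
#'
#' Stacks per-source tables, normalises breed text, computes decimal ages
#' (records whose DOB postdates the age endpoint are set to NA age and
#' counted, rather than aborting the batch), assigns age groups and
#' morphology, and (re)derives region/country from the geography lookup.
#'
#' @param records a `source_tables` object, list of data.frames, or one
#'   combined data.frame.
#' @param geo a `geography_map` (columns `area`, `region`, `country`,
#'   `human_population`).
#' @param reference_date date the data were received.
#' @return a data.table of annotated records (attribute `clean_report` holds
#'   malformed-DOB counts).
#' @export
clean_records <- function(records, geo,
                          reference_date = as.Date("2019-12-31")) {
  dt <- if (is.data.frame(records)) data.table::as.data.table(records)
        else combine_sources(records)
  if (!".row" %in% names(dt)) dt[, .row := seq_len(.N)]

  nb <- normalize_breed(dt$breed_raw, dt$crossbred_flag)
  dt[, breed_canonical := nb$breed_canonical]
  dt[, lineage := nb$lineage]

  # malformed DOB (after endpoint) -> NA age, counted, batch continues
  term <- suppressWarnings(as.Date(as.character(dt$termination_date)))
  start <- suppressWarnings(as.Date(
    ifelse(is.na(dt$dob) | nchar(dt$dob) >= 10, as.character(dt$dob),
           paste0(dt$dob, "-15"))))
  end <- rep(as.Date(reference_date), nrow(dt))
  use_term <- !is.na(dt$status) & dt$status == "dead" & !is.na(term)
  end[use_term] <- term[use_term]
  bad <- !is.na(start) & start > end
  age <- as.numeric(end - start) / 365.25
  age[bad] <- NA_real_
  dt[, age_years := age]
  dt[, age_group := assign_age_group(age_years)]

  morph <- annotate_morphology(dt$breed_canonical, dt$lineage)
  dt[, body_size := morph$body_size]
  dt[, cephalic_index := morph$cephalic_index]

  gi <- match(dt$postcode_area, geo$area)
  dt[, region := geo$region[gi]]
  dt[, country := geo$country[gi]]
  data.table::setattr(dt, "clean_report",
                      list(n = nrow(dt), malformed_dob = sum(bad)))
  dt[]
}

#' Apply the inclusion filters
#'
#' Drops, in order: records with incomplete crossbred flag, status, or sex;
#' records older than the age cap (18.3 years, the age by which ~95% of the
#' pet population is deceased, excluding dogs unlikely to be alive in the
#' study year); and dead records terminated before the study year started.
#' Records with missing DOB are kept for abundance counts but flagged, since
#' they cannot enter age demographics.
#'
#' @param records annotated records from [clean_records()].
#' @param reference_date date the data were received.
#' @param study_start first day of the study year.
#' @param age_cap maximum age retained, in years.
#' @return list with `records` (the surviving rows) and `report` (per-rule
#'   drop counts, in rule order; counts sum to input minus output).
#' @export
apply_filters <- function(records, reference_date = as.Date("2019-12-31"),
                          study_start = as.Date("2019-01-01"),
                          age_cap = AGE_CAP_YEARS) {
  dt <- data.table::as.data.table(records)
  n_in <- nrow(dt)
  drop <- c(incomplete_crossbred = 0L, incomplete_status = 0L,
            incomplete_sex = 0L, age_cap = 0L, not_alive_in_study_year = 0L)

  keep <- rep(TRUE, n_in)
  bad <- keep & (is.na(dt$crossbred_flag) | !dt$crossbred_flag %in% c("Y", "N"))
  drop["incomplete_crossbred"] <- sum(bad); keep <- keep & !bad
  bad <- keep & (is.na(dt$status) | !dt$status %in% c("alive", "dead"))
  drop["incomplete_status"] <- sum(bad); keep <- keep & !bad
  bad <- keep & (is.na(dt$sex) | !dt$sex %in% c("M", "F"))
  drop["incomplete_sex"] <- sum(bad); keep <- keep & !bad
  bad <- keep & !is.na(dt$age_years) & dt$age_years > age_cap
  drop["age_cap"] <- sum(bad); keep <- keep & !bad
  term <- suppressWarnings(as.Date(as.character(dt$termination_date)))
  bad <- keep & !is.na(dt$status) & dt$status == "dead" & !is.na(term) &
    term < as.Date(study_start)
  drop["not_alive_in_study_year"] <- sum(bad); keep <- keep & !bad

  out <- dt[keep]
  report <- list(input = n_in, dropped = as.list(drop),
                 missing_dob_kept = sum(is.na(out$age_years)),
                 output = nrow(out))
  list(records = out[], report = report)
}
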