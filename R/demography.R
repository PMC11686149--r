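# Descriptive outputs: demographic proportions from the deduplicated records,
# posterior partitioning into categories within/between geographies,
# per-capita densities, breed rankings, ratios and replacement arithmetic,
# and external-reference correlation.

#' Demographic proportions from cleaned, deduplicated records
#'
#' Extracts per-geography category proportions used to partition posterior
#' population estimates. Records with missing or unclassifiable values for
#' the grouping (e.g. unknown age, `unclassified` morphology) are excluded
#' from the denominator; the exclusion is recorded in the table's metadata
#' attribute. Proportions sum to 1 per geography.
#'
#' @param records cleaned records (one row per individual).
#' @param grouping one of `"age_group"`, `"lineage"`, `"breed"`,
#'   `"cephalic_index"`, `"body_size"`.
#' @param geography column defining geographies (default `"country"`).
#' @param include_unclassified keep `unclassified`/missing categories in the
#'   denominator (default FALSE).
#' @return data.frame `geography`, `category`, `count`, `proportion`, with
#'   attribute `metadata`.
#' @export
demographic_table <- function(records,
                              grouping = c("age_group", "lineage", "breed",
                                           "cephalic_index", "body_size"),
                              geography = "country",
                              include_unclassified = FALSE) {
  grouping <- match.arg(grouping)
  dt <- data.table::as.data.table(records)
  col <- if (grouping == "breed") "breed_canonical" else grouping
  dt <- dt[!is.na(get(col)) & !is.na(get(geography))]
  excluded <- 0L
  if (!include_unclassified) {
    drop <- dt[[col]] %in% c("unclassified", "Unclassified")
    excluded <- sum(drop)
    dt <- dt[!drop]
  }
  tab <- dt[, .(count = .N), by = c(geography, col)]
  data.table::setnames(tab, c(geography, col), c("geography", "category"))
  tab[, proportion := count / sum(count), by = geography]
  data.table::setorder(tab, geography, -count, category)
  out <- as.data.frame(tab)
  attr(out, "metadata") <- list(grouping = grouping, geography = geography,
                                excluded_unclassified = excluded,
                                include_unclassified = include_unclassified)
  out
}

#' Within/between percentages for category estimates
#'
#' For category population estimates per geography: the within percentage is
#' the category's share of its geography's total, and the between percentage
#' is the geography's share of that category's grand total. Percentages are
#' rounded half away from zero to 1 decimal.
#'
#' @param tab data.frame with columns `geography`, `category`, `estimate`.
#' @param geography_totals optional named vector of geography totals; by
#'   default the per-geography sum of the category estimates.
#' @return `tab` with `within_pct` and `between_pct` columns added.
#' @export
within_between_pct <- function(tab, geography_totals = NULL) {
  dt <- data.table::as.data.table(tab)
  if (is.null(geography_totals)) {
    dt[, geo_total := sum(estimate), by = geography]
  } else {
    dt[, geo_total := geography_totals[geography]]
    if (anyNA(dt$geo_total))
      stop("geography label mismatch: ",
           paste(setdiff(dt$geography, names(geography_totals)), collapse = ", "))
  }
  dt[, within_pct := round_half_up(100 * estimate / geo_total, 1)]
  dt[, between_pct := round_half_up(100 * estimate / sum(estimate), 1),
     by = category]
  dt[, geo_total := NULL]
  as.data.frame(dt)
}

#' Partition posterior estimates by demographic proportions
#'
#' Multiplies each geography's posterior estimate by its category proportions
#' and reports within/between percentages.
#'
#' @param summary data.frame from [posterior_summary()] (columns `group`,
#'   `mean`).
#' @param demo a [demographic_table()] with matching geography labels.
#' @return data.frame `geography`, `category`, `estimate`, `within_pct`,
#'   `between_pct`.
#' @export
partition_estimates <- function(summary, demo) {
  miss <- setdiff(unique(demo$geography), summary$group)
  if (length(miss))
    stop("geography label mismatch: ", paste(miss, collapse = ", "))
  est <- setNames(summary$mean, summary$group)
  tab <- data.frame(geography = demo$geography, category = demo$category,
                    estimate = est[demo$geography] * demo$proportion,
                    row.names = NULL)
  within_between_pct(tab, geography_totals = est)
}

#' Posterior dogs-per-person density per area
#'
#' Each posterior abundance draw is divided by the area's human population,
#' then summarised (mean and equal-tailed 95% credible interval). Areas whose
#' mean density exceeds `outlier_threshold` are flagged: such values usually
#' indicate a source-correction artefact rather than genuinely dense dog
#' ownership, and warrant caution.
#'
#' @param draws a `posterior_draws`.
#' @param geo a `geography_map` with positive human populations.
#' @param outlier_threshold flag areas whose mean exceeds this many dogs per
#'   person (default 1.5).
#' @return data.frame `area`, `mean`, `lower`, `upper`, `outlier`.
#' @export
per_capita <- function(draws, geo, outlier_threshold = 1.5) {
  gi <- match(draws$site_ids, geo$area)
  if (anyNA(gi)) stop("sites not in geography map")
  h <- geo$human_population[gi]
  if (any(!is.finite(h)) || any(h <= 0))
    stop("human populations must be positive")
  Nd <- draw_matrix(draws, "N")
  dens <- sweep(Nd, 2, h, "/")
  data.frame(area = draws$site_ids,
             mean = colMeans(dens),
             lower = apply(dens, 2, quantile, 0.025, names = FALSE),
             upper = apply(dens, 2, quantile, 0.975, names = FALSE),
             outlier = colMeans(dens) > outlier_threshold,
             row.names = NULL)
}

#' Rank breeds by popularity
#'
#' Counts individuals per canonical breed within a lineage class, descending
#' (ties broken alphabetically), with percentages of the lineage total
#' rounded half away from zero to 1 decimal. `Mix Breed` (unknown lineage)
#' can be excluded from the crossbred ranking.
#'
#' @param records cleaned records (one row per individual).
#' @param lineage `"purebred"` or `"crossbred"` (the latter includes mix
#'   breeds unless excluded).
#' @param top_k number of rows to return (>= 1).
#' @param geography optional value to filter on (e.g. a country name).
#' @param geography_col column used by `geography` (default `"country"`).
#' @param include_mix keep `Mix Breed` in the crossbred ranking and
#'   denominator (default FALSE).
#' @return data.frame `rank`, `breed`, `count`, `pct`.
#' @export
rank_breeds <- function(records, lineage = c("purebred", "crossbred"),
                        top_k = 15L, geography = NULL,
                        geography_col = "country", include_mix = FALSE) {
  lineage <- match.arg(lineage)
  if (top_k < 1L) stop("invalid parameter: top_k must be >= 1")
  dt <- data.table::as.data.table(records)
  if (!is.null(geography)) dt <- dt[get(geography_col) %in% geography]
  dt <- if (lineage == "purebred") {
    dt[lineage == "purebred" & !is.na(breed_canonical) &
         breed_canonical != "Unclassified"]
  } else {
    dt[lineage %in% c("crossbred", "mixbreed")]
  }
  if (!include_mix) dt <- dt[breed_canonical != "Mix Breed"]
  tab <- dt[, .(count = .N), by = .(breed = breed_canonical)]
  total <- sum(tab$count)
  data.table::setorder(tab, -count, breed)
  tab[, pct := round_half_up(100 * count / total, 1)]
  tab[, rank := seq_len(.N)]
  as.data.frame(head(tab[, .(rank, breed, count, pct)], top_k))
}

#' Purebred-to-crossbred ratio
#'
#' @param n_pure,n_cross counts or estimates.
#' @param digits decimals in the ratio (default 2).
#' @return list with `ratio` (numeric, `Inf` with `infinite = TRUE` when the
#'   crossbred count is zero) and `label` in `"r:1"` form.
#' @export
pure_cross_ratio <- function(n_pure, n_cross, digits = 2) {
  if (n_cross == 0)
    return(list(ratio = Inf, label = "Inf:1", infinite = TRUE))
  r <- round_half_up(n_pure / n_cross, digits)
  list(ratio = r, label = paste0(formatC(r, format = "f", digits = digits),
                                 ":1"), infinite = FALSE)
}

#' Annual replacement rate
#'
#' The number of dogs needed each year to hold the population constant,
#' approximated as total population divided by median lifespan, in millions
#' rounded half away from zero to 2 decimals.
#'
#' @param total population size (individuals).
#' @param median_lifespan_years median lifespan (> 0), vectorised.
#' @return numeric vector, millions per year.
#' @export
replacement_rate <- function(total, median_lifespan_years) {
  if (any(median_lifespan_years <= 0))
    stop("invalid parameter: median_lifespan_years must be > 0")
  round_half_up(total / median_lifespan_years / 1e6, 2)
}

#' Ratios and replacement arithmetic per geography
#'
#' From the posterior summary and the deduplicated records: per-geography
#' purebred:crossbred ratio (2 decimals, `r:1` form) and male:female sex
#' ratio, plus the annual replacement requirement of the overall total for
#' each supplied median lifespan.
#'
#' @param summary data.frame from [posterior_summary()] at the geography
#'   level (columns `group`, `mean`).
#' @param records cleaned records (one row per individual) with `lineage`,
#'   `sex`, and the geography column.
#' @param median_lifespan_years lifespans to evaluate (default 12.0 and 12.5).
#' @param geography_col records column matching `summary$group`.
#' @return list with `lineage_ratios`, `sex_ratios`, `replacement`.
#' @export
ratios_and_replacement <- function(summary, records,
                                   median_lifespan_years = c(12.0, 12.5),
                                   geography_col = "country") {
  dt <- data.table::as.data.table(records)
  est <- setNames(summary$mean, summary$group)
  lr <- do.call(rbind, lapply(names(est), function(g) {
    sub <- dt[get(geography_col) == g]
    n <- nrow(sub)
    if (!n) return(NULL)
    p_pure <- mean(sub$lineage == "purebred")
    n_pure <- est[[g]] * p_pure
    n_cross <- est[[g]] * (1 - p_pure)
    r <- pure_cross_ratio(n_pure, n_cross)
    data.frame(geography = g, n_pure = n_pure, n_cross = n_cross,
               ratio = r$ratio, label = r$label, infinite = r$infinite)
  }))
  sr <- do.call(rbind, lapply(names(est), function(g) {
    sub <- dt[get(geography_col) == g & sex %in% c("M", "F")]
    if (!nrow(sub)) return(NULL)
    nm <- sum(sub$sex == "M"); nf <- sum(sub$sex == "F")
    data.frame(geography = g,
               ratio = round_half_up(nm / max(nf, 1), 2),
               label = paste0(round_half_up(nm / max(nf, 1), 2), ":1"))
  }))
  total <- sum(est)
  repl <- data.frame(median_lifespan_years = median_lifespan_years,
                     replacement_millions =
                       replacement_rate(total, median_lifespan_years))
  list(lineage_ratios = lr, sex_ratios = sr, replacement = repl)
}

#' Correlate abundance estimates with an external reference
#'
#' Pearson product-moment correlation between per-area estimates and any
#' user-supplied per-area reference abundance table, on their shared areas.
#'
#' @param estimates data.frame with columns `area` and `value` (e.g.
#'   posterior means per area).
#' @param reference data.frame with columns `area` and `value`.
#' @return list with `r`, `df` (n - 2), `p`, `n`.
#' @export
correlate_reference <- function(estimates, reference) {
  m <- merge(as.data.frame(estimates)[, c("area", "value")],
             as.data.frame(reference)[, c("area", "value")],
             by = "area", suffixes = c("_est", "_ref"))
  if (nrow(m) < 3) stop("need at least 3 shared areas")
  ct <- stats::cor.test(m$value_est, m$value_ref, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p = ct$p.value, n = nrow(m))
}
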