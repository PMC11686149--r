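# Internal helpers shared across modules.

# The 18-variable record schema: the ten fields requested from data providers
# plus identifier/annotation fields filled in (or left missing) by each source.
SCHEMA_FIELDS <- c(
  "record_id", "source_id", "breed_raw", "crossbred_flag", "sex", "dob",
  "postcode_area", "name_prefix", "chip_suffix", "chip_suffix_2", "status",
  "termination_date", "longevity", "age_group", "region", "country",
  "purebred_flag", "crossbred_description"
)

# Key variables used by deduplication phases 3-4.
KEY_FIELDS <- c("breed_canonical", "sex", "dob", "name_prefix")

AGE_GROUPS <- c("puppy", "juvenile", "young_adult", "mature_adult",
                "senior", "geriatric")

# Maximum age retained after filtering (years): the age by which ~95% of pet
# dogs are deceased, used to exclude dogs unlikely to be alive in the study year.
AGE_CAP_YEARS <- 18.3

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Percentages and population figures in reports are rounded half away from
#' zero (so 0.05 -> 0.1), the convention used throughout the package's tables,
#' rather than base R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.05, 0.15, -0.05), 1)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All package randomness flows through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a root seed; kept well below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 31L + offset) %% 2147480000)
}

# Memoised readers for the packaged reference tables.
.dogpop_cache <- new.env(parent = emptyenv())

read_pkg_table <- function(file) {
  if (!is.null(.dogpop_cache[[file]])) return(.dogpop_cache[[file]])
  path <- system.file("extdata", file, package = "dogpop")
  if (!nzchar(path)) stop("packaged table not found: ", file)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  .dogpop_cache[[file]] <- tab
  tab
}

#' Packaged breed reference tables
#'
#' The package ships editable starter tables: canonical purebred names with
#' body-size and cephalic-index classes plus popularity weights
#' (`breed_attributes()`), alternative spellings collapsed to canonical names
#' (`breed_aliases()`), and recognised named crosses such as the Cockerpoo
#' (`named_crosses()`). They drive both breed normalisation and the synthetic
#' generator; replacing the CSVs under `extdata/` changes behaviour without
#' code changes.
#'
#' @return a data.frame.
#' @export
breed_attributes <- function() read_pkg_table("breed_attributes.csv")

#' @rdname breed_attributes
#' @export
breed_aliases <- function() read_pkg_table("breed_aliases.csv")

#' @rdname breed_attributes
#' @export
named_crosses <- function() read_pkg_table("named_crosses.csv")

dog_names <- function() read_pkg_table("dog_names.csv")$name

# Standardise a covariate to mean 0 / sd 1, keeping the transform so new data
# can be placed on the same scale.
standardize_covariate <- function(x, center = NULL, scale = NULL) {
  center <- center %||% mean(x)
  scale <- scale %||% sd(x)
  if (!is.finite(scale) || scale <= 0) scale <- 1
  structure((x - center) / scale, center = center, scale = scale)
}

# md5 of an object's canonical JSON (names sorted recursively); used for
# config hashing in run manifests.
canonical_hash <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v))) {
      v <- v[order(names(v))]
      lapply(v, sort_rec)
    } else if (is.list(v)) lapply(v, sort_rec) else v
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
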