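# Four-phase deduplication: exact duplicates, microchip linkage, key-variable
# matching within postcode-area blocks, and partial-key matching. Phases are
# plain state -> state functions behind `dedup_records()` so alternative
# phase definitions can be swapped in without API change.

# Initialise the linkage state from cleaned records. `work` holds one row per
# current cluster (initially one per record); `members` tracks the partition.
init_linkage_state <- function(records) {
  dt <- data.table::as.data.table(records)
  if (!".row" %in% names(dt)) dt[, .row := seq_len(.N)]
  if (!"breed_canonical" %in% names(dt)) {
    nb <- normalize_breed(dt$breed_raw, dt$crossbred_flag)
    dt[, breed_canonical := nb$breed_canonical]
  }
  missing_fields <- setdiff(SCHEMA_FIELDS, names(dt))
  if (length(missing_fields))
    stop("schema mismatch: records lack fields: ",
         paste(missing_fields, collapse = ", "))
  # the breed key is the canonical breed, but a record with no reported
  # breed text is missing the key (normalisation would otherwise coerce it
  # to a fallback category)
  dt[, breed_key := ifelse(is.na(breed_raw), NA_character_, breed_canonical)]
  dt <- dt[, c(SCHEMA_FIELDS, "breed_canonical", "breed_key", ".row"),
           with = FALSE]
  dt[, nonmiss := rowSums(!is.na(as.matrix(
    dt[, lapply(.SD, as.character), .SDcols = SCHEMA_FIELDS])))]
  # cluster labels are row-based (labels are arbitrary; the partition itself
  # is order-invariant because survivorship ties break on record_id)
  dt[, cluster := .row]
  members <- dt[, .(.row, record_id, source_id, postcode_area, nonmiss,
                    cluster, phase = NA_integer_)]
  list(work = dt, members = members,
       phase_counts = c(exact = 0L, microchip = 0L, keys = 0L, partial = 0L),
       n_input = nrow(dt), n_after_phase1 = nrow(dt),
       unresolved = 0L, conflicts = list())
}

# Merge work rows according to `mg` (data.table: wi = work row index, gid =
# merge group). The surviving representative is the most complete member
# (ties: lowest record id); its fields are the field-wise union (first
# non-missing in that order) so later phases see everything known.
merge_work <- function(state, mg, phase_name, phase_no) {
  if (!nrow(mg)) return(state)
  w <- state$work
  sub <- w[mg$wi]
  sub[, .gid := mg$gid]
  data.table::setorder(sub, .gid, -nonmiss, record_id)
  datacols <- setdiff(names(sub), ".gid")
  reps <- sub[, lapply(.SD, function(col) col[!is.na(col)][1]),
              by = .gid, .SDcols = datacols]
  reps[, cluster := sub[, cluster[1], by = .gid]$V1]
  reps[, .gid := NULL]
  reps[, nonmiss := rowSums(!is.na(as.matrix(
    reps[, lapply(.SD, as.character), .SDcols = SCHEMA_FIELDS])))]
  removed <- nrow(sub) - length(unique(mg$gid))

  # reassign members of absorbed clusters; absorbed reps get this phase
  remap <- sub[, .(old = cluster, new = cluster[1]), by = .gid]
  remap <- remap[old != new]
  if (nrow(remap)) {
    mem <- state$members
    i <- match(mem$cluster, remap$old)
    hit <- !is.na(i)
    mem[hit & is.na(mem$phase), phase := phase_no]
    mem[hit, cluster := remap$new[i[hit]]]
    state$members <- mem
  }
  state$work <- rbind(w[-mg$wi], reps, use.names = TRUE)
  state$phase_counts[phase_name] <- state$phase_counts[phase_name] + removed
  state
}

#' Deduplication phase 1: exact duplicates
#'
#' Collapses byte-identical re-submissions: records agreeing exactly on all
#' 18 schema fields (missingness pattern included) with more than 10 of the
#' 18 fields populated. Groups with 10 or fewer populated fields are left
#' alone. One representative survives per group (most complete, ties by
#' lowest record id).
#'
#' @param state a linkage state from `init_linkage_state()`, or cleaned
#'   records (coerced).
#' @return the updated linkage state.
#' @export
phase1_exact <- function(state) {
  if (!is.list(state) || is.null(state$work)) state <- init_linkage_state(state)
  w <- state$work
  vals <- w[, lapply(.SD, function(x) {
    x <- as.character(x); x[is.na(x)] <- "\x01"; x
  }), .SDcols = SCHEMA_FIELDS]
  key <- do.call(paste, c(vals, sep = "\x1f"))
  key[w$nonmiss <= 10L] <- paste0("\x02solo\x1f", w$.row[w$nonmiss <= 10L])
  dup <- duplicated(key)
  if (any(dup)) {
    gid <- match(key, key)  # index of first occurrence
    ingrp <- gid %in% gid[dup]
    mg <- data.table::data.table(wi = which(ingrp), gid = gid[ingrp])
    state <- merge_work(state, mg, "exact", 1L)
  }
  state$n_after_phase1 <- nrow(state$work)
  state
}

#' Deduplication phase 2: microchip linkage
#'
#' Records sharing any 6-character microchip suffix (primary or secondary),
#' directly or through chains of shared suffixes, are merged unless the group
#' conflicts on sex or DOB, in which case the group is left unmerged and
#' flagged. Records without a chip are untouched.
#'
#' @inheritParams phase1_exact
#' @return the updated linkage state.
#' @export
phase2_microchip <- function(state) {
  if (!is.list(state) || is.null(state$work)) state <- init_linkage_state(state)
  w <- state$work
  i1 <- which(!is.na(w$chip_suffix))
  i2 <- which(!is.na(w$chip_suffix_2))
  edges <- data.table::data.table(
    wi = c(i1, i2), chip = c(w$chip_suffix[i1], w$chip_suffix_2[i2]))
  if (!nrow(edges)) return(state)
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("w", edges$wi), to = paste0("c", edges$chip)),
    directed = FALSE)
  comp <- igraph::components(g)$membership
  wi <- as.integer(sub("^w", "", names(comp)[startsWith(names(comp), "w")]))
  gid <- unname(comp[startsWith(names(comp), "w")])
  cand <- data.table::data.table(wi = wi, gid = gid)
  cand <- cand[gid %in% cand[, .N, by = gid][N >= 2L, gid]]
  if (!nrow(cand)) return(state)
  # conflict check: >1 distinct observed sex or DOB within the group
  info <- w[cand$wi, .(sex, dob)][, gid := cand$gid]
  bad <- info[, .(conflict = data.table::uniqueN(stats::na.omit(sex)) > 1L |
                    data.table::uniqueN(stats::na.omit(dob)) > 1L), by = gid]
  state$conflicts$microchip <- sum(bad$conflict)
  keep <- cand[gid %in% bad[conflict == FALSE, gid]]
  merge_work(state, keep, "microchip", 2L)
}

#' Deduplication phase 3: key-variable matching
#'
#' Blocks on postcode area; within a block, records equal on all four key
#' variables (canonical breed, sex, DOB, name prefix) merge. Records missing
#' any key are deferred to phase 4.
#'
#' @inheritParams phase1_exact
#' @return the updated linkage state.
#' @export
phase3_keys <- function(state) {
  if (!is.list(state) || is.null(state$work)) state <- init_linkage_state(state)
  w <- state$work
  ok <- which(!is.na(w$postcode_area) & !is.na(w$breed_key) &
                !is.na(w$sex) & !is.na(w$dob) & !is.na(w$name_prefix))
  if (!length(ok)) return(state)
  key <- paste(w$postcode_area[ok], w$breed_key[ok], w$sex[ok],
               w$dob[ok], w$name_prefix[ok], sep = "\x1f")
  gid <- match(key, key)
  dupg <- unique(gid[duplicated(gid) | duplicated(gid, fromLast = TRUE)])
  ingrp <- gid %in% dupg
  mg <- data.table::data.table(wi = ok[ingrp], gid = gid[ingrp])
  merge_work(state, mg, "keys", 3L)
}

#' Deduplication phase 4: partial-key matching
#'
#' Records with exactly one missing key merge - first with each other (same
#' missing-key pattern, same area, equal on the three present keys), then
#' into a key-complete cluster when exactly one such cluster in the same area
#' matches the three present keys and microchip evidence does not conflict
#' (both sides carrying chips with none shared). Records with two or more
#' missing keys are retained as singletons and counted into the unresolved
#' fraction.
#'
#' @inheritParams phase1_exact
#' @return the updated linkage state.
#' @export
phase4_partial <- function(state) {
  if (!is.list(state) || is.null(state$work)) state <- init_linkage_state(state)

  kpres <- function(w) (!is.na(w$breed_key)) + (!is.na(w$sex)) +
    (!is.na(w$dob)) + (!is.na(w$name_prefix))
  keymat <- function(w) cbind(w$breed_key, w$sex, w$dob, w$name_prefix)

  # (a) merge one-missing records among themselves, per missing-key pattern
  w <- state$work
  kp <- kpres(w)
  one <- which(kp == 3L & !is.na(w$postcode_area))
  if (length(one)) {
    km <- keymat(w)[one, , drop = FALSE]
    pat <- apply(is.na(km), 1L, which)  # index of the single missing key
    km[is.na(km)] <- ""
    key <- paste(pat, w$postcode_area[one], km[, 1], km[, 2], km[, 3], km[, 4],
                 sep = "\x1f")
    gid <- match(key, key)
    dupg <- unique(gid[duplicated(gid)])
    ingrp <- gid %in% dupg
    if (any(ingrp)) {
      mg <- data.table::data.table(wi = one[ingrp], gid = gid[ingrp])
      state <- merge_work(state, mg, "partial", 4L)
    }
  }

  # (b) merge remaining one-missing records into a unique matching complete
  # cluster in the same area
  w <- state$work
  kp <- kpres(w)
  one <- which(kp == 3L & !is.na(w$postcode_area))
  full <- which(kp == 4L & !is.na(w$postcode_area))
  if (length(one) && length(full)) {
    km_full <- keymat(w)[full, , drop = FALSE]
    km_one <- keymat(w)[one, , drop = FALSE]
    pat_one <- apply(is.na(km_one), 1L, which)
    pairs <- NULL
    for (k in 1:4) {
      oi <- one[pat_one == k]
      if (!length(oi)) next
      keep <- setdiff(1:4, k)
      fkey <- do.call(paste, c(as.data.frame(km_full[, keep, drop = FALSE]),
                               list(w$postcode_area[full], sep = "\x1f")))
      okey <- do.call(paste, c(as.data.frame(
        keymat(w)[oi, keep, drop = FALSE]),
        list(w$postcode_area[oi], sep = "\x1f")))
      hit <- match(okey, fkey)  # first matching full row
      # number of full rows matching each one-missing row's key
      cnt <- table(fkey[fkey %in% okey])
      n_for_o <- as.integer(cnt[okey]); n_for_o[is.na(n_for_o)] <- 0L
      sel <- which(n_for_o == 1L)
      if (!length(sel)) next
      pairs <- rbind(pairs, data.table::data.table(
        wi_one = oi[sel], wi_full = full[hit[sel]]))
    }
    if (!is.null(pairs) && nrow(pairs)) {
      chips <- function(i) {
        v <- c(state$work$chip_suffix[i], state$work$chip_suffix_2[i])
        v[!is.na(v)]
      }
      okc <- vapply(seq_len(nrow(pairs)), function(r) {
        a <- chips(pairs$wi_one[r]); b <- chips(pairs$wi_full[r])
        !length(a) || !length(b) || length(intersect(a, b)) > 0
      }, logical(1))
      pairs <- pairs[okc]
      if (nrow(pairs)) {
        mg <- data.table::data.table(
          wi = c(pairs$wi_full, pairs$wi_one),
          gid = c(pairs$wi_full, pairs$wi_full))
        mg <- unique(mg)
        state <- merge_work(state, mg, "partial", 4L)
      }
    }
  }

  # (c) unresolved: two or more missing keys; retained as singleton clusters
  w <- state$work
  state$unresolved <- sum(kpres(w) <= 2L)
  state
}

DEDUP_PHASES <- list(exact = phase1_exact, microchip = phase2_microchip,
                     keys = phase3_keys, partial = phase4_partial)

#' Deduplicate records across sources
#'
#' Runs the four-phase deduplication and returns the resulting partition of
#' records into individuals. Each phase never increases the record count, and
#' the outcome is invariant to input row order (survivorship is most-complete
#' record, ties broken by lowest record id).
#'
#' @param records cleaned records (from [clean_records()]); must carry the
#'   18-field schema plus `breed_canonical`.
#' @param phases character vector naming built-in phases to run, in order
#'   (default all four), or a named list of `state -> state` functions for
#'   alternative phase definitions.
#' @return an object of class `linkage_result`: `clusters` (data.table:
#'   `.row`, `record_id`, `source_id`, `postcode_area`, `cluster_id`,
#'   `phase_merged`), `phase_counts` (records removed per phase),
#'   `unresolved_fraction` (share of post-phase-1 records with >= 2 missing
#'   keys), `n_records`, `n_clusters`, and `work` (representative rows).
#' @export
dedup_records <- function(records, phases = names(DEDUP_PHASES)) {
  state <- init_linkage_state(records)
  fns <- if (is.list(phases)) phases else DEDUP_PHASES[phases]
  for (f in fns) state <- f(state)
  clusters <- state$members[, .(.row, record_id, source_id, postcode_area,
                                nonmiss, cluster_id = cluster,
                                phase_merged = phase)]
  out <- list(clusters = clusters, phase_counts = state$phase_counts,
              unresolved_fraction = state$unresolved /
                max(1L, state$n_after_phase1),
              n_records = state$n_input, n_clusters = nrow(state$work),
              conflicts = state$conflicts, work = state$work)
  class(out) <- "linkage_result"
  out
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("<linkage_result>", x$n_records, "records ->", x$n_clusters,
      "individuals\n  removed per phase:",
      paste(names(x$phase_counts), x$phase_counts, sep = "=", collapse = ", "),
      sprintf("\n  unresolved fraction: %.3f\n", x$unresolved_fraction))
  invisible(x)
}

#' Build the sites-by-sources count matrix
#'
#' In `"attributed"` mode (default) `y[i, j]` is the number of distinct
#' individuals attributed to source `j` at area `i` after global
#' deduplication: an individual seen by k sources contributes 1 to each of
#' its k columns - this cross-source redundancy is the recapture signal. A
#' cluster's area is the modal area of its member records (ties: the area of
#' the most complete member). `"per-source"` mode instead counts records
#' surviving phase 1 per (area, source), i.e. within-source deduplication
#' only.
#'
#' @param linkage a `linkage_result`.
#' @param geo a `geography_map`; every cluster area must appear in it.
#' @param mode `"attributed"` or `"per-source"`.
#' @return an integer matrix of class `count_matrix` with areas as rows and
#'   source ids as columns.
#' @export
build_count_matrix <- function(linkage, geo,
                               mode = c("attributed", "per-source")) {
  mode <- match.arg(mode)
  mem <- linkage$clusters
  if (mode == "per-source") {
    keep <- mem[is.na(phase_merged) | phase_merged != 1L]
    tab <- keep[!is.na(postcode_area), .N, by = .(postcode_area, source_id)]
    area_of <- tab$postcode_area
  } else {
    ma <- mem[!is.na(postcode_area)]
    cnt <- ma[, .N, by = .(cluster_id, postcode_area)]
    cnt[, mx := max(N), by = cluster_id]
    cand <- cnt[N == mx]
    ntie <- cand[, .N, by = cluster_id]
    single <- cand[cluster_id %in% ntie[N == 1L, cluster_id],
                   .(cluster_id, area = postcode_area)]
    tied_ids <- ntie[N > 1L, cluster_id]
    if (length(tied_ids)) {
      # tie: take the area of the most complete member, then lowest record id
      comp <- mem[cluster_id %in% tied_ids & !is.na(postcode_area)]
      data.table::setorder(comp, cluster_id, -nonmiss, record_id)
      tie_area <- comp[, .(area = postcode_area[1]), by = cluster_id]
      areas <- rbind(single, tie_area)
    } else areas <- single
    src <- unique(mem[, .(cluster_id, source_id)])
    tab <- merge(src, areas, by = "cluster_id")[, .N, by = .(area, source_id)]
    data.table::setnames(tab, "area", "postcode_area")
  }
  bad <- setdiff(unique(tab$postcode_area), geo$area)
  if (length(bad))
    stop("areas not in geography map: ", paste(sort(bad), collapse = ", "))
  sources <- sort(unique(mem$source_id))
  y <- matrix(0L, nrow(geo), length(sources),
              dimnames = list(geo$area, sources))
  y[cbind(match(tab$postcode_area, geo$area),
          match(tab$source_id, sources))] <- tab$N
  class(y) <- c("count_matrix", class(y))
  y
}

#' Score a linkage against ground-truth labels
#'
#' Pairwise precision and recall of the recovered partition against the
#' hidden true-individual labels carried by synthetic records.
#'
#' @param linkage a `linkage_result`.
#' @param records the records that were deduplicated, carrying `true_id`
#'   and `.row` columns.
#' @return list with `precision`, `recall`, `true_pairs`, `linked_pairs`.
#' @export
linkage_metrics <- function(linkage, records) {
  dt <- data.table::as.data.table(records)
  if (!".row" %in% names(dt)) dt[, .row := seq_len(.N)]
  m <- merge(linkage$clusters[, .(.row, cluster_id)],
             dt[, .(.row, true_id)], by = ".row")
  m <- m[!is.na(true_id)]
  ch2 <- function(n) n * (n - 1) / 2
  linked <- sum(ch2(m[, .N, by = cluster_id]$N))
  truth <- sum(ch2(m[, .N, by = true_id]$N))
  tp <- sum(ch2(m[, .N, by = .(cluster_id, true_id)]$N))
  list(precision = if (linked > 0) tp / linked else 1,
       recall = if (truth > 0) tp / truth else 1,
       true_pairs = truth, linked_pairs = linked)
}
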