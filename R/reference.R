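#' Healthy-reference profile set stratified by age and gender
#'
#' Builds, for every (age bin, gender) stratum with at least one contributing
#' control, the per-level median relative-abundance profile across that
#' stratum's controls. The taxon universe of a stratum is the union of taxa
#' seen in its controls (absent taxa enter the median as 0) and the median
#' vector is renormalised to sum 1, which keeps the dissimilarity index inside
#' its [0, 1] bound. The raw control profiles are retained so that matching
#' can fall back to wider control pools for thin strata.
#'
#' @param control_profiles list of `multi_level_profile` for control subjects
#'   (see [build_profiles()]).
#' @param metadata metadata data.frame carrying `subject_id`, `age_years`,
#'   `gender` for those subjects.
#' @param age_bins ordered numeric break points in years; bin i is
#'   `[age_bins[i], age_bins[i+1])`. Default paediatric bins 0-4, 4-11, 11-19.
#' @return an object of class `reference_set`.
#' @export
build_reference <- function(control_profiles, metadata,
                            age_bins = c(0, 4, 11, 19)) {
  if (!length(control_profiles)) stop("empty control list")
  if (is.unsorted(age_bins, strictly = TRUE))
    stop("`age_bins` must be strictly increasing break points")
  meta <- unique(metadata[, c("subject_id", "age_years", "gender")])
  ids <- vapply(control_profiles, `[[`, character(1), "subject_id")
  names(control_profiles) <- ids
  meta <- meta[match(ids, meta$subject_id), , drop = FALSE]
  if (anyNA(meta$subject_id))
    stop("metadata missing for control subject(s): ",
         paste(ids[is.na(meta$subject_id)], collapse = ", "))
  bin_idx <- assign_age_bin(meta$age_years, age_bins)
  keys <- paste(bin_label(bin_idx, age_bins), meta$gender, sep = "|")
  strata <- lapply(split(seq_along(ids), keys), function(i)
    list(profile = median_profile(control_profiles[i]), count = length(i)))
  structure(list(strata = strata,
                 age_bins = age_bins,
                 controls = control_profiles,
                 control_meta = data.frame(subject_id = meta$subject_id,
                                           age_years = meta$age_years,
                                           gender = meta$gender,
                                           bin = bin_idx,
                                           stringsAsFactors = FALSE)),
            class = "reference_set")
}

assign_age_bin <- function(age, breaks) {
  idx <- findInterval(age, breaks, rightmost.closed = FALSE)
  # ages outside the grid are clamped to the edge bins
  pmin(pmax(idx, 1L), length(breaks) - 1L)
}

bin_label <- function(idx, breaks) {
  sprintf("[%g,%g)", breaks[idx], breaks[idx + 1L])
}

# per-level, per-taxon median across profiles over the union taxon universe,
# renormalised to the simplex
median_profile <- function(profiles) {
  levels <- Reduce(union, lapply(profiles, function(p) names(p$levels)))
  out <- lapply(levels, function(lv) {
    vecs <- lapply(profiles, function(p) p$levels[[lv]])
    vecs <- vecs[!vapply(vecs, is.null, logical(1))]
    taxa <- Reduce(union, lapply(vecs, names))
    m <- vapply(vecs, function(v) {
      full <- stats::setNames(numeric(length(taxa)), taxa)
      full[names(v)] <- v
      full
    }, numeric(length(taxa)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(taxa),
                                     dimnames = list(taxa, NULL))
    renormalize_simplex(apply(m, 1, stats::median))
  })
  names(out) <- levels
  structure(list(subject_id = NA_character_, levels = out),
            class = "multi_level_profile")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d strata, %d controls, bins %s\n",
              length(x$strata), length(x$controls),
              paste(x$age_bins, collapse = "/")))
  for (k in names(x$strata))
    cat(sprintf("  %-18s n = %d\n", k, x$strata[[k]]$count))
  invisible(x)
}

#' Match a subject to its reference stratum
#'
#' Returns the median profile of the (age bin, gender) stratum for a subject.
#' Thin strata fall back along a cascade, re-medianing over progressively
#' wider control pools until at least `min_controls` contribute:
#' (1) pool both genders within the age bin, (2) widen to the adjacent age
#' bins (genders pooled), (3) pool all controls. The level used is recorded in
#' attribute `provenance` (`"exact"`, `"gender_pooled"`, `"age_widened"`,
#' `"all_pooled"`).
#'
#' @param age_years,gender subject age in years and `"male"`/`"female"`.
#' @param ref a [build_reference()] result.
#' @param min_controls minimum controls a stratum needs before falling back.
#' @return a `multi_level_profile` with attribute `provenance`.
#' @export
match_stratum <- function(age_years, gender, ref, min_controls = 5) {
  stopifnot(inherits(ref, "reference_set"))
  if (!length(ref$controls)) stop("reference set has no controls")
  meta <- ref$control_meta
  bin <- assign_age_bin(age_years, ref$age_bins)
  pools <- list(
    exact         = meta$bin == bin & meta$gender == gender,
    gender_pooled = meta$bin == bin,
    age_widened   = abs(meta$bin - bin) <= 1L,
    all_pooled    = rep(TRUE, nrow(meta))
  )
  for (prov in names(pools)) {
    sel <- pools[[prov]]
    if (sum(sel) >= min_controls || (prov == "all_pooled" && any(sel))) {
      key <- paste(bin_label(bin, ref$age_bins), gender, sep = "|")
      prof <- if (prov == "exact" && !is.null(ref$strata[[key]]))
        ref$strata[[key]]$profile
      else median_profile(ref$controls[meta$subject_id[sel]])
      attr(prof, "provenance") <-
        if (prov == "exact") paste0(key, "|exact")
        else paste0(bin_label(bin, ref$age_bins), "|", prov)
      attr(prof, "n_controls") <- sum(sel)
      return(prof)
    }
  }
  stop("no controls available to match subject")
}

#' Serialise / read a reference set as JSON
#'
#' The JSON document carries the age bins, the per-stratum medians and
#' counts, and the contributing control profiles (needed for fallback
#' matching), so a fixed reference can ship with a deployment.
#'
#' @param ref a `reference_set`.
#' @param path output (input) file path.
#' @return `path` invisibly; `read_reference_json()` returns a
#'   `reference_set`.
#' @export
write_reference_json <- function(ref, path) {
  stopifnot(inherits(ref, "reference_set"))
  doc <- list(
    age_bins = ref$age_bins,
    strata = lapply(ref$strata, function(s)
      list(count = s$count, levels = lapply(s$profile$levels, as.list))),
    controls = lapply(ref$controls, function(p)
      list(subject_id = p$subject_id, levels = lapply(p$levels, as.list))),
    control_meta = ref$control_meta
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_json
#' @export
read_reference_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_profile <- function(lv_list, sid = NA_character_) {
    lvls <- lapply(lv_list, function(v) unlist(v))
    structure(list(subject_id = sid, levels = lvls),
              class = "multi_level_profile")
  }
  controls <- lapply(doc$controls, function(p)
    as_profile(p$levels, p$subject_id))
  names(controls) <- vapply(controls, `[[`, character(1), "subject_id")
  meta <- do.call(rbind, lapply(doc$control_meta, function(r)
    data.frame(subject_id = r$subject_id, age_years = r$age_years,
               gender = r$gender, bin = r$bin, stringsAsFactors = FALSE)))
  strata <- lapply(doc$strata, function(s)
    list(profile = as_profile(s$levels), count = s$count))
  structure(list(strata = strata,
                 age_bins = unlist(doc$age_bins),
                 controls = controls,
                 control_meta = meta),
            class = "reference_set")
}
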