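#' Percentage quadratic dissimilarity between two abundance profiles
#'
#' The core statistic of the package, on the 0-1 scale:
#' \deqn{Z = \sqrt{\tfrac12 \sum_t (f_{case,t} - f_{control,t})^2}}
#' where both vectors are relative-abundance profiles aligned to the union of
#' their taxa (a taxon absent from one side contributes its full squared
#' abundance). Z is symmetric, 0 for identical profiles and 1 for fully
#' disjoint one-hot profiles; for any two points on the probability simplex
#' it stays within [0, 1].
#'
#' @param f_case,f_controls non-negative numeric vectors each summing to
#'   1 (tolerance `1e-6`). If both are named, they are aligned on the union
#'   of their names; unnamed vectors must have equal length.
#' @return a number in `[0, 1]`.
#' @export
#' @examples
#' quadratic_dissimilarity(c(a = 1, b = 0), c(a = 0, b = 1))  # 1
#' quadratic_dissimilarity(c(0.5, 0.5, 0), c(0, 0.5, 0.5))    # 0.5
quadratic_dissimilarity <- function(f_case, f_controls) {
  al <- align_union(f_case, f_controls)
  a <- al[[1]]; b <- al[[2]]
  for (v in list(a, b)) {
    if (any(v < 0)) stop("abundance vectors must be non-negative")
    if (sum(v) == 0) stop("abundance vector sums to zero")
    if (abs(sum(v) - 1) > 1e-6)
      stop("abundance vector does not sum to 1 (got ", format(sum(v)), ")")
  }
  sqrt(0.5 * sum((a - b)^2))
}

# align two vectors on the union of their names (absent taxa = 0)
align_union <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    taxa <- union(names(a), names(b))
    fa <- stats::setNames(numeric(length(taxa)), taxa)
    fb <- fa
    fa[names(a)] <- a
    fb[names(b)] <- b
    list(fa, fb)
  } else {
    if (length(a) != length(b))
      stop("unnamed abundance vectors must have equal length")
    list(a, b)
  }
}

#' Classify a dysbiosis index percentage
#'
#' Mild below 25\%, moderate from 25\% to 35\% (both endpoints included),
#' high above 35\%.
#'
#' @param mdi_percent number(s) in `[0, 100]`.
#' @param mild_max,moderate_max class boundaries (percent).
#' @return factor with levels `mild`, `moderate`, `high`.
#' @export
classify_mdi <- function(mdi_percent, mild_max = 25, moderate_max = 35) {
  if (any(mdi_percent < 0 | mdi_percent > 100))
    stop("MDI percent must lie in [0, 100]")
  cls <- ifelse(mdi_percent < mild_max, "mild",
                ifelse(mdi_percent <= moderate_max, "moderate", "high"))
  factor(cls, levels = c("mild", "moderate", "high"))
}

#' Compute the microbial dysbiosis index for one subject
#'
#' The quadratic dissimilarity against the matched reference is computed at
#' each taxonomic level present in both the case profile and the reference,
#' and the index is 100 times the unweighted mean of the per-level values.
#'
#' @param case a `multi_level_profile` (see [build_profiles()]).
#' @param ref a [build_reference()] result.
#' @param age_years,gender used for stratum matching.
#' @param min_controls passed to [match_stratum()].
#' @param mild_max,moderate_max class boundaries passed to [classify_mdi()].
#' @return an `mdi_result`: list with `subject_id`, `z_by_level`,
#'   `mdi_percent`, `dysbiosis_class`, `reference_provenance`.
#' @export
compute_mdi <- function(case, ref, age_years, gender, min_controls = 5,
                        mild_max = 25, moderate_max = 35) {
  stopifnot(inherits(case, "multi_level_profile"))
  matched <- match_stratum(age_years, gender, ref, min_controls)
  levels <- intersect(names(case$levels), names(matched$levels))
  if (!length(levels))
    stop("no taxonomic level shared between case and reference")
  z <- vapply(levels, function(lv)
    quadratic_dissimilarity(case$levels[[lv]], matched$levels[[lv]]),
    numeric(1))
  mdi <- 100 * mean(z)
  structure(list(subject_id = case$subject_id,
                 z_by_level = z,
                 mdi_percent = mdi,
                 dysbiosis_class = as.character(
                   classify_mdi(mdi, mild_max, moderate_max)),
                 reference_provenance = attr(matched, "provenance")),
            class = "mdi_result")
}

#' @export
print.mdi_result <- function(x, ...) {
  cat(sprintf("<mdi_result> %s: MDI = %.2f%% (%s; ref %s)\n", x$subject_id,
              x$mdi_percent, x$dysbiosis_class, x$reference_provenance))
  invisible(x)
}

#' Compute MDI for a whole cohort
#'
#' @param profiles list of `multi_level_profile` for the case subjects.
#' @param ref a `reference_set`.
#' @param metadata metadata with `subject_id`, `age_years`, `gender`.
#' @param ... passed to [compute_mdi()].
#' @return list of `mdi_result`.
#' @export
compute_mdi_cohort <- function(profiles, ref, metadata, ...) {
  meta <- unique(metadata[, c("subject_id", "age_years", "gender")])
  lapply(profiles, function(p) {
    i <- match(p$subject_id, meta$subject_id)
    if (is.na(i)) stop("metadata missing for subject ", p$subject_id)
    compute_mdi(p, ref, meta$age_years[i], meta$gender[i], ...)
  })
}

#' Summarise a cohort by dysbiosis class
#'
#' @param results list of `mdi_result`, or a factor/character vector of
#'   classes, or a numeric vector of MDI percentages.
#' @return data.frame with `class`, `n`, `percent` (one decimal, half-up;
#'   percentages sum to 100 within rounding).
#' @export
stratify_cohort <- function(results) {
  cls <- if (is.numeric(results)) classify_mdi(results)
  else if (is.list(results))
    vapply(results, `[[`, character(1), "dysbiosis_class")
  else results
  cls <- factor(as.character(cls), levels = c("mild", "moderate", "high"))
  if (!length(cls)) stop("nothing to summarise")
  n <- table(cls)
  data.frame(class = names(n),
             n = as.integer(n),
             percent = round_half_up(100 * as.integer(n) / length(cls), 1),
             stringsAsFactors = FALSE)
}

#' Write / read an MDI report
#'
#' TSV with one row per subject: `subject_id`, one `Z_<level>` column per
#' taxonomic level, `MDI_percent`, `class`, `reference`. Values survive a
#' round trip to at least six significant digits.
#'
#' @param results non-empty list of `mdi_result`.
#' @param path file path.
#' @return `path` invisibly; `read_mdi_report()` returns a data.frame.
#' @export
write_mdi_report <- function(results, path) {
  if (!length(results)) stop("nothing to write: empty result list")
  levels <- names(results[[1]]$z_by_level)
  rows <- lapply(results, function(r) {
    z <- stats::setNames(as.list(r$z_by_level[levels]), paste0("Z_", levels))
    c(list(subject_id = r$subject_id), z,
      list(MDI_percent = r$mdi_percent, class = r$dysbiosis_class,
           reference = r$reference_provenance %||% NA_character_))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) format(col, digits = 10,
                                                  trim = TRUE,
                                                  scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_mdi_report
#' @export
read_mdi_report <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
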