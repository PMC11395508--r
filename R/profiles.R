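#' Taxonomic levels used by the dysbiosis index
#' @keywords internal
.mdi_levels <- c("phylum", "family", "genus")

.rank_prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                    order = "o__", family = "f__", genus = "g__")

# extract the label at `level` from a rank-prefixed lineage string;
# "" when the rank is absent or empty
lineage_rank <- function(lineages, level) {
  prefix <- .rank_prefixes[[level]]
  parts <- strsplit(lineages %||% character(), ";", fixed = TRUE)
  vapply(parts, function(p) {
    p <- trimws(p)
    hit <- p[startsWith(p, prefix)]
    if (!length(hit)) return("")
    sub(paste0("^", prefix), "", hit[[1]])
  }, character(1))
}

#' Collapse a taxa table to a taxonomic rank
#'
#' Rows sharing the same label at the requested rank are summed; rows whose
#' lineage lacks that rank (or carries an empty label) are pooled into
#' `unclassified_<level>`. Per-sample totals are conserved exactly.
#'
#' @param table a [taxa_table()] with lineages.
#' @param level `"phylum"`, `"family"` or `"genus"`.
#' @return a collapsed `taxa_table`; lineages are truncated at the rank.
#' @export
collapse_to_level <- function(table, level = c("phylum", "family", "genus")) {
  level <- match.arg(level)
  stopifnot(inherits(table, "taxa_table"))
  if (is.null(table$lineages))
    stop("taxa table has no lineages; cannot collapse")
  labels <- lineage_rank(table$lineages, level)
  labels[labels == ""] <- paste0("unclassified_", level)
  groups <- unique(labels)
  v <- rowsum(table$values, group = labels, reorder = FALSE)
  v <- v[groups, , drop = FALSE]
  # keep the lineage truncated at the collapsed rank (first occurrence wins)
  rank_idx <- match(level, names(.rank_prefixes))
  lin <- vapply(groups, function(g) {
    i <- match(g, labels)
    parts <- trimws(strsplit(table$lineages[[i]], ";", fixed = TRUE)[[1]])
    keep <- parts[seq_len(min(rank_idx, length(parts)))]
    paste(keep, collapse = "; ")
  }, character(1))
  if (any(startsWith(groups, "unclassified_")))
    lin[startsWith(groups, "unclassified_")] <- ""
  taxa_table(v, lineages = lin, value_kind = table$value_kind)
}

#' Convert counts to relative abundances
#'
#' Each sample column is divided by its total. All-zero columns stay zero and
#' are reported through a warning (attribute `zero_samples` on the result).
#'
#' @param table a `taxa_table` of counts (or normalized values).
#' @return a `taxa_table` with `value_kind = "relative"`.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "taxa_table"))
  if (table$value_kind == "relative") return(table)
  cs <- colSums(table$values)
  zero <- cs == 0
  scale <- ifelse(zero, 1, cs)
  v <- sweep(table$values, 2, scale, "/")
  out <- taxa_table(v, lineages = table$lineages, value_kind = "relative")
  if (any(zero)) {
    warning("all-zero sample(s) left as zero: ",
            paste(colnames(v)[zero], collapse = ", "))
    attr(out, "zero_samples") <- colnames(v)[zero]
  }
  out
}

#' Prevalence/abundance filter
#'
#' A taxon is retained iff it is "present" — relative abundance >= `min_ra` —
#' in at least a `min_prevalence` fraction of samples, both boundaries
#' inclusive. Mirrors the usual 16S pre-filter of dropping taxa seen at
#' < 1\% relative abundance in < 25\% of samples. Relative abundances are
#' computed internally when the table holds counts; the returned table keeps
#' the original values of the retained taxa.
#'
#' @param table a `taxa_table`.
#' @param min_prevalence fraction of samples in `[0, 1]`.
#' @param min_ra relative-abundance presence threshold in `[0, 1]`.
#' @return filtered `taxa_table`; removed taxa in attribute `removed`.
#' @export
prevalence_abundance_filter <- function(table, min_prevalence = 0.25,
                                        min_ra = 0.01) {
  stopifnot(inherits(table, "taxa_table"))
  if (min_prevalence < 0 || min_prevalence > 1)
    stop("`min_prevalence` must be in [0, 1]")
  if (min_ra < 0 || min_ra > 1) stop("`min_ra` must be in [0, 1]")
  ra <- to_relative_abundance(table)$values
  present <- ra >= min_ra
  prevalence <- rowMeans(present)
  keep <- prevalence >= min_prevalence
  # dropping rows of a relative table takes its columns off the simplex;
  # the survivors keep their original values but lose the "relative" badge
  kind <- if (table$value_kind == "relative") "normalized"
          else table$value_kind
  out <- taxa_table(table$values[keep, , drop = FALSE],
                    lineages = table$lineages[keep],
                    value_kind = kind)
  attr(out, "removed") <- taxon_ids(table)[!keep]
  out
}

#' Cumulative sum scaling (CSS) normalisation
#'
#' Per sample j, the scaling factor is the sum of that sample's counts that do
#' not exceed the `percentile` quantile of its nonzero counts; output values
#' are `count / s_j * scale`. A fixed quantile is used so the transform is
#' deterministic; 0.5 (the median of nonzero counts) is the default.
#'
#' @param table a `taxa_table` of counts.
#' @param percentile quantile of the nonzero count distribution in `(0, 1]`.
#' @param scale output scale (counts per `scale` "reads").
#' @return a `taxa_table` with `value_kind = "normalized"`.
#' @export
css_normalize <- function(table, percentile = 0.5, scale = 1000) {
  stopifnot(inherits(table, "taxa_table"))
  if (table$value_kind != "counts") stop("CSS requires a counts table")
  if (percentile <= 0 || percentile > 1) stop("`percentile` must be in (0, 1]")
  v <- table$values
  s <- vapply(seq_len(ncol(v)), function(j) {
    col <- v[, j]
    nz <- col[col > 0]
    if (!length(nz))
      stop("all-zero sample cannot be CSS-normalised: ", colnames(v)[j])
    q <- stats::quantile(nz, probs = percentile, names = FALSE)
    sum(col[col <= q])
  }, numeric(1))
  out <- sweep(v, 2, s, "/") * scale
  taxa_table(out, lineages = table$lineages, value_kind = "normalized")
}

#' Rarefy counts to a common depth
#'
#' Each sample is subsampled without replacement (hypergeometric) to exactly
#' `depth` reads via [vegan::rrarefy()]. Samples below `depth` are dropped
#' with a warning, or abort the run when `shallow = "error"`.
#'
#' @param table a `taxa_table` of integer counts.
#' @param depth target depth (positive integer).
#' @param seed integer seed; the same seed reproduces the same table.
#' @param shallow `"drop"` or `"error"` for samples with fewer reads.
#' @return a rarefied `taxa_table` of counts; every column sums to `depth`.
#' @export
rarefy_table <- function(table, depth, seed, shallow = c("drop", "error")) {
  shallow <- match.arg(shallow)
  stopifnot(inherits(table, "taxa_table"))
  if (table$value_kind != "counts") stop("rarefaction requires counts")
  if (depth <= 0) stop("`depth` must be positive")
  v <- table$values
  if (any(abs(v - round(v)) > 1e-8)) stop("rarefaction requires integer counts")
  cs <- colSums(v)
  low <- cs < depth
  if (any(low)) {
    msg <- paste(colnames(v)[low], collapse = ", ")
    if (shallow == "error")
      stop("sample(s) below rarefaction depth ", depth, ": ", msg)
    warning("dropping sample(s) below rarefaction depth ", depth, ": ", msg)
    v <- v[, !low, drop = FALSE]
  }
  if (!ncol(v)) stop("no samples at or above rarefaction depth")
  sub <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(t(v), sample = depth),
    # vegan cautions whenever the smallest nonzero count exceeds 1, which is
    # routine for legitimate count tables; silence only that message
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  taxa_table(t(sub), lineages = table$lineages, value_kind = "counts")
}

#' Build per-subject multi-level relative-abundance profiles
#'
#' For every subject in `metadata`, the table is collapsed at the phylum,
#' family and genus ranks and converted to relative abundances. A subject with
#' one sample gets that sample's vector; with several samples, the per-taxon
#' median across the subject's samples is taken and the vector renormalised to
#' sum 1 (coordinate-wise medians need not live on the simplex).
#'
#' @param table a `taxa_table` with lineages (counts or relative).
#' @param metadata metadata data.frame with `subject_id`, `sample_id`.
#' @param levels taxonomic ranks to profile.
#' @return a named list of `multi_level_profile` objects (one per subject),
#'   each a list with `subject_id` and `levels` (rank -> named abundance
#'   vector summing to 1).
#' @export
build_profiles <- function(table, metadata, levels = .mdi_levels) {
  stopifnot(inherits(table, "taxa_table"))
  check_samples_present(metadata, table)
  subjects <- unique(metadata$subject_id)
  rel_by_level <- lapply(levels, function(lv)
    to_relative_abundance(collapse_to_level(table, lv))$values)
  names(rel_by_level) <- levels
  out <- lapply(subjects, function(sid) {
    samples <- metadata$sample_id[metadata$subject_id == sid]
    if (!length(samples)) stop("subject with no samples: ", sid)
    lvls <- lapply(rel_by_level, function(m) {
      sub <- m[, samples, drop = FALSE]
      med <- apply(sub, 1, stats::median)
      renormalize_simplex(med)
    })
    structure(list(subject_id = sid, levels = lvls),
              class = "multi_level_profile")
  })
  names(out) <- subjects
  out
}

# rescale a non-negative vector to sum 1 (error on all-zero)
renormalize_simplex <- function(x) {
  s <- sum(x)
  if (s <= 0) stop("cannot renormalise an all-zero abundance vector")
  x / s
}

#' @export
print.multi_level_profile <- function(x, ...) {
  cat(sprintf("<multi_level_profile> subject %s: %s\n", x$subject_id,
              paste(sprintf("%s (%d taxa)", names(x$levels),
                            lengths(x$levels)), collapse = ", ")))
  invisible(x)
}
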