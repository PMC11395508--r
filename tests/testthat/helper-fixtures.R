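# small in-code fixtures shared across the suite

# 3 genera in 2 families / 2 phyla, counts for `n` samples
make_counts_table <- function(values = NULL, n_samples = 2) {
  lineages <- c(
    g1 = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Ruminococcaceae; g__Faecalibacterium",
    g2 = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__Roseburia",
    g3 = "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Enterobacteriales; f__Enterobacteriaceae; g__Escherichia")
  if (is.null(values))
    values <- matrix(c(10, 0, 90, 20, 5, 75), nrow = 3)[, seq_len(n_samples),
                                                        drop = FALSE]
  dimnames(values) <- list(names(lineages),
                           paste0("s", seq_len(ncol(values))))
  taxa_table(values, lineages = lineages, value_kind = "counts")
}

# uniform random point on the k-simplex
runif_simplex <- function(k) {
  g <- stats::rgamma(k, 1)
  g / sum(g)
}

# full MDI pass over a generated cohort bundle; returns named percent vector
cohort_mdi <- function(bundle, min_controls = 5) {
  md <- bundle$metadata
  profs <- build_profiles(bundle$table, md)
  ctrl <- md[md$role == "control", ]
  case <- md[md$role == "case", ]
  ref <- build_reference(profs[unique(ctrl$subject_id)], ctrl)
  res <- compute_mdi_cohort(profs[unique(case$subject_id)], ref, case,
                            min_controls = min_controls)
  vapply(res, `[[`, numeric(1), "mdi_percent")
}

# one-sample-per-subject metadata for a plain table
simple_metadata <- function(table, role = "case", age = 12, gender = "male") {
  ids <- sample_ids(table)
  data.frame(subject_id = ids, sample_id = ids,
             age_years = age, gender = gender, role = role,
             stringsAsFactors = FALSE)
}

# build a multi_level_profile directly from named level vectors
profile_of <- function(subject_id, ...) {
  structure(list(subject_id = subject_id, levels = list(...)),
            class = "multi_level_profile")
}
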