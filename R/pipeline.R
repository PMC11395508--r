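#' Run the full dysbiosis-scoring workflow
#'
#' Wires the modules into the standard analysis order: genus collapse ->
#' prevalence/abundance filter -> three normalisation branches (rarefaction
#' for diversity, relative abundance for the dysbiosis index, CSS for the
#' correlation battery) -> reference building from controls -> per-case MDI
#' and classification -> taxa-MDI correlations -> optional faecal-ileal
#' network. All artifacts are written under `out_dir`; inputs are never
#' modified. A rerun with the same config and seed reproduces every output
#' byte for byte.
#'
#' @param table a [taxa_table()] of counts with lineages, or a TSV path.
#' @param metadata metadata data.frame or TSV path (see [read_metadata()]).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed used for every stochastic stage.
#' @param ileal_table optional second counts table (same subjects) for the
#'   faecal-ileal network; its sample ids must map to subjects via
#'   `ileal_metadata` (defaults to `metadata`).
#' @param ileal_metadata metadata for `ileal_table`.
#' @param min_prevalence,min_ra filter thresholds
#'   (see [prevalence_abundance_filter()]).
#' @param rarefy_depth rarefaction depth; default = smallest sample total.
#' @param css_percentile,css_scale CSS parameters (see [css_normalize()]).
#' @param age_bins,min_controls reference stratification parameters.
#' @param mild_max,moderate_max MDI class boundaries (percent).
#' @param n_perm PERMANOVA permutations.
#' @param p_threshold network edge threshold.
#' @return (invisibly) a list with the in-memory results: `mdi_results`,
#'   `stratification`, `correlations`, `alpha`, `permanova`, `network`,
#'   `reference`, `manifest`.
#' @export
run_pipeline <- function(table, metadata, out_dir, seed = 1,
                         ileal_table = NULL, ileal_metadata = NULL,
                         min_prevalence = 0.25, min_ra = 0.01,
                         rarefy_depth = NULL,
                         css_percentile = 0.5, css_scale = 1000,
                         age_bins = c(0, 4, 11, 19), min_controls = 5,
                         mild_max = 25, moderate_max = 35,
                         n_perm = 999, p_threshold = 0.05) {
  if (is.character(table)) table <- read_taxa_table(table, "counts")
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))

  check_samples_present(metadata, table)

  # collapse + filter
  genus <- stage("collapse", collapse_to_level(table, "genus"))
  filtered <- stage("filter",
    prevalence_abundance_filter(genus, min_prevalence, min_ra))
  write_taxa_table(filtered, out("filtered_genus.tsv"))

  # diversity branch: rarefy, alpha, beta
  depth <- rarefy_depth %||% min(colSums(filtered$values))
  rare <- stage("rarefy", rarefy_table(filtered, depth, seed = seed))
  write_taxa_table(rare, out("rarefied_genus.tsv"))
  alpha <- stage("alpha_diversity", alpha_diversity(rare))
  utils::write.table(alpha, out("alpha_diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  beta <- stage("beta_diversity", beta_diversity(rare))
  utils::write.table(as.matrix(beta), out("beta_diversity.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)

  # MDI branch: profiles, reference, per-case index
  is_ctrl <- metadata$role == "control"
  profiles <- stage("profiles", build_profiles(filtered, metadata))
  ctrl_ids <- unique(metadata$subject_id[is_ctrl])
  case_ids <- unique(metadata$subject_id[!is_ctrl])
  ref <- stage("reference",
    build_reference(profiles[ctrl_ids], metadata[is_ctrl, ], age_bins))
  write_reference_json(ref, out("reference.json"))
  mdi_results <- stage("mdi",
    compute_mdi_cohort(profiles[case_ids], ref, metadata[!is_ctrl, ],
                       min_controls = min_controls, mild_max = mild_max,
                       moderate_max = moderate_max))
  write_mdi_report(mdi_results, out("mdi_report.tsv"))
  strat <- stratify_cohort(mdi_results)
  utils::write.table(strat, out("stratification.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # PERMANOVA of beta diversity across dysbiosis classes (case samples)
  mdi_pct <- vapply(mdi_results, `[[`, numeric(1), "mdi_percent")
  cls <- vapply(mdi_results, `[[`, character(1), "dysbiosis_class")
  case_samples <- metadata$sample_id[match(case_ids, metadata$subject_id)]
  in_rare <- case_samples %in% sample_ids(rare)
  perm <- tryCatch({
    grp <- cls[in_rare]
    sub <- stats::as.dist(as.matrix(beta)[case_samples[in_rare],
                                          case_samples[in_rare]])
    permanova(sub, grp, n_perm = n_perm, seed = seed)
  }, error = function(e) list(pseudo_F = NA_real_, p = NA_real_,
                              note = conditionMessage(e)))

  # correlation branch: CSS-normalised genus abundances vs MDI
  css <- stage("css", css_normalize(filtered, css_percentile, css_scale))
  write_taxa_table(css, out("css_genus.tsv"))
  mdi_by_sample <- stats::setNames(mdi_pct[match(case_ids, names(mdi_pct))],
                                   case_samples)
  corr <- stage("correlate", suppressWarnings(
    correlate_with_mdi(css, mdi_by_sample)))
  utils::write.table(corr, out("correlations_faecal.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # optional niche network
  network <- NULL
  if (!is.null(ileal_table)) {
    if (is.character(ileal_table))
      ileal_table <- read_taxa_table(ileal_table, "counts")
    imeta <- ileal_metadata %||% metadata
    fg <- rename_to_subjects(filtered, metadata)
    ig <- rename_to_subjects(collapse_to_level(ileal_table, "genus"), imeta)
    network <- stage("network", suppressWarnings(
      build_niche_network(fg, ig, p_threshold = p_threshold)))
    write_network(network, out("network_edges.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mdikit")),
    seed = seed,
    parameters = list(min_prevalence = min_prevalence, min_ra = min_ra,
                      rarefy_depth = depth, css_percentile = css_percentile,
                      css_scale = css_scale, age_bins = age_bins,
                      min_controls = min_controls, mild_max = mild_max,
                      moderate_max = moderate_max, n_perm = n_perm,
                      p_threshold = p_threshold),
    counts = list(input_taxa = n_taxa(table), input_samples = n_samples(table),
                  genus_taxa = n_taxa(genus),
                  filtered_taxa = n_taxa(filtered),
                  rarefied_samples = n_samples(rare),
                  controls = length(ctrl_ids), cases = length(case_ids),
                  mdi_rows = length(mdi_results),
                  correlation_rows = nrow(corr),
                  network_edges = if (is.null(network)) 0L
                                  else nrow(network$edges)),
    permanova = perm[c("pseudo_F", "p")])
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(mdi_results = mdi_results, stratification = strat,
                 correlations = corr, alpha = alpha, permanova = perm,
                 network = network, reference = ref, manifest = manifest))
}

# relabel sample columns by owning subject (first sample per subject)
rename_to_subjects <- function(table, metadata) {
  i <- match(sample_ids(table), metadata$sample_id)
  keep <- !is.na(i) & !duplicated(metadata$subject_id[i])
  v <- table$values[, keep, drop = FALSE]
  colnames(v) <- metadata$subject_id[i][keep]
  taxa_table(v, lineages = table$lineages, value_kind = table$value_kind)
}
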