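#' Genus catalogue used by the synthetic cohort generator
#'
#' A fixed set of gut genera with Greengenes-style lineages, baseline
#' relative weights, and ecological roles: `inflamm` taxa are enriched and
#' `protect` taxa depleted as the injected dysbiosis effect grows, mirroring
#' the pro-inflammatory (Enterobacteriaceae-like) expansion and loss of
#' butyrate producers (Faecalibacterium-like) seen in IBD guts.
#'
#' @return data.frame with `genus`, `family`, `phylum`, `weight`, `role`.
#' @export
default_taxon_catalog <- function() {
  rows <- list(
    # genus, family, phylum, baseline weight, role
    c("Faecalibacterium", "Ruminococcaceae", "Firmicutes", 32, "protect"),
    c("Oscillospira", "Ruminococcaceae", "Firmicutes", 2.5, "neutral"),
    c("Ruminococcus", "Ruminococcaceae", "Firmicutes", 3, "neutral"),
    c("Butyricicoccus", "Ruminococcaceae", "Firmicutes", 2, "neutral"),
    c("Gemmiger", "Ruminococcaceae", "Firmicutes", 1, "neutral"),
    c("Blautia", "Lachnospiraceae", "Firmicutes", 4, "neutral"),
    c("Roseburia", "Lachnospiraceae", "Firmicutes", 4, "neutral"),
    c("Coprococcus", "Lachnospiraceae", "Firmicutes", 2.5, "neutral"),
    c("Dorea", "Lachnospiraceae", "Firmicutes", 1.5, "neutral"),
    c("Anaerostipes", "Lachnospiraceae", "Firmicutes", 1, "neutral"),
    c("Lachnospira", "Lachnospiraceae", "Firmicutes", 1.5, "neutral"),
    c("Clostridium", "Lachnospiraceae", "Firmicutes", 1.5, "neutral"),
    c("Veillonella", "Veillonellaceae", "Firmicutes", 0.6, "neutral"),
    c("Dialister", "Veillonellaceae", "Firmicutes", 1, "neutral"),
    c("Streptococcus", "Streptococcaceae", "Firmicutes", 1, "neutral"),
    c("Lactobacillus", "Lactobacillaceae", "Firmicutes", 0.8, "neutral"),
    c("Enterococcus", "Enterococcaceae", "Firmicutes", 0.3, "neutral"),
    c("Gemella", "Gemellaceae", "Firmicutes", 0.2, "neutral"),
    c("Turicibacter", "Erysipelotrichaceae", "Firmicutes", 0.4, "neutral"),
    c("Christensenella", "Christensenellaceae", "Firmicutes", 0.4, "neutral"),
    c("Bacteroides", "Bacteroidaceae", "Bacteroidetes", 22, "protect"),
    c("Prevotella", "Prevotellaceae", "Bacteroidetes", 2, "neutral"),
    c("Alistipes", "Rikenellaceae", "Bacteroidetes", 2, "neutral"),
    c("Parabacteroides", "Porphyromonadaceae", "Bacteroidetes", 2.5, "neutral"),
    c("Barnesiella", "Barnesiellaceae", "Bacteroidetes", 1, "neutral"),
    c("Odoribacter", "Odoribacteraceae", "Bacteroidetes", 0.8, "neutral"),
    c("Escherichia", "Enterobacteriaceae", "Proteobacteria", 3, "inflamm"),
    c("Klebsiella", "Enterobacteriaceae", "Proteobacteria", 0.4, "inflamm"),
    c("Enterobacter", "Enterobacteriaceae", "Proteobacteria", 0.3, "inflamm"),
    c("Haemophilus", "Pasteurellaceae", "Proteobacteria", 0.5, "neutral"),
    c("Actinobacillus", "Pasteurellaceae", "Proteobacteria", 0.25, "neutral"),
    c("Sutterella", "Alcaligenaceae", "Proteobacteria", 0.8, "neutral"),
    c("Achromobacter", "Alcaligenaceae", "Proteobacteria", 0.2, "neutral"),
    c("Pseudomonas", "Pseudomonadaceae", "Proteobacteria", 0.2, "neutral"),
    c("Fusobacterium", "Fusobacteriaceae", "Fusobacteria", 0.3, "neutral"),
    c("Bifidobacterium", "Bifidobacteriaceae", "Actinobacteria", 4, "neutral"),
    c("Eggerthella", "Coriobacteriaceae", "Actinobacteria", 0.4, "neutral"),
    c("Collinsella", "Coriobacteriaceae", "Actinobacteria", 1, "neutral"),
    c("Actinomyces", "Actinomycetaceae", "Actinobacteria", 0.25, "neutral"),
    c("Akkermansia", "Verrucomicrobiaceae", "Verrucomicrobia", 2.5, "neutral"))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("genus", "family", "phylum", "weight", "role")
  df$weight <- as.numeric(df$weight)
  df$weight <- df$weight / sum(df$weight)
  df
}

.phylum_class_order <- c(
  Firmicutes = "c__Clostridia; o__Clostridiales",
  Bacteroidetes = "c__Bacteroidia; o__Bacteroidales",
  Proteobacteria = "c__Gammaproteobacteria; o__Enterobacteriales",
  Fusobacteria = "c__Fusobacteriia; o__Fusobacteriales",
  Actinobacteria = "c__Actinobacteria; o__Bifidobacteriales",
  Verrucomicrobia = "c__Verrucomicrobiae; o__Verrucomicrobiales")

catalog_lineages <- function(catalog) {
  sprintf("k__Bacteria; p__%s; %s; f__%s; g__%s",
          catalog$phylum, .phylum_class_order[catalog$phylum],
          catalog$family, catalog$genus)
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_controls,n_cases cohort sizes.
#' @param base_concentration Dirichlet concentration of the community draw;
#'   lower values give more between-subject overdispersion.
#' @param effect_size maximum dysbiosis shift: each case's true effect is
#'   drawn Uniform(0, `effect_size`), the mass (as a fraction of the
#'   community) moved from protective to pro-inflammatory taxa.
#' @param depth sequencing depth (multinomial reads per sample), >= 100.
#' @param score_link `c(a, b, sd)`: clinical activity score =
#'   `a + b * true_effect + Normal(0, sd)`, clipped to the instrument range.
#' @param catalog taxon catalogue (see [default_taxon_catalog()]).
#' @param inflamm_taxa,protect_taxa genus names overriding the catalogue
#'   roles (must be disjoint).
#' @param marker_means,marker_sds means/SDs of the lognormally drawn
#'   microbiota-associated markers (indican mg/L, zonulin ng/mL, sIgA ug/mL).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_controls = 50, n_cases = 35,
                         base_concentration = 50, effect_size = 0.2,
                         depth = 10000, score_link = c(5, 100, 3),
                         catalog = default_taxon_catalog(),
                         inflamm_taxa = NULL, protect_taxa = NULL,
                         marker_means = c(indican = 91.77, zonulin = 211.42,
                                          sIgA = 3265.82),
                         marker_sds = c(indican = 60.13, zonulin = 186.59,
                                        sIgA = 2669.03),
                         seed = 1) {
  if (depth < 100) stop("`depth` must be at least 100")
  if (effect_size < 0) stop("`effect_size` must be >= 0")
  inflamm <- inflamm_taxa %||% catalog$genus[catalog$role == "inflamm"]
  protect <- protect_taxa %||% catalog$genus[catalog$role == "protect"]
  if (length(intersect(inflamm, protect)))
    stop("inflamm and protect taxon sets must be disjoint")
  structure(list(n_controls = n_controls, n_cases = n_cases,
                 base_concentration = base_concentration,
                 effect_size = effect_size, depth = depth,
                 score_link = score_link, catalog = catalog,
                 inflamm_taxa = inflamm, protect_taxa = protect,
                 marker_means = marker_means, marker_sds = marker_sds,
                 seed = as.integer(seed)),
            class = "synth_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# shift `effect` total mass from the protect set to the inflamm set,
# proportionally to baseline weights within each set
shift_mean <- function(mean_vec, effect, inflamm, protect) {
  if (effect == 0) return(mean_vec)
  pmass <- sum(mean_vec[protect])
  if (effect > pmass)
    stop("effect mass ", effect, " exceeds available protective mass ",
         signif(pmass, 4))
  out <- mean_vec
  out[protect] <- out[protect] * (1 - effect / pmass)
  out[inflamm] <- out[inflamm] + effect * mean_vec[inflamm] /
    sum(mean_vec[inflamm])
  out
}

lognormal_pars <- function(m, s) {
  list(meanlog = log(m^2 / sqrt(m^2 + s^2)),
       sdlog = sqrt(log(1 + s^2 / m^2)))
}

#' Generate a synthetic case/control cohort
#'
#' Controls are drawn Dirichlet(concentration x baseline mean) then
#' multinomial at the configured depth; cases use a mean shifted by each
#' case's true effect (mass moved from protective to pro-inflammatory taxa).
#' Ages and genders are assigned to populate every (age bin, gender)
#' stratum; clinical scores follow the configured linear link to the true
#' effect; marker levels are lognormal noise. Same config (incl. seed) gives
#' a byte-identical cohort.
#'
#' @param config a [synth_config()].
#' @param case_meta optional data.frame overriding per-case `effect`,
#'   `gender`, `age_years`, `disease`, `activity`, `localisation` (recycled
#'   columns optional); used by [emulate_ibd_cohort()].
#' @return list with `table` (genus-level counts [taxa_table()] with
#'   lineages), `metadata` (one row per sample), `true_effects` (named by
#'   subject), `config`.
#' @export
generate_cohort <- function(config, case_meta = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cat <- config$catalog
  base_mean <- stats::setNames(cat$weight, cat$genus)
  with_seed(config$seed, {
    nC <- config$n_controls
    nP <- config$n_cases
    ctrl_ids <- sprintf("CTRL%02d", seq_len(nC))
    case_ids <- sprintf("IBD%02d", seq_len(nP))

    # controls: cycle the (age bin x gender) grid so all strata are filled
    bins <- list(c(0.5, 4), c(4, 11), c(11, 18.5))
    grid <- expand.grid(bin = seq_along(bins), gender = c("male", "female"),
                        stringsAsFactors = FALSE)
    gi <- rep_len(seq_len(nrow(grid)), nC)
    ctrl_gender <- grid$gender[gi]
    ctrl_age <- vapply(grid$bin[gi], function(b)
      stats::runif(1, bins[[b]][1], bins[[b]][2]), numeric(1))

    if (is.null(case_meta)) case_meta <- data.frame(row.names = seq_len(nP))
    effects <- if (!is.null(case_meta$effect)) case_meta$effect
      else stats::runif(nP, 0, config$effect_size)
    case_gender <- case_meta$gender %||%
      rep_len(c("male", "female"), nP)
    case_age <- case_meta$age_years %||% stats::runif(nP, 6, 18)
    disease <- case_meta$disease %||%
      rep_len(c("UC", "CD"), nP)
    activity <- case_meta$activity %||% rep("unknown", nP)
    localisation <- case_meta$localisation %||% rep("unknown", nP)

    draw_sample <- function(effect) {
      m <- shift_mean(base_mean, effect, config$inflamm_taxa,
                      config$protect_taxa)
      p <- rdirichlet1(config$base_concentration * m)
      stats::rmultinom(1, size = config$depth, prob = p)[, 1]
    }
    counts <- vapply(c(rep(0, nC), effects), draw_sample,
                     numeric(nrow(cat)))
    dimnames(counts) <- list(cat$genus,
                             paste0(c(ctrl_ids, case_ids), "-S1"))

    score_raw <- config$score_link[1] + config$score_link[2] * effects +
      stats::rnorm(nP, 0, config$score_link[3])
    pucai <- ifelse(disease == "UC", pmin(pmax(score_raw, 0), 85), NA)
    pcdai <- ifelse(disease == "CD", pmin(pmax(score_raw, 0), 100), NA)

    marker <- function(name, n) {
      lp <- lognormal_pars(config$marker_means[[name]],
                           config$marker_sds[[name]])
      stats::rlnorm(n, lp$meanlog, lp$sdlog)
    }
    metadata <- data.frame(
      subject_id = c(ctrl_ids, case_ids),
      sample_id = paste0(c(ctrl_ids, case_ids), "-S1"),
      age_years = c(ctrl_age, case_age),
      gender = c(ctrl_gender, case_gender),
      role = c(rep("control", nC), rep("case", nP)),
      disease = c(rep("none", nC), disease),
      activity = c(rep("unknown", nC), activity),
      localisation = c(rep("unknown", nC), localisation),
      PUCAI = c(rep(NA_real_, nC), pucai),
      PCDAI = c(rep(NA_real_, nC), pcdai),
      indican_mg_L = c(rep(NA_real_, nC), marker("indican", nP)),
      zonulin_ng_mL = c(rep(NA_real_, nC), marker("zonulin", nP)),
      sIgA_ug_mL = c(rep(NA_real_, nC), marker("sIgA", nP)),
      stringsAsFactors = FALSE)

    list(table = taxa_table(counts, lineages = catalog_lineages(cat),
                            value_kind = "counts"),
         metadata = metadata,
         true_effects = stats::setNames(effects, case_ids),
         config = config)
  })
}

# per-class dysbiosis effects for the emulated cohort: calibrated once
# against the mdi pipeline at depth 10000 / concentration 50 so the class
# centres land near 15% / 30% / 45% MDI, then frozen
.emulated_effects <- c(mild = 0.08, moderate = 0.33, high = 0.48)

#' Emulate the reference IBD study cohort
#'
#' A 35-patient paediatric IBD cohort (14 UC scored with PUCAI, 21 CD scored
#' with PCDAI; 18 male / 17 female; 11 active / 24 in remission; disease
#' localisation absence 4, proctitis 3, left colitis 4, extensive colitis 9,
#' ileum/ileocolon 15) plus a 50-control healthy reference pool. Per-case
#' dysbiosis effects are fixed at three levels so that the MDI
#' classification of the cohort lands near an 8 mild / 19 moderate / 8 high
#' split.
#'
#' @param seed integer seed.
#' @return a cohort bundle as from [generate_cohort()].
#' @export
emulate_ibd_cohort <- function(seed = 1) {
  n <- 35
  effect_class <- rep(c("mild", "moderate", "high"), c(8, 19, 8))
  case_meta <- data.frame(
    effect = unname(.emulated_effects[effect_class]),
    # alternating over 35 gives exactly 18 male / 17 female
    gender = rep_len(c("male", "female"), n),
    age_years = seq(6, 18, length.out = n),
    # 7 cycles of (UC, CD, CD, UC, CD) give exactly 14 UC / 21 CD,
    # interleaved so disease is not confounded with the effect level
    disease = rep_len(c("UC", "CD", "CD", "UC", "CD"), n),
    activity = rep("remission", n),
    localisation = rep(c("absence", "proctitis", "left_colitis",
                         "extensive_colitis", "ileo_ileocolon"),
                       c(4, 3, 4, 9, 15)),
    stringsAsFactors = FALSE)
  # exact Table-1 activity margin: 11 active / 24 remission, spread out
  case_meta$activity <- rep("remission", n)
  case_meta$activity[round(seq(1, n, length.out = 11))] <- "active"
  cfg <- synth_config(n_controls = 50, n_cases = n, seed = seed)
  generate_cohort(cfg, case_meta = case_meta)
}
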