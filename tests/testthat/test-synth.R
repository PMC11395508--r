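test_that("cohort generation is a deterministic function of the config", {
  b1 <- generate_cohort(synth_config(n_controls = 6, n_cases = 6,
                                     depth = 2000, seed = 42))
  b2 <- generate_cohort(synth_config(n_controls = 6, n_cases = 6,
                                     depth = 2000, seed = 42))
  expect_identical(b1$table$values, b2$table$values)
  expect_identical(b1$metadata, b2$metadata)
  expect_identical(b1$true_effects, b2$true_effects)
  b3 <- generate_cohort(synth_config(n_controls = 6, n_cases = 6,
                                     depth = 2000, seed = 43))
  expect_false(identical(b1$table$values, b3$table$values))
})

test_that("generated tables are valid count tables at the configured depth", {
  b <- generate_cohort(synth_config(n_controls = 4, n_cases = 4,
                                    depth = 500, seed = 3))
  expect_s3_class(b$table, "taxa_table")
  expect_true(all(colSums(b$table$values) == 500))
  expect_equal(n_samples(b$table), 8)
  expect_false(is.null(b$table$lineages))
  # lineages collapse cleanly at every index level
  for (lv in c("phylum", "family", "genus"))
    expect_gt(n_taxa(collapse_to_level(b$table, lv)), 1)
})

test_that("a zero effect size produces exchangeable cases and controls", {
  b <- generate_cohort(synth_config(n_controls = 100, n_cases = 100,
                                    effect_size = 0, depth = 5000, seed = 11))
  rel <- to_relative_abundance(b$table)$values
  ctrl <- rel[, b$metadata$sample_id[b$metadata$role == "control"]]
  case <- rel[, b$metadata$sample_id[b$metadata$role == "case"]]
  for (tx in c("Faecalibacterium", "Bacteroides", "Escherichia")) {
    diff <- mean(case[tx, ]) - mean(ctrl[tx, ])
    se <- sqrt(stats::var(case[tx, ]) / 100 + stats::var(ctrl[tx, ]) / 100)
    # Monte-Carlo bound: a genuine shift registers at z > 10 here
    expect_lt(abs(diff), 4 * se)
  }
  expect_true(all(b$true_effects == 0))
})

test_that("the dysbiosis shift moves mass in the documented direction", {
  cfg <- synth_config(n_controls = 2, n_cases = 40, effect_size = 0,
                      seed = 13)
  b <- generate_cohort(cfg, case_meta = data.frame(effect = rep(0.4, 40)))
  rel <- to_relative_abundance(b$table)$values
  case <- rel[, b$metadata$sample_id[b$metadata$role == "case"]]
  catalog <- default_taxon_catalog()
  base <- stats::setNames(catalog$weight, catalog$genus)
  expect_lt(mean(case["Faecalibacterium", ]), base[["Faecalibacterium"]])
  expect_gt(mean(case["Escherichia", ]), base[["Escherichia"]] + 0.2)
  # effect mass beyond the protective pool is an error
  expect_error(
    generate_cohort(cfg, case_meta = data.frame(effect = rep(0.9, 40))),
    "exceeds available protective mass")
})

test_that("clinical scores track the injected effect", {
  b <- generate_cohort(synth_config(n_controls = 5, n_cases = 60,
                                    effect_size = 0.4, depth = 1000,
                                    score_link = c(5, 100, 2), seed = 17))
  md <- b$metadata[b$metadata$role == "case", ]
  score <- ifelse(is.na(md$PUCAI), md$PCDAI, md$PUCAI)
  f <- linear_fit(b$true_effects[md$subject_id], score)
  expect_gt(f$slope, 0)
  expect_lt(f$p, 0.01)
  expect_true(all(score >= 0))
  # the instrument matches the disease
  expect_true(all(is.na(md$PUCAI[md$disease == "CD"])))
  expect_true(all(is.na(md$PCDAI[md$disease == "UC"])))
})

test_that("the emulated IBD cohort reproduces the reference margins", {
  b <- emulate_ibd_cohort(seed = 4)
  md <- b$metadata
  case <- md[md$role == "case", ]
  expect_equal(nrow(case), 35)
  expect_equal(sum(md$role == "control"), 50)
  expect_equal(as.vector(table(case$disease)[c("UC", "CD")]), c(14L, 21L))
  expect_equal(as.vector(table(case$gender)[c("male", "female")]), c(18L, 17L))
  expect_equal(sum(case$activity == "active"), 11)
  expect_equal(as.vector(table(case$localisation)[
    c("absence", "proctitis", "left_colitis", "extensive_colitis",
      "ileo_ileocolon")]), c(4L, 3L, 4L, 9L, 15L))
  b2 <- emulate_ibd_cohort(seed = 4)
  expect_identical(b$table$values, b2$table$values)
  expect_identical(b$metadata, b2$metadata)
})

test_that("taxa-MDI correlations are calibrated under the null", {
  # pooled over 5 independent null cohorts: 40 taxa x 5 = 200 tests
  tot <- 0; flagged <- 0
  for (s in 1:5) {
    b <- generate_cohort(synth_config(n_controls = 50, n_cases = 50,
                                      effect_size = 0, seed = 100 + s))
    v <- cohort_mdi(b)
    names(v) <- b$metadata$sample_id[match(names(v),
                                           b$metadata$subject_id)]
    rel <- to_relative_abundance(collapse_to_level(b$table, "genus"))
    rec <- suppressWarnings(correlate_with_mdi(rel, v))
    tot <- tot + nrow(rec)
    flagged <- flagged + sum(rec$p_value < 0.05)
  }
  expect_gte(tot, 195)
  expect_lt(abs(flagged / tot - 0.05), 0.03 + 1e-9)
})
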