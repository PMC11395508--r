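test_that("rank collapse sums within groups, pools unclassified, conserves totals", {
  lin <- c(a = "k__Bacteria; p__Firmicutes; f__Lachnospiraceae; g__Roseburia",
           b = "k__Bacteria; p__Firmicutes; f__Lachnospiraceae; g__Blautia",
           c = "k__Bacteria; p__Firmicutes; f__Ruminococcaceae")
  v <- matrix(c(10, 30, 5, 1, 2, 3), nrow = 3,
              dimnames = list(names(lin), c("s1", "s2")))
  tt <- taxa_table(v, lineages = lin, value_kind = "counts")

  fam <- collapse_to_level(tt, "family")
  expect_equal(fam$values["Lachnospiraceae", ], c(s1 = 40, s2 = 3))
  expect_equal(colSums(fam$values), colSums(v))

  gen <- collapse_to_level(tt, "genus")
  expect_true("unclassified_genus" %in% taxon_ids(gen))
  expect_equal(gen$values["unclassified_genus", ], c(s1 = 5, s2 = 3))
  expect_equal(colSums(gen$values), colSums(v))

  expect_error(collapse_to_level(taxa_table(v, value_kind = "counts"), "genus"),
               "no lineages")
})

test_that("relative-abundance conversion normalises columns and flags zeros", {
  v <- matrix(c(10, 30, 60, 0, 0, 0), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  tt <- taxa_table(v, value_kind = "counts")
  expect_warning(rel <- to_relative_abundance(tt), "all-zero")
  expect_equal(rel$values[, "s1"], c(a = 0.1, b = 0.3, c = 0.6))
  expect_equal(sum(rel$values[, "s1"]), 1, tolerance = 1e-9)
  expect_equal(unname(rel$values[, "s2"]), c(0, 0, 0))
  expect_equal(attr(rel, "zero_samples"), "s2")
})

test_that("prevalence/abundance filter applies the boundary-inclusive rule", {
  # 8 samples; row1 at RA >= 0.01 in exactly 2 (2/8 = 25%): retained
  # row2 at RA >= 0.01 in 1 sample: removed
  # row3 at RA 0.005 everywhere ("absent" at the 1% level): removed
  # row4 abundant everywhere: retained and absorbs the remaining mass
  n <- 8
  ra <- rbind(
    r1 = c(0.02, 0.02, rep(0.001, 6)),
    r2 = c(0.05, rep(0.002, 7)),
    r3 = rep(0.005, 8))
  ra <- rbind(ra, r4 = 1 - colSums(ra))
  colnames(ra) <- paste0("s", 1:n)
  tt <- taxa_table(ra, value_kind = "relative")
  out <- prevalence_abundance_filter(tt, min_prevalence = 0.25, min_ra = 0.01)
  expect_setequal(taxon_ids(out), c("r1", "r4"))
  expect_setequal(attr(out, "removed"), c("r2", "r3"))

  # idempotence on a counts table (thresholds re-derived from the survivors)
  ct <- make_counts_table(matrix(c(100, 1, 899, 120, 2, 878), nrow = 3))
  once <- prevalence_abundance_filter(ct)
  twice <- prevalence_abundance_filter(once)
  expect_equal(twice$values, once$values)

  expect_error(prevalence_abundance_filter(tt, min_prevalence = 1.2), "0, 1")
})

test_that("CSS normalisation matches the hand-computed scaling factor", {
  v <- matrix(c(10, 10, 80, 10, 10, 80), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  tt <- taxa_table(v, value_kind = "counts")
  out <- css_normalize(tt, percentile = 0.5, scale = 1000)
  # nonzero median = 10, s = 10 + 10 = 20 -> (500, 500, 4000)
  expect_equal(out$values[, "s1"], c(a = 500, b = 500, c = 4000))
  expect_equal(out$values[, "s1"], out$values[, "s2"])  # identical columns
  expect_equal(out$value_kind, "normalized")

  v0 <- v; v0[, 2] <- 0
  expect_error(css_normalize(taxa_table(v0, value_kind = "counts")), "s2")
})

test_that("rarefaction is deterministic, depth-exact, and drops shallow samples", {
  v <- matrix(c(500, 300, 200, 40, 30, 30), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("deep", "shallow")))
  tt <- taxa_table(v, value_kind = "counts")
  expect_warning(r1 <- rarefy_table(tt, depth = 200, seed = 7), "shallow")
  expect_equal(sample_ids(r1), "deep")
  expect_true(all(colSums(r1$values) == 200))
  expect_warning(r2 <- rarefy_table(tt, depth = 200, seed = 7), "shallow")
  expect_identical(r1$values, r2$values)
  expect_error(rarefy_table(tt, depth = 200, seed = 7, shallow = "error"),
               "shallow")
  # depth equal to the total leaves the column unchanged
  full <- suppressWarnings(rarefy_table(tt, depth = 1000, seed = 1))
  expect_equal(full$values[, "deep"], v[, "deep"])
  expect_error(rarefy_table(tt, depth = 0, seed = 1), "positive")
})

test_that("rarefied counts follow the hypergeometric expectation", {
  v <- matrix(c(5000, 5000), nrow = 2,
              dimnames = list(c("a", "b"), "s1"))
  tt <- taxa_table(v, value_kind = "counts")
  draws <- vapply(seq_len(2000), function(s)
    rarefy_table(tt, depth = 1000, seed = s)$values["a", 1], numeric(1))
  se <- sqrt(1000 * 0.5 * 0.5 * (10000 - 1000) / (10000 - 1)) / sqrt(2000)
  expect_lt(abs(mean(draws) - 500), 3 * se)
})

test_that("per-subject profiles take medians and renormalise", {
  tt <- make_counts_table(matrix(c(20, 80, 0, 40, 60, 0), nrow = 3))
  md <- data.frame(subject_id = c("P1", "P1"), sample_id = c("s1", "s2"),
                   stringsAsFactors = FALSE)
  prof <- build_profiles(tt, md)[["P1"]]
  # medians of (0.2, 0.8) and (0.4, 0.6) are (0.3, 0.7), already on the simplex
  expect_equal(prof$levels$genus[c("Faecalibacterium", "Roseburia")],
               c(Faecalibacterium = 0.3, Roseburia = 0.7))
  expect_equal(sum(prof$levels$phylum), 1, tolerance = 1e-9)

  # a single-sample subject gets exactly that sample's relative abundances
  md1 <- data.frame(subject_id = "P2", sample_id = "s1",
                    stringsAsFactors = FALSE)
  p2 <- build_profiles(tt, md1)[["P2"]]
  expect_equal(p2$levels$genus[["Faecalibacterium"]], 0.2)

  # renormalisation: coordinate-wise medians (0.5, 0.5, 0.5) -> equal thirds
  expect_equal(mdikit:::renormalize_simplex(c(0.5, 0.5, 0.5)), rep(1 / 3, 3))
})
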