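test_that("correlation wrapper recovers exact relations and flags constants", {
  x <- 1:10
  expect_equal(cor_assoc(x, 2 * x + 1)$rho, 1, tolerance = 1e-12)
  expect_equal(cor_assoc(x, -x)$rho, -1, tolerance = 1e-12)
  # orthogonalised residuals are exactly uncorrelated with x
  set.seed(2)
  y0 <- stats::rnorm(10)
  y <- stats::resid(stats::lm(y0 ~ x))
  expect_lt(abs(cor_assoc(x, y)$rho), 1e-12)
  expect_warning(r <- cor_assoc(x, rep(3, 10)), "constant")
  expect_true(r$undefined)
  expect_true(is.na(r$rho))
  expect_error(cor_assoc(1:2, 1:2), "at least 3")
})

test_that("Spearman uses mid-ranks and honours monotone transforms", {
  x <- c(1, 3, 2, 8, 5)
  expect_equal(cor_assoc(x, exp(x), "spearman")$rho, 1, tolerance = 1e-12)
  expect_equal(cor_assoc(x, -x^3, "spearman")$rho, -1, tolerance = 1e-12)
  expect_equal(cor_assoc(c(1, 2, 2, 3), c(1, 2, 2, 3), "spearman")$rho, 1,
               tolerance = 1e-12)
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.037), 0.037)
  q <- bh_fdr(c(0.5, 0.001, 0.04))
  expect_true(all(q >= c(0.5, 0.001, 0.04)))  # q >= p elementwise
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.1)), "\\(0, 1\\]")
})

test_that("strength bands are right-closed on |rho| and monotone", {
  expect_equal(as.character(band_strength(c(0.634, -0.537, 0.71))),
               c("moderate", "moderate", "strong"))
  expect_equal(as.character(band_strength(c(0.3, -0.3, 0.7, -0.7))),
               rep(c("weak", "moderate"), each = 2))
  rho <- seq(0, 1, by = 0.01)
  expect_true(!is.unsorted(as.integer(band_strength(rho))))
  expect_error(band_strength(1.2), "exceed 1")
})

test_that("the taxa-MDI battery ranks, corrects, and excludes properly", {
  set.seed(9)
  n <- 20
  mdi <- stats::setNames(stats::runif(n, 5, 45), paste0("s", 1:n))
  v <- rbind(linear = 0.002 * mdi + 0.01,
             noise1 = stats::runif(n), noise2 = stats::runif(n),
             noise3 = stats::runif(n), noise4 = stats::runif(n),
             flat = rep(0.5, n))
  colnames(v) <- names(mdi)
  tt <- taxa_table(v, value_kind = "normalized")
  expect_warning(rec <- correlate_with_mdi(tt, mdi), "constant")
  expect_false("flat" %in% rec$feature_id)
  expect_equal(rec$feature_id[1], "linear")   # sorted by rho, exact linear
  expect_equal(rec$rho[1], 1, tolerance = 1e-12)
  expect_equal(rec$band[1], "strong")
  expect_equal(which.max(abs(rec$rho)), 1L)
  expect_equal(rec$q_value, bh_fdr(rec$p_value))
  expect_true(all(rec$q_value >= rec$p_value))
})

test_that("linear fit matches OLS identities", {
  x <- 1:12
  f <- suppressWarnings(linear_fit(x, 3 * x - 2))  # "perfect fit" caution
  expect_equal(f$slope, 3, tolerance = 1e-12)
  expect_equal(f$intercept, -2, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  set.seed(12)
  y <- stats::rnorm(1000)
  xr <- stats::rnorm(1000)
  f2 <- linear_fit(xr, y)
  expect_lt(f2$r_squared, 0.02)
  expect_equal(f2$r_squared, cor_assoc(xr, y)$rho^2, tolerance = 1e-12)
  expect_error(linear_fit(rep(1, 5), 1:5), "constant")
})

test_that("group comparison picks the right rank test and is symmetric", {
  same <- c(1, 2, 3, 1, 2, 3)
  g2 <- rep(c("a", "b"), each = 3)
  expect_gt(group_compare(same, g2)$p, 0.9)

  r <- group_compare(c(1, 2, 3, 101, 102, 103), g2)
  expect_equal(r$test, "mann-whitney")
  expect_equal(r$statistic, 0)      # complete separation -> U = 0
  expect_equal(r$p, 0.1)            # minimal two-sided exact p at n = 3, 3

  # swapping the group labels reflects U to n1*n2 - U
  r2 <- group_compare(c(1, 2, 3, 101, 102, 103), rev(g2))
  expect_equal(r2$statistic, 9)
  expect_equal(r2$p, r$p)

  # p invariant under a common strictly monotone transform (exact case)
  vals <- c(3, 9, 27, 2, 8, 1)
  expect_equal(group_compare(vals, g2)$p, group_compare(log(vals), g2)$p)

  k <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(k$test, "kruskal-wallis")
  expect_error(group_compare(1:3, rep("a", 3)), "two non-empty")
})

test_that("niche networks keep only significant cross-niche edges", {
  set.seed(14)
  n <- 30
  subj <- paste0("P", 1:n)
  driver <- stats::runif(n)
  fv <- rbind(linked_f = driver + stats::rnorm(n, 0, 0.01),
              f2 = stats::runif(n), f3 = stats::runif(n))
  iv <- rbind(linked_i = 2 * driver^2 + stats::rnorm(n, 0, 0.01),
              i2 = stats::runif(n), i3 = stats::runif(n))
  colnames(fv) <- colnames(iv) <- subj
  faecal <- taxa_table(fv, value_kind = "normalized")
  ileal <- taxa_table(iv, value_kind = "normalized")

  net <- build_niche_network(faecal, ileal, p_threshold = 0.05)
  expect_true(any(net$edges$faecal == "linked_f" &
                  net$edges$ileal == "linked_i"))
  expect_true(all(net$edges$p < 0.05))
  expect_lte(nrow(net$nodes), nrow(fv) + nrow(iv))

  # swapping niches transposes the edge list
  net_t <- build_niche_network(ileal, faecal, p_threshold = 0.05)
  a <- paste(net$edges$faecal, net$edges$ileal)
  b <- paste(net_t$edges$ileal, net_t$edges$faecal)
  expect_setequal(a, b)

  empty <- build_niche_network(faecal, ileal, p_threshold = 0)
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(nrow(empty$nodes), 0L)

  expect_error(build_niche_network(
    taxa_table(fv[, 1:2], value_kind = "normalized"), ileal), "3 shared")
})
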