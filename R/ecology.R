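#' Shannon diversity index
#'
#' Entropy of the normalised abundance vector, `H = -sum p_i log(p_i)` over
#' nonzero entries. Natural log by default; pass `base = 2` for the QIIME
#' convention. Invariant to rescaling of the input.
#'
#' @param abundances non-negative vector, not all zero.
#' @param base logarithm base.
#' @return a non-negative number.
#' @export
shannon <- function(abundances, base = exp(1)) {
  if (any(abundances < 0)) stop("abundances must be non-negative")
  if (sum(abundances) == 0) stop("all-zero abundance vector")
  as.numeric(vegan::diversity(abundances, index = "shannon", base = base))
}

#' Chao1 richness estimator
#'
#' With `S` observed taxa, `F1` singletons and `F2` doubletons:
#' `S + F1^2 / (2 F2)` when doubletons exist, otherwise the bias-corrected
#' `S + F1 (F1 - 1) / 2`.
#'
#' @param counts non-negative integer vector, not all zero.
#' @return estimated richness (>= observed richness).
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("Chao1 requires integer counts")
  counts <- round(counts)
  if (sum(counts) == 0) stop("all-zero count vector")
  s <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / 2
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 sum(min(a, b)) / (sum(a) + sum(b))`; 0 for identical vectors, 1 for
#' disjoint supports. Bounded in [0, 1] but not a metric (no triangle
#' inequality).
#'
#' @param a,b equal-length non-negative vectors, not both all-zero.
#' @return a number in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("abundances must be non-negative")
  if (sum(a) + sum(b) == 0) stop("both vectors are all-zero")
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' Bray-Curtis distance matrix across the samples of a taxa table
#'
#' @param table a [taxa_table()].
#' @return a `dist` object labelled with the sample ids (symmetric, zero
#'   diagonal).
#' @export
beta_diversity <- function(table) {
  stopifnot(inherits(table, "taxa_table"))
  vegan::vegdist(t(table$values), method = "bray")
}

#' Alpha diversity table
#'
#' Shannon and Chao1 per sample. Chao1 is only meaningful on raw counts and
#' is reported as `NA` for non-count tables.
#'
#' @param table a `taxa_table`.
#' @param base Shannon log base.
#' @return data.frame with `sample_id`, `shannon`, `chao1`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "taxa_table"))
  v <- table$values
  data.frame(
    sample_id = colnames(v),
    shannon = apply(v, 2, shannon, base = base),
    chao1 = if (table$value_kind == "counts")
      apply(v, 2, chao1) else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (Anderson's pseudo-F on
#' among/within sums of squared distances), via [vegan::adonis2()]. The
#' p-value uses the +1 permutation correction,
#' `p = (1 + #permuted F >= observed F) / (1 + n_perm)`, so the smallest
#' attainable p is `1 / (n_perm + 1)`.
#'
#' @param dm a `dist` or symmetric matrix of dissimilarities.
#' @param groups group labels, one per sample; every group needs >= 2
#'   members and >= 2 groups are required.
#' @param n_perm number of permutations.
#' @param seed integer seed; same seed gives the same p.
#' @return list with `pseudo_F`, `p`, `df`, `n_perm`.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = NULL) {
  if (!inherits(dm, "dist")) dm <- stats::as.dist(dm)
  groups <- as.factor(as.character(groups))
  if (length(groups) != attr(dm, "Size"))
    stop("one group label per sample is required")
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two members")
  if (n_perm < 1) stop("`n_perm` must be positive")
  fit <- with_seed(seed,
    vegan::adonis2(dm ~ groups, permutations = n_perm))
  list(pseudo_F = fit$F[1], p = fit$`Pr(>F)`[1], df = fit$Df[1],
       n_perm = n_perm)
}
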