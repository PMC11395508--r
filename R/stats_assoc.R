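#' Pearson or Spearman correlation with p-value
#'
#' Wraps [stats::cor.test()]. Spearman uses mid-ranks for ties (p from the
#' t approximation when ties are present). A constant input does not yield a
#' silent `rho = 0`: the result is flagged `undefined = TRUE` with `NA`
#' estimates, and callers exclude such features.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `rho`, `p`, `n`, `undefined`.
#' @export
cor_assoc <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("vectors must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                undefined = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = NULL))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       undefined = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_i = min_{j >= rank(i)} m p_(j) / j`, capped at
#' 1 and returned in input order.
#'
#' @param p_values vector of p-values in `(0, 1]`.
#' @return vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Correlation strength band
#'
#' Bands on the absolute coefficient, right-closed: weak `|rho| <= 0.3`,
#' moderate `0.3 < |rho| <= 0.7`, strong `|rho| > 0.7`.
#'
#' @param rho coefficient(s) with `|rho| <= 1`.
#' @return factor with levels `weak`, `moderate`, `strong`.
#' @export
band_strength <- function(rho) {
  if (any(abs(rho) > 1, na.rm = TRUE)) stop("|rho| cannot exceed 1")
  a <- abs(rho)
  factor(ifelse(a <= 0.3, "weak", ifelse(a <= 0.7, "moderate", "strong")),
         levels = c("weak", "moderate", "strong"))
}

#' Correlate every taxon with the dysbiosis index
#'
#' One test per taxon row of `table` against the per-sample index values,
#' BH-FDR across all taxa tested in the call (one correction family per
#' run, e.g. one per niche). Constant taxa are excluded with a warning.
#' Records are sorted by `rho` descending.
#'
#' @param table a [taxa_table()] (relative or CSS-normalised values).
#' @param mdi named numeric vector of index values; names are sample ids (or
#'   subject ids equal to the table's sample ids).
#' @param method correlation type, default Pearson.
#' @return data.frame: `feature_id`, `rho`, `p_value`, `q_value`, `band`,
#'   `n`; excluded constant features in attribute `excluded`.
#' @export
correlate_with_mdi <- function(table, mdi, method = "pearson") {
  stopifnot(inherits(table, "taxa_table"))
  shared <- intersect(sample_ids(table), names(mdi))
  if (length(shared) < 3)
    stop("need at least 3 samples with both abundances and index values")
  v <- table$values[, shared, drop = FALSE]
  y <- mdi[shared]
  res <- lapply(rownames(v), function(tx) {
    r <- withCallingHandlers(
      cor_assoc(v[tx, ], y, method = method),
      warning = function(w) invokeRestart("muffleWarning"))
    c(list(feature_id = tx), r)
  })
  undef <- vapply(res, function(r) isTRUE(r$undefined), logical(1))
  excluded <- vapply(res[undef], `[[`, character(1), "feature_id")
  if (any(undef))
    warning("excluding constant feature(s): ",
            paste(excluded, collapse = ", "))
  res <- res[!undef]
  if (!length(res)) stop("no testable (non-constant) features")
  out <- data.frame(
    feature_id = vapply(res, `[[`, character(1), "feature_id"),
    rho = vapply(res, `[[`, numeric(1), "rho"),
    p_value = vapply(res, `[[`, numeric(1), "p"),
    n = vapply(res, `[[`, numeric(1), "n"),
    stringsAsFactors = FALSE)
  out$p_value <- pmax(out$p_value, .Machine$double.xmin)  # keep p in (0,1]
  out$q_value <- bh_fdr(out$p_value)
  out$band <- as.character(band_strength(out$rho))
  out <- out[order(-out$rho), c("feature_id", "rho", "p_value", "q_value",
                                "band", "n")]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Ordinary least-squares fit of y on x
#'
#' @param x,y numeric vectors, `n >= 3`, `x` non-constant.
#' @return list with `slope`, `intercept`, `r_squared` (the squared Pearson
#'   coefficient), and the two-sided `p` of the slope test.
#' @export
linear_fit <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("`x` is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p = unname(s$coefficients[2, 4]))
}

#' Rank-based group comparison
#'
#' Two groups: two-sided Mann-Whitney U (exact for small untied samples,
#' normal approximation with tie correction otherwise, as in
#' [stats::wilcox.test()]). More than two groups: Kruskal-Wallis.
#'
#' @param values numeric vector.
#' @param labels group labels, one per value.
#' @return list with `statistic`, `p`, `test` (`"mann-whitney"` or
#'   `"kruskal-wallis"`).
#' @export
group_compare <- function(values, labels) {
  labels <- as.factor(as.character(labels))
  if (length(values) != length(labels)) stop("one label per value required")
  if (any(table(labels) == 0) || nlevels(labels) < 2)
    stop("need at least two non-empty groups")
  if (nlevels(labels) == 2) {
    g <- split(values, labels)
    ht <- suppressWarnings(stats::wilcox.test(g[[1]], g[[2]],
                                              alternative = "two.sided"))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         test = "mann-whitney")
  } else {
    ht <- stats::kruskal.test(values, labels)
    list(statistic = unname(ht$statistic), p = ht$p.value,
         test = "kruskal-wallis")
  }
}

#' Faecal-ileal correlation network
#'
#' Spearman correlation for every (faecal taxon, ileal taxon) pair across the
#' subjects shared by the two tables; edges kept when `p < p_threshold`.
#' Nodes are the taxa incident to at least one kept edge; within-niche edges
#' are never formed.
#'
#' @param faecal,ileal [taxa_table()]s whose sample (column) ids identify the
#'   same subjects.
#' @param p_threshold edge inclusion threshold on the p-value.
#' @param method correlation type, default Spearman.
#' @return a `niche_network`: list with `edges` (data.frame `faecal`,
#'   `ileal`, `rho`, `p`), `nodes` (data.frame `taxon`, `niche`, `degree`),
#'   `n_subjects`.
#' @export
build_niche_network <- function(faecal, ileal, p_threshold = 0.05,
                                method = "spearman") {
  stopifnot(inherits(faecal, "taxa_table"), inherits(ileal, "taxa_table"))
  shared <- intersect(sample_ids(faecal), sample_ids(ileal))
  if (length(shared) < 3) stop("need at least 3 shared subjects")
  fv <- faecal$values[, shared, drop = FALSE]
  iv <- ileal$values[, shared, drop = FALSE]
  pairs <- expand.grid(faecal = rownames(fv), ileal = rownames(iv),
                       stringsAsFactors = FALSE)
  stats_list <- Map(function(ft, it) {
    r <- withCallingHandlers(cor_assoc(fv[ft, ], iv[it, ], method = method),
                             warning = function(w)
                               invokeRestart("muffleWarning"))
    c(r$rho, r$p)
  }, pairs$faecal, pairs$ileal)
  m <- do.call(rbind, stats_list)
  pairs$rho <- m[, 1]
  pairs$p <- m[, 2]
  edges <- pairs[!is.na(pairs$p) & pairs$p < p_threshold, , drop = FALSE]
  rownames(edges) <- NULL
  f_nodes <- unique(edges$faecal)
  i_nodes <- unique(edges$ileal)
  nodes <- data.frame(taxon = c(f_nodes, i_nodes),
                      niche = rep(c("faecal", "ileal"),
                                  c(length(f_nodes), length(i_nodes))),
                      stringsAsFactors = FALSE)
  nodes$degree <- if (nrow(nodes)) mapply(function(tx, niche)
    sum(edges[[niche]] == tx), nodes$taxon, nodes$niche) else integer()
  structure(list(edges = edges, nodes = nodes,
                 n_subjects = length(shared),
                 p_threshold = p_threshold),
            class = "niche_network")
}

#' @export
print.niche_network <- function(x, ...) {
  cat(sprintf("<niche_network> %d nodes, %d edges (p < %g, n = %d subjects)\n",
              nrow(x$nodes), nrow(x$edges), x$p_threshold, x$n_subjects))
  invisible(x)
}

#' Export a niche network
#'
#' Edge list as TSV, and optionally GraphML via igraph.
#'
#' @param network a `niche_network`.
#' @param path output path (`.tsv` edge list or `.graphml`).
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    e <- network$edges
    g <- igraph::graph_from_data_frame(
      data.frame(from = paste0("faecal:", e$faecal),
                 to = paste0("ileal:", e$ileal),
                 rho = e$rho, p = e$p),
      directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
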