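#' Taxa abundance table
#'
#' The exchange object of the package: a taxa-by-samples numeric matrix with
#' optional rank-prefixed lineage strings (Greengenes style,
#' `k__...; p__...; c__...; o__...; f__...; g__...`) attached to each taxon.
#' Values are either raw sequence counts (`value_kind = "counts"`), relative
#' abundances summing to 1 per sample (`"relative"`), or scale-normalised
#' continuous values such as CSS output (`"normalized"`).
#'
#' @param values numeric matrix, taxa in rows, samples in columns; both
#'   dimensions must be named with unique identifiers.
#' @param lineages optional character vector of semicolon-delimited lineage
#'   strings, one per taxon (recycled names from `values` rownames if unnamed).
#' @param value_kind one of `"counts"`, `"relative"`, `"normalized"`.
#'
#' @return an object of class `taxa_table` with fields `values`, `lineages`,
#'   `value_kind`.
#' @export
#' @examples
#' m <- matrix(c(10, 0, 90, 20, 5, 75), nrow = 3,
#'             dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
#' tt <- taxa_table(m, value_kind = "counts")
#' n_taxa(tt)
taxa_table <- function(values, lineages = NULL,
                       value_kind = c("counts", "relative", "normalized")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have taxon rownames and sample colnames")
  if (!is.null(lineages)) {
    if (length(lineages) != nrow(values))
      stop("`lineages` must have one entry per taxon")
    lineages <- as.character(lineages)
    names(lineages) <- rownames(values)
  }
  out <- structure(
    list(values = values, lineages = lineages, value_kind = value_kind),
    class = "taxa_table"
  )
  validate_taxa_table(out)
  out
}

#' @rdname taxa_table
#' @param x a `taxa_table`.
#' @export
n_taxa <- function(x) nrow(x$values)

#' @rdname taxa_table
#' @export
n_samples <- function(x) ncol(x$values)

#' @rdname taxa_table
#' @export
taxon_ids <- function(x) rownames(x$values)

#' @rdname taxa_table
#' @export
sample_ids <- function(x) colnames(x$values)

validate_taxa_table <- function(x, tol = 1e-9) {
  v <- x$values
  if (anyNA(v)) stop("taxa table contains missing values")
  if (any(v < 0)) stop("taxa table contains negative values")
  if (anyDuplicated(rownames(v)))
    stop("duplicate taxon id: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stop("duplicate sample id: ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  if (x$value_kind == "relative") {
    cs <- colSums(v)
    bad <- abs(cs - 1) > tol & cs > 0
    if (any(bad))
      stop("column not normalized: ",
           paste(colnames(v)[bad], collapse = ", "),
           " (relative-abundance columns must sum to 1 or be all zero)")
  }
  invisible(x)
}

#' @export
print.taxa_table <- function(x, ...) {
  cat(sprintf("<taxa_table> %d taxa x %d samples (%s%s)\n",
              n_taxa(x), n_samples(x), x$value_kind,
              if (is.null(x$lineages)) "" else ", with lineages"))
  invisible(x)
}

# column names that are treated as the lineage column on read (case-insensitive)
.lineage_col_names <- c("lineage", "taxonomy", "taxon_lineage")

#' Read a taxa abundance table from TSV
#'
#' Expects a UTF-8 tab-delimited file: header row of sample identifiers, first
#' column taxon identifiers, optional second column of lineage strings (header
#' `lineage` or `taxonomy`). Decimal separator is always the point, regardless
#' of locale.
#'
#' @param path file path.
#' @param value_kind `"counts"` or `"relative"`; relative columns are checked
#'   to sum to 1 (all-zero columns allowed).
#' @param transpose set `TRUE` if the file is samples-by-taxa.
#' @return a [taxa_table()].
#' @export
read_taxa_table <- function(path, value_kind = c("counts", "relative"),
                            transpose = FALSE) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("taxa table needs at least one sample column")
  ids <- df[[1]]
  df <- df[, -1, drop = FALSE]
  lineages <- NULL
  if (tolower(names(df)[1]) %in% .lineage_col_names) {
    lineages <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  num <- suppressWarnings(
    vapply(df, function(col) as.numeric(col), numeric(nrow(df)))
  )
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(df)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at taxon '%s', sample '%s'",
                 ids[bad[1]], colnames(num)[bad[2]]))
  }
  rownames(num) <- ids
  if (transpose) {
    num <- t(num)
    lineages <- NULL
  }
  taxa_table(num, lineages = lineages, value_kind = value_kind)
}

#' Write a taxa table to TSV
#'
#' Inverse of [read_taxa_table()]: values survive a round trip to at least
#' 1e-9 relative accuracy (15 significant digits are written).
#'
#' @param x a `taxa_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_taxa_table <- function(x, path) {
  stopifnot(inherits(x, "taxa_table"))
  df <- data.frame(taxon_id = taxon_ids(x), stringsAsFactors = FALSE)
  if (!is.null(x$lineages)) df$lineage <- unname(x$lineages)
  vals <- as.data.frame(x$values, check.names = FALSE)
  vals[] <- lapply(vals, function(col) format(col, digits = 15, trim = TRUE,
                                              scientific = FALSE))
  df <- cbind(df, vals)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
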