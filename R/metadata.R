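#' Read subject/sample metadata from TSV
#'
#' One row per sample. Recognised columns (case-insensitive): `subject_id`,
#' `sample_id`, `age_years`, `gender` (male/female, aliases m/f), `role`
#' (case/control, aliases patient/ctrl/healthy), `disease` (UC/CD/none),
#' `activity` (active/remission/unknown), `localisation` (absence, proctitis,
#' left_colitis, extensive_colitis, ileo_ileocolon, unknown), the clinical
#' scores `PUCAI`, `PCDAI`, `Matts`, `SES_CD`, and the microbiota-associated
#' markers `indican_mg_L`, `zonulin_ng_mL`, `sIgA_ug_mL`. Unknown columns are
#' preserved untouched. Empty cells and "NA" become missing values — never 0.
#'
#' @param path TSV file path.
#' @return a `data.frame` with one row per sample, standardized column names
#'   and parsed enum/numeric columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("", "NA"),
                          fileEncoding = "UTF-8")
  names(df) <- standardize_metadata_names(names(df))
  for (col in c("subject_id", "sample_id"))
    if (!col %in% names(df)) stop("metadata is missing required column: ", col)

  if ("age_years" %in% names(df)) {
    df$age_years <- as.numeric(df$age_years)
    if (any(df$age_years < 0, na.rm = TRUE)) stop("negative age in metadata")
  }
  if ("gender" %in% names(df))
    df$gender <- parse_enum(df$gender, "gender",
                            c(male = "male", m = "male",
                              female = "female", f = "female"))
  if ("role" %in% names(df))
    df$role <- parse_enum(df$role, "role",
                          c(case = "case", patient = "case",
                            control = "control", ctrl = "control",
                            healthy = "control"))
  if ("disease" %in% names(df))
    df$disease <- parse_enum(df$disease, "disease",
                             c(uc = "UC", cd = "CD", none = "none"),
                             default = "none")
  if ("activity" %in% names(df))
    df$activity <- parse_enum(df$activity, "activity",
                              c(active = "active", remission = "remission",
                                unknown = "unknown"), default = "unknown")
  if ("localisation" %in% names(df))
    df$localisation <- parse_enum(
      df$localisation, "localisation",
      c(absence = "absence", proctitis = "proctitis",
        left_colitis = "left_colitis", extensive_colitis = "extensive_colitis",
        ileo_ileocolon = "ileo_ileocolon", unknown = "unknown"),
      default = "unknown")
  for (col in intersect(c("PUCAI", "PCDAI", "Matts", "SES_CD", "indican_mg_L",
                          "zonulin_ng_mL", "sIgA_ug_mL"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  check_score_disease(df)
  df
}

standardize_metadata_names <- function(nms) {
  canon <- c(subject_id = "subject_id", subject = "subject_id",
             sample_id = "sample_id", sample = "sample_id",
             age_years = "age_years", age = "age_years",
             gender = "gender", sex = "gender",
             role = "role", cohort = "role",
             disease = "disease", activity = "activity",
             localisation = "localisation", localization = "localisation",
             pucai = "PUCAI", pcdai = "PCDAI", matts = "Matts",
             ses_cd = "SES_CD", ses = "SES_CD",
             indican_mg_l = "indican_mg_L", indican = "indican_mg_L",
             zonulin_ng_ml = "zonulin_ng_mL", zonulin = "zonulin_ng_mL",
             siga_ug_ml = "sIgA_ug_mL", siga = "sIgA_ug_mL")
  key <- tolower(nms)
  ifelse(key %in% names(canon), unname(canon[key]), nms)
}

parse_enum <- function(x, field, map, default = NULL) {
  key <- tolower(trimws(x))
  out <- unname(map[key])
  if (!is.null(default)) out[is.na(x)] <- default
  unknown <- !is.na(x) & is.na(out)
  if (any(unknown))
    stop(sprintf("unknown %s token: %s", field,
                 paste(unique(x[unknown]), collapse = ", ")))
  out
}

check_score_disease <- function(df) {
  # PUCAI is a UC instrument, PCDAI a CD instrument; both set is inconsistent
  if (all(c("PUCAI", "PCDAI") %in% names(df))) {
    both <- !is.na(df$PUCAI) & !is.na(df$PCDAI)
    if (any(both))
      stop("rows carry both PUCAI and PCDAI: ",
           paste(df$sample_id[both], collapse = ", "))
  }
  if ("disease" %in% names(df)) {
    if ("PUCAI" %in% names(df) && any(!is.na(df$PUCAI) & df$disease == "CD"))
      stop("PUCAI assigned to a CD subject")
    if ("PCDAI" %in% names(df) && any(!is.na(df$PCDAI) & df$disease == "UC"))
      stop("PCDAI assigned to a UC subject")
  }
  invisible(df)
}

#' Write subject/sample metadata to TSV
#'
#' @param metadata data.frame as returned by [read_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Check that every metadata sample is present in a taxa table
#'
#' @param metadata metadata data.frame.
#' @param table a [taxa_table()].
#' @return invisibly `TRUE`; errors listing orphan samples otherwise.
#' @export
check_samples_present <- function(metadata, table) {
  missing <- setdiff(metadata$sample_id, sample_ids(table))
  if (length(missing))
    stop("metadata samples absent from taxa table: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
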