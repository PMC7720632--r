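.tp53_vocab <- c("wild-type", "deleted", "mutated", "missing")

.check_cols <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
}

#' Read / write the replicate-level spot table (TSV)
#'
#' Long format, one row per printed spot: `sample_id, slide_id,
#' scan_batch, slide_batch, subarray, analyte_id, clone_id, replicate,
#' fg, bg, flag`. Lines starting with `#` are comments. Validation:
#' replicate index 1--3, non-negative intensities, flag vocabulary
#' (`ok`/`bad`), unique (sample, analyte, replicate) keys.
#'
#' @param path file path.
#' @return `read_spot_table`: a data.table.
#' @export
read_spot_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "")
  .check_cols(dt, c("sample_id", "slide_id", "scan_batch", "slide_batch",
                    "subarray", "analyte_id", "clone_id", "replicate",
                    "fg", "bg", "flag"), "spot table")
  if (any(dt$replicate < 1L | dt$replicate > 3L))
    stop("column 'replicate': index outside 1..3 (three replicate spots per analyte)")
  if (any(dt$fg < 0, na.rm = TRUE) || any(dt$bg < 0, na.rm = TRUE))
    stop("columns 'fg'/'bg': intensities must be non-negative")
  bad <- setdiff(unique(dt$flag), c("ok", "bad"))
  if (length(bad))
    stop("column 'flag': unknown value(s) ", paste(bad, collapse = ", "))
  if (anyDuplicated(dt[, c("sample_id", "analyte_id", "replicate")]))
    stop("duplicate (sample_id, analyte_id, replicate) keys")
  dt
}

#' @rdname read_spot_table
#' @param spots spot table to write.
#' @param version_comment include a header comment with the package
#'   version.
#' @export
write_spot_table <- function(spots, path, version_comment = TRUE) {
  if (version_comment)
    writeLines(sprintf("# mclris %s spot table",
                       as.character(packageVersion("mclris"))), path)
  data.table::fwrite(spots, path, sep = "\t", append = version_comment,
                     col.names = TRUE)
  invisible(path)
}

#' Read / write the per-patient clinical table (CSV)
#'
#' Columns: `patient_id, os_months, os_event, pfs_months, pfs_event, age,
#' ecog, ldh_ratio, wbc, mipi_score, ki67_pct, tp53_status`. Missing
#' values are empty fields. Validation: unique patient ids, binary event
#' flags, `pfs_months <= os_months`, ECOG 0--4, TP53 vocabulary.
#'
#' @param path file path.
#' @return `read_clinical`: a data.frame.
#' @export
read_clinical <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = ",", header = TRUE,
                                        na.strings = ""))
  .check_cols(df, c("patient_id", "os_months", "os_event", "pfs_months",
                    "pfs_event", "age", "ecog", "ldh_ratio", "wbc"),
              "clinical table")
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id")
  for (cc in c("os_event", "pfs_event"))
    if (!all(df[[cc]] %in% c(0, 1)))
      stop("column '", cc, "': event flags must be 0/1")
  if (any(df$pfs_months > df$os_months + 1e-9, na.rm = TRUE))
    stop("column 'pfs_months': PFS exceeds OS for some patient(s)")
  if (any(!is.na(df$ecog) & (df$ecog < 0 | df$ecog > 4)))
    stop("column 'ecog': must be 0..4")
  if ("tp53_status" %in% names(df)) {
    bad <- setdiff(unique(na.omit(df$tp53_status)), .tp53_vocab)
    if (length(bad))
      stop("column 'tp53_status': unknown value(s) ",
           paste(bad, collapse = ", "))
  }
  df
}

#' @rdname read_clinical
#' @param clinical clinical table to write.
#' @export
write_clinical <- function(clinical, path) {
  data.table::fwrite(clinical, path, sep = ",", na = "")
  invisible(path)
}

#' Read / write the analyte annotation (CSV)
#'
#' Maps each printed scFv clone to its target protein: `analyte_id,
#' protein_id, protein_name, uniprot_id, clone_number`.
#'
#' @param path file path.
#' @return `read_annotation`: a data.frame.
#' @export
read_annotation <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = ",", header = TRUE,
                                        na.strings = ""))
  .check_cols(df, c("analyte_id", "protein_id"), "annotation")
  if (anyDuplicated(df$analyte_id)) stop("duplicate analyte_id in annotation")
  df
}

#' @rdname read_annotation
#' @param annotation annotation table to write.
#' @export
write_annotation <- function(annotation, path) {
  data.table::fwrite(annotation, path, sep = ",", na = "")
  invisible(path)
}

#' Read / write an expression matrix (TSV, samples x analytes)
#'
#' First column `sample_id`, remaining columns analytes, values log2
#' signal; empty fields are missing. `#` header comments are skipped.
#'
#' @param path file path.
#' @return `read_expression_matrix`: numeric matrix with sample rownames.
#' @export
read_expression_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "")
  m <- as.matrix(dt[, -1L])
  rownames(m) <- dt[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_matrix
#' @param x matrix to write.
#' @param version_comment include a header comment with the package
#'   version.
#' @export
write_expression_matrix <- function(x, path, version_comment = TRUE) {
  df <- data.table::data.table(sample_id = rownames(x))
  df <- cbind(df, data.table::as.data.table(x))
  if (version_comment)
    writeLines(sprintf("# mclris %s expression matrix",
                       as.character(packageVersion("mclris"))), path)
  data.table::fwrite(df, path, sep = "\t", append = version_comment,
                     col.names = TRUE, na = "")
  invisible(path)
}
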