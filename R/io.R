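# Table readers/writers. All files are UTF-8 CSV (TSV accepted by extension);
# numeric columns are written with 17 significant digits so that
# write -> read round trips are lossless at double precision.

sep_for_path <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, sep = sep_for_path(path), stringsAsFactors = FALSE,
                  check.names = FALSE, fileEncoding = "UTF-8")
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}

coerce_numeric_col <- function(df, col, what, allow_na = FALSE) {
  raw <- df[[col]]
  x <- suppressWarnings(as.numeric(raw))
  bad <- is.na(x) & !(is.na(raw) | raw == "")
  if (any(bad)) {
    stop(what, ": non-numeric value in column '", col, "' at data row(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  if (!allow_na && anyNA(x)) {
    stop(what, ": missing value in column '", col, "' at data row(s) ",
         paste(utils::head(which(is.na(x)), 5L), collapse = ", "))
  }
  x
}

format_full <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- ""
    out
  } else if (is.numeric(x)) {
    out <- as.character(x)
    out[is.na(x)] <- ""
    out
  } else if (is.logical(x)) {
    as.character(x)
  } else {
    as.character(x)
  }
}

write_delim_precise <- function(df, path) {
  out <- as.data.frame(lapply(df, format_full), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  # quote free-text columns only (descriptions may contain commas)
  qcols <- which(vapply(df, is.character, logical(1)))
  utils::write.csv(out, path, row.names = FALSE,
                   quote = if (length(qcols)) qcols else FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample design table
#'
#' The design table describes every MS sample: `sample_id`, `condition` (e.g.
#' VC/IBU/PEA), `replicate` (integer), `time_h` (hours) and `labeled` (TRUE for
#' D2O labeling, FALSE for H2O natural-abundance controls).
#'
#' @param path CSV/TSV file path.
#' @return Data frame with one row per sample.
#' @export
read_design <- function(path) {
  df <- read_delim_auto(path)
  require_columns(df, c("sample_id", "condition", "replicate", "time_h",
                        "labeled"), "design table")
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  df$replicate <- as.integer(coerce_numeric_col(df, "replicate", "design table"))
  df$time_h <- coerce_numeric_col(df, "time_h", "design table")
  lab <- df$labeled
  if (!is.logical(lab)) lab <- toupper(as.character(lab)) %in% c("TRUE", "T", "1", "YES")
  df$labeled <- lab
  validate_design(df)
  df
}

validate_design <- function(design) {
  if (anyDuplicated(design$sample_id)) stop("duplicated sample_id in design")
  key <- paste(design$condition, design$replicate, design$time_h, design$labeled)
  if (anyDuplicated(key)) {
    stop("duplicated (condition, replicate, time_h, labeled) combination in design")
  }
  if (any(design$replicate < 1L)) stop("replicate indices must be >= 1")
  if (any(design$time_h < 0)) stop("negative time_h in design")
  lab <- design[design$labeled, , drop = FALSE]
  reps <- tapply(lab$replicate, lab$condition, function(r) length(unique(r)))
  if (length(unique(reps)) > 1L) {
    stop("labeled samples must have the same replicate count in every condition")
  }
  invisible(design)
}

#' Read a peptide mass-isotopomer table
#'
#' Expected columns: `peptide_id`, `sequence`, `protein_accession`,
#' `sample_id`, `time_h`, `m0`, `m1`.
#'
#' @param path CSV/TSV file path.
#' @param design Optional design table; when supplied, unknown `sample_id`
#'   values are an error rather than silently dropped.
#' @return Data frame with one row per (peptide, sample) measurement.
#' @export
read_isotopomer_table <- function(path, design = NULL) {
  df <- read_delim_auto(path)
  require_columns(df, c("peptide_id", "sequence", "protein_accession",
                        "sample_id", "time_h", "m0", "m1"),
                  "isotopomer table")
  df$peptide_id <- as.character(df$peptide_id)
  df$sequence <- as.character(df$sequence)
  df$protein_accession <- as.character(df$protein_accession)
  df$sample_id <- as.character(df$sample_id)
  df$time_h <- coerce_numeric_col(df, "time_h", "isotopomer table")
  df$m0 <- coerce_numeric_col(df, "m0", "isotopomer table")
  df$m1 <- coerce_numeric_col(df, "m1", "isotopomer table")
  if (any(df$m0 < 0) || any(df$m1 < 0)) stop("negative isotopomer intensity")
  if (!is.null(design)) {
    unknown <- setdiff(unique(df$sample_id), design$sample_id)
    if (length(unknown)) {
      stop("isotopomer table contains sample_id(s) absent from design: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
  }
  df
}

#' @rdname read_isotopomer_table
#' @param x Isotopomer data frame to write.
#' @export
write_isotopomer_table <- function(x, path) write_delim_precise(x, path)

#' Read a protein abundance matrix
#'
#' A wide table with a `protein_accession` column followed by one column per
#' sample (values in fmol/ug; empty cells mean "not quantified", never zero).
#'
#' @param path CSV/TSV file path.
#' @param design Design table; every sample column must appear in it.
#' @return Numeric matrix (proteins x samples) with accession rownames and
#'   attribute `normalized = FALSE`.
#' @export
read_abundance_table <- function(path, design) {
  df <- read_delim_auto(path)
  require_columns(df, "protein_accession", "abundance table")
  acc <- as.character(df$protein_accession)
  if (anyDuplicated(acc)) {
    stop("duplicated protein accession(s) in abundance table: ",
         paste(utils::head(unique(acc[duplicated(acc)]), 5L), collapse = ", "))
  }
  samp <- setdiff(names(df), "protein_accession")
  unknown <- setdiff(samp, design$sample_id)
  if (length(unknown)) {
    stop("abundance table contains sample column(s) absent from design: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  vals <- vapply(samp, function(cl)
    coerce_numeric_col(df, cl, "abundance table", allow_na = TRUE),
    numeric(nrow(df)))
  mat <- matrix(vals, nrow = nrow(df), dimnames = list(acc, samp))
  if (any(mat < 0, na.rm = TRUE)) stop("negative abundance value")
  attr(mat, "normalized") <- FALSE
  mat
}

#' @rdname read_abundance_table
#' @param mat Abundance matrix to write (rownames are accessions).
#' @export
write_abundance_table <- function(mat, path) {
  df <- data.frame(protein_accession = rownames(mat),
                   as.data.frame(mat, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_delim_precise(df, path)
}

#' Read a protein description table
#'
#' Two columns: `protein_accession` and free-text `description` (used for
#' ribosomal protein classification).
#'
#' @param path CSV/TSV file path.
#' @return Data frame with `protein_accession` and `description`.
#' @export
read_description_table <- function(path) {
  df <- read_delim_auto(path)
  require_columns(df, c("protein_accession", "description"), "description table")
  df$protein_accession <- as.character(df$protein_accession)
  df$description <- as.character(df$description)
  df
}

#' @rdname read_design
#' @param x Design data frame to write.
#' @export
write_design <- function(x, path) write_delim_precise(x, path)
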