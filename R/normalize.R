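#' Inter-sample abundance normalization
#'
#' Scales every sample by a single factor so that the median protein-wise
#' ratio of that sample to a reference sample equals one. The reference is the
#' sample whose median log-abundance is closest to the overall median of
#' sample medians (ties broken by sample name order). Zeros and missing cells
#' are excluded from ratio medians; zeros are otherwise kept as measured
#' values.
#'
#' @param mat Abundance matrix from [read_abundance_table()] (proteins x
#'   samples, not yet normalized).
#' @return The scaled matrix with attributes `normalized = TRUE`,
#'   `scaling_factors` (named per-sample factors) and `reference_sample`.
#' @export
normalize_intersample <- function(mat) {
  if (isTRUE(attr(mat, "normalized"))) stop("matrix is already normalized")
  if (ncol(mat) < 2L) stop("normalization needs at least 2 samples")
  logmed <- apply(mat, 2L, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (!length(v)) stop("sample with no positive abundances")
    stats::median(log(v))
  })
  target <- stats::median(logmed)
  cand <- which(abs(logmed - target) == min(abs(logmed - target)))
  ref <- cand[order(colnames(mat)[cand])][1L]
  factors <- vapply(seq_len(ncol(mat)), function(j) {
    ok <- !is.na(mat[, j]) & !is.na(mat[, ref]) & mat[, j] > 0 & mat[, ref] > 0
    if (!any(ok)) {
      stop("sample '", colnames(mat)[j],
           "' shares no nonzero proteins with the reference sample")
    }
    1 / stats::median(mat[ok, j] / mat[ok, ref])
  }, numeric(1))
  names(factors) <- colnames(mat)
  out <- sweep(mat, 2L, factors, `*`)
  attr(out, "normalized") <- TRUE
  attr(out, "scaling_factors") <- factors
  attr(out, "reference_sample") <- colnames(mat)[ref]
  out
}

#' Protein abundance ratios across the labeling window
#'
#' For every protein and labeled (condition, replicate) pair, computes the
#' abundance ratio P(t1)/P(t0) used to adjust the degradation rate constant.
#' Pairing is per replicate by default (same condition, same replicate at the
#' two time points); `"condition_mean"` instead uses the mean across replicates
#' at each time point, giving one shared ratio per condition.
#'
#' @param mat Normalized abundance matrix.
#' @param design Design table covering the matrix's sample columns.
#' @param t0,t1 Window boundaries in hours.
#' @param pairing `"replicate"` (default) or `"condition_mean"`.
#' @return Long data frame: `protein_accession`, `condition`, `replicate`,
#'   `abundance_ratio` (`NA` when either abundance is missing or nonpositive).
#' @export
abundance_ratio_table <- function(mat, design, t0 = 12, t1 = 36,
                                  pairing = c("replicate", "condition_mean")) {
  pairing <- match.arg(pairing)
  lab <- design[design$labeled, , drop = FALSE]
  cells <- unique(lab[, c("condition", "replicate")])
  cells <- cells[order(cells$condition, cells$replicate), , drop = FALSE]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cond <- cells$condition[i]; rep_i <- cells$replicate[i]
    s0 <- lab$sample_id[lab$condition == cond & lab$replicate == rep_i & lab$time_h == t0]
    s1 <- lab$sample_id[lab$condition == cond & lab$replicate == rep_i & lab$time_h == t1]
    if (pairing == "replicate") {
      if (length(s0) != 1L || length(s1) != 1L ||
          !all(c(s0, s1) %in% colnames(mat))) {
        ratio <- rep(NA_real_, nrow(mat))
      } else {
        p0 <- mat[, s0]; p1 <- mat[, s1]
        ratio <- ifelse(!is.na(p0) & !is.na(p1) & p0 > 0 & p1 > 0, p1 / p0, NA_real_)
      }
    } else {
      s0 <- lab$sample_id[lab$condition == cond & lab$time_h == t0]
      s1 <- lab$sample_id[lab$condition == cond & lab$time_h == t1]
      s0 <- intersect(s0, colnames(mat)); s1 <- intersect(s1, colnames(mat))
      if (!length(s0) || !length(s1)) {
        ratio <- rep(NA_real_, nrow(mat))
      } else {
        p0 <- rowMeans(mat[, s0, drop = FALSE], na.rm = TRUE)
        p1 <- rowMeans(mat[, s1, drop = FALSE], na.rm = TRUE)
        ratio <- ifelse(is.finite(p0) & is.finite(p1) & p0 > 0 & p1 > 0,
                        p1 / p0, NA_real_)
      }
    }
    data.frame(protein_accession = rownames(mat), condition = cond,
               replicate = rep_i, abundance_ratio = ratio,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Complete-case filtering over the condition x replicate grid
#'
#' Retains only proteins quantified in every (condition, replicate) cell of
#' the labeled design, the filter that gates all downstream statistics (no
#' imputation is ever performed).
#'
#' @param x Either a long data frame with columns `protein_accession`,
#'   `condition`, `replicate` and `value`, or an abundance matrix whose
#'   columns are samples.
#' @param design Design table defining the full grid.
#' @param time_h For the matrix method, optionally restrict the grid to
#'   labeled samples at the given time point(s).
#' @param ... Passed to methods.
#' @return List with `data` (the filtered input), `retained` (character vector
#'   of retained accessions) and `n_retained`.
#' @export
filter_complete_cases <- function(x, design, ...) UseMethod("filter_complete_cases")

#' @rdname filter_complete_cases
#' @export
filter_complete_cases.data.frame <- function(x, design, ...) {
  require_columns(x, c("protein_accession", "condition", "replicate", "value"),
                  "complete-case input")
  lab <- design[design$labeled, , drop = FALSE]
  cells <- unique(paste(lab$condition, lab$replicate, sep = "\r"))
  ok <- !is.na(x$value)
  key <- paste(x$condition, x$replicate, sep = "\r")[ok]
  acc <- x$protein_accession[ok]
  ncell <- tapply(key, acc, function(k) length(unique(intersect(k, cells))))
  retained <- sort(names(ncell)[ncell == length(cells)])
  data <- x[x$protein_accession %in% retained, , drop = FALSE]
  list(data = data, retained = retained, n_retained = length(retained))
}

#' @rdname filter_complete_cases
#' @export
filter_complete_cases.matrix <- function(x, design, time_h = NULL, ...) {
  lab <- design[design$labeled, , drop = FALSE]
  if (!is.null(time_h)) lab <- lab[lab$time_h %in% time_h, , drop = FALSE]
  cols <- intersect(lab$sample_id, colnames(x))
  if (length(cols) < nrow(lab)) {
    stop("abundance matrix lacks sample column(s) required by the design grid")
  }
  keep <- rowSums(is.na(x[, cols, drop = FALSE])) == 0L
  retained <- sort(rownames(x)[keep])
  data <- x[keep, , drop = FALSE]
  attr(data, "normalized") <- attr(x, "normalized")
  list(data = data, retained = retained, n_retained = length(retained))
}
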