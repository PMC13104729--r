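#' Fit two-point turnover kinetics to a labeling experiment
#'
#' The central estimator of the package. Converts a peptide mass-isotopomer
#' table into peptide- and protein-level degradation rate constants and
#' fractional synthesis rates (FSR) using the two-point rise-to-plateau model:
#' each peptide's RIA at the start and end of the labeling window, together
#' with its exchangeable-hydrogen plateau and the protein's abundance ratio
#' across the window, yield `k_deg` in closed form (see [compute_kdeg()]).
#' Protein FSR is the median over the protein's valid unique peptides,
#' computed per condition and replicate.
#'
#' @param isotopomer Data frame from [read_isotopomer_table()] (columns
#'   `peptide_id`, `sequence`, `protein_accession`, `sample_id`, `time_h`,
#'   `m0`, `m1`).
#' @param design Design table from [read_design()].
#' @param abundance Optional abundance matrix from [read_abundance_table()];
#'   when supplied, per-protein abundance ratios P(t1)/P(t0) adjust `k_deg`.
#'   Proteins without usable abundance get ratio 1 and are flagged.
#' @param exchange_table Per-residue exchangeable hydrogen table
#'   ([read_exchangeable_table()]).
#' @param dh_exp,dh_nat Precursor D:H ratios (experimental and natural).
#' @param t0,t1 Labeling window boundaries in hours (default 12 and 36).
#' @param ria_t0_mode `"control"` (default): baseline RIA is the per-peptide
#'   mean RIA across unlabeled (H2O) control samples, falling back to the
#'   labeled `t0` sample for peptides without control measurements;
#'   `"first_timepoint"`: always the labeled `t0` sample of the same
#'   condition and replicate.
#' @param abundance_pairing Passed to [abundance_ratio_table()].
#' @param normalize Normalize the abundance matrix with
#'   [normalize_intersample()] first (skipped when already normalized).
#' @return An object of class `"turnover_fit"`: a list with elements
#'   `peptides` (per peptide x condition x replicate kinetics, with validity
#'   flags and reasons), `proteins` (protein-level median FSR with peptide
#'   support), `complete` (complete-case filter result), `mixed` (per-sample
#'   mixed-protein FSR), `abundance` (normalized matrix or NULL), `design`,
#'   `settings` and `counts`.
#' @seealso [fsr_contrasts()], [subunit_summaries()], [simulate_dpp()]
#' @export
turnover_fit <- function(isotopomer, design, abundance = NULL,
                         exchange_table = read_exchangeable_table(),
                         dh_exp = 0.04, dh_nat = 1.5576e-4,
                         t0 = 12, t1 = 36,
                         ria_t0_mode = c("control", "first_timepoint"),
                         abundance_pairing = c("replicate", "condition_mean"),
                         normalize = TRUE) {
  ria_t0_mode <- match.arg(ria_t0_mode)
  abundance_pairing <- match.arg(abundance_pairing)
  validate_design(design)
  unknown <- setdiff(unique(isotopomer$sample_id), design$sample_id)
  if (length(unknown)) {
    stop("isotopomer table contains sample_id(s) absent from design: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }

  zero <- (isotopomer$m0 + isotopomer$m1) == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) with zero isotopomer signal dropped")
    isotopomer <- isotopomer[!zero, , drop = FALSE]
  }

  # peptide metadata; a peptide sequence observed under >1 accession is not
  # "unique" and is excluded from protein medians
  pep <- unique(isotopomer[, c("peptide_id", "sequence", "protein_accession")])
  if (anyDuplicated(pep$peptide_id)) {
    stop("peptide_id mapped to more than one sequence/accession")
  }
  seq_acc <- unique(pep[, c("sequence", "protein_accession")])
  shared <- unique(seq_acc$sequence[duplicated(seq_acc$sequence)])
  pep$unique_peptide <- !(pep$sequence %in% shared)
  pep$n_exchangeable <- count_exchangeable_hydrogens(pep$sequence, exchange_table)

  di <- match(isotopomer$sample_id, design$sample_id)
  rec <- data.frame(peptide_id = isotopomer$peptide_id,
                    condition = design$condition[di],
                    replicate = design$replicate[di],
                    time_h = design$time_h[di],
                    labeled = design$labeled[di],
                    m0 = isotopomer$m0, m1 = isotopomer$m1,
                    stringsAsFactors = FALSE)

  # collapse duplicate measurements of a peptide within one sample by summing
  # intensities before forming the ratio
  rec_key <- paste(rec$peptide_id, rec$condition, rec$replicate, rec$time_h,
                   rec$labeled, sep = "\r")
  m0s <- rowsum(rec$m0, rec_key); m1s <- rowsum(rec$m1, rec_key)
  u <- !duplicated(rec_key)
  rec <- rec[u, , drop = FALSE]
  rec$m0 <- m0s[match(rec_key[u], rownames(m0s)), 1L]
  rec$m1 <- m1s[match(rec_key[u], rownames(m1s)), 1L]
  rec$ria <- rec$m1 / (rec$m0 + rec$m1)

  # baseline RIA per peptide (control mode) and per cell (first-timepoint)
  ctrl <- rec[!rec$labeled, , drop = FALSE]
  ctrl_mean <- if (nrow(ctrl)) tapply(ctrl$ria, ctrl$peptide_id, mean) else NULL

  lab1 <- rec[rec$labeled & rec$time_h == t1, , drop = FALSE]
  lab0 <- rec[rec$labeled & rec$time_h == t0, , drop = FALSE]
  cell_key <- function(d) paste(d$peptide_id, d$condition, d$replicate, sep = "\r")
  r0_first <- lab0$ria[match(cell_key(lab1), cell_key(lab0))]

  if (ria_t0_mode == "control" && !is.null(ctrl_mean)) {
    r0_ctrl <- as.numeric(ctrl_mean[match(lab1$peptide_id, names(ctrl_mean))])
    ria_t0 <- ifelse(is.na(r0_ctrl), r0_first, r0_ctrl)
    ria_t0_source <- ifelse(is.na(r0_ctrl), "first_timepoint", "control")
  } else {
    ria_t0 <- r0_first
    ria_t0_source <- rep("first_timepoint", nrow(lab1))
  }

  pi <- match(lab1$peptide_id, pep$peptide_id)
  out <- data.frame(peptide_id = lab1$peptide_id,
                    sequence = pep$sequence[pi],
                    protein_accession = pep$protein_accession[pi],
                    condition = lab1$condition,
                    replicate = lab1$replicate,
                    n_exchangeable = pep$n_exchangeable[pi],
                    unique_peptide = pep$unique_peptide[pi],
                    ria_t0 = ria_t0,
                    ria_t1 = lab1$ria,
                    ria_t0_source = ria_t0_source,
                    stringsAsFactors = FALSE, row.names = NULL)

  # abundance ratios
  abn <- NULL
  out$abundance_ratio <- 1
  out$abundance_imputed <- TRUE
  if (!is.null(abundance)) {
    abn <- abundance
    if (normalize && !isTRUE(attr(abn, "normalized"))) {
      abn <- normalize_intersample(abn)
    }
    ratios <- abundance_ratio_table(abn, design, t0 = t0, t1 = t1,
                                    pairing = abundance_pairing)
    rk <- paste(ratios$protein_accession, ratios$condition, ratios$replicate,
                sep = "\r")
    ok <- paste(out$protein_accession, out$condition, out$replicate, sep = "\r")
    r <- ratios$abundance_ratio[match(ok, rk)]
    hit <- !is.na(r)
    out$abundance_ratio[hit] <- r[hit]
    out$abundance_imputed <- !hit
  }

  # kinetics, row-wise validity
  valid_in <- !is.na(out$ria_t0) & !is.na(out$ria_t1)
  reason <- ifelse(valid_in, "ok", "missing baseline RIA")
  degen <- valid_in & out$ria_t0 >= 1
  reason[degen] <- "degenerate baseline"
  calc <- valid_in & !degen
  out$ria_plateau <- NA_real_
  out$f <- NA_real_; out$k_deg <- NA_real_
  if (any(calc)) {
    pl <- compute_ria_plateau(out$ria_t0[calc], out$n_exchangeable[calc],
                              dh_exp = dh_exp, dh_nat = dh_nat)
    out$ria_plateau[calc] <- pl
    kd <- compute_kdeg(out$ria_t0[calc], out$ria_t1[calc], pl, t0 = t0, t1 = t1,
                       abundance_ratio = out$abundance_ratio[calc])
    out$f[calc] <- kd$f
    out$k_deg[calc] <- kd$k_deg
    reason[calc] <- kd$reason
  }
  out$valid <- reason == "ok"
  out$reason <- reason
  out$fsr_pct_per_h <- ifelse(out$valid, 100 * out$k_deg, NA_real_)

  # protein-level median FSR over valid unique peptides, per cell
  vu <- out[out$valid & out$unique_peptide, , drop = FALSE]
  if (nrow(vu)) {
    key <- paste(vu$protein_accession, vu$condition, vu$replicate, sep = "\r")
    med <- tapply(vu$fsr_pct_per_h, key, stats::median)
    npep <- tapply(vu$fsr_pct_per_h, key, length)
    parts <- do.call(rbind, strsplit(names(med), "\r", fixed = TRUE))
    proteins <- data.frame(protein_accession = parts[, 1L],
                           condition = parts[, 2L],
                           replicate = as.integer(parts[, 3L]),
                           median_fsr = as.numeric(med),
                           n_peptides = as.integer(npep),
                           stringsAsFactors = FALSE, row.names = NULL)
    proteins <- proteins[order(proteins$protein_accession, proteins$condition,
                               proteins$replicate), , drop = FALSE]
    rownames(proteins) <- NULL
  } else {
    proteins <- data.frame(protein_accession = character(0),
                           condition = character(0), replicate = integer(0),
                           median_fsr = numeric(0), n_peptides = integer(0))
  }

  long <- proteins
  names(long)[names(long) == "median_fsr"] <- "value"
  complete <- filter_complete_cases(long[, c("protein_accession", "condition",
                                             "replicate", "value")], design)

  # mixed-protein FSR: per sample median over complete-case proteins
  cc <- proteins[proteins$protein_accession %in% complete$retained, , drop = FALSE]
  if (nrow(cc)) {
    mkey <- paste(cc$condition, cc$replicate, sep = "\r")
    mf <- tapply(cc$median_fsr, mkey, stats::median)
    mp <- do.call(rbind, strsplit(names(mf), "\r", fixed = TRUE))
    mixed <- data.frame(condition = mp[, 1L], replicate = as.integer(mp[, 2L]),
                        mixed_fsr = as.numeric(mf), stringsAsFactors = FALSE,
                        row.names = NULL)
    mixed <- mixed[order(mixed$condition, mixed$replicate), , drop = FALSE]
    rownames(mixed) <- NULL
  } else {
    mixed <- data.frame(condition = character(0), replicate = integer(0),
                        mixed_fsr = numeric(0))
  }

  structure(list(
    call = match.call(),
    peptides = out,
    proteins = proteins,
    complete = complete,
    mixed = mixed,
    abundance = abn,
    design = design,
    settings = list(dh_exp = dh_exp, dh_nat = dh_nat, t0 = t0, t1 = t1,
                    ria_t0_mode = ria_t0_mode,
                    abundance_pairing = abundance_pairing,
                    abundance_adjusted = !is.null(abundance)),
    counts = list(
      n_records = nrow(isotopomer),
      n_peptides = nrow(pep),
      n_peptide_rates = nrow(out),
      n_valid_peptide_rates = sum(out$valid),
      n_proteins = length(unique(out$protein_accession)),
      n_proteins_quantified = length(unique(proteins$protein_accession)),
      n_proteins_complete = complete$n_retained)
  ), class = "turnover_fit")
}

#' @export
print.turnover_fit <- function(x, ...) {
  cat("Two-point D2O turnover fit\n")
  cat(sprintf("  %d peptides / %d proteins; %d of %d peptide rates valid\n",
              x$counts$n_peptides, x$counts$n_proteins,
              x$counts$n_valid_peptide_rates, x$counts$n_peptide_rates))
  cat(sprintf("  labeling window %g-%g h; precursor enrichment %.4g (natural %.4g)\n",
              x$settings$t0, x$settings$t1, x$settings$dh_exp, x$settings$dh_nat))
  cat(sprintf("  %d proteins quantified, %d complete across all condition x replicate cells\n",
              x$counts$n_proteins_quantified, x$counts$n_proteins_complete))
  invisible(x)
}

#' @export
summary.turnover_fit <- function(object, ...) {
  mx <- object$mixed
  bycond <- NULL
  p_mixed <- NA_real_
  if (nrow(mx)) {
    bycond <- data.frame(
      condition = sort(unique(mx$condition)),
      mean_mixed_fsr = as.numeric(tapply(mx$mixed_fsr, mx$condition, mean)[sort(unique(mx$condition))]),
      sd_mixed_fsr = as.numeric(tapply(mx$mixed_fsr, mx$condition, sd)[sort(unique(mx$condition))]),
      stringsAsFactors = FALSE)
    if (length(unique(mx$condition)) >= 2L &&
        all(table(mx$condition) >= 2L)) {
      p_mixed <- one_way_anova(mx$mixed_fsr, mx$condition)$p_value
    }
  }
  res <- list(counts = object$counts, settings = object$settings,
              mixed_by_condition = bycond, mixed_anova_p = p_mixed,
              invalid_reasons = table(object$peptides$reason[!object$peptides$valid]))
  class(res) <- "summary.turnover_fit"
  res
}

#' @export
print.summary.turnover_fit <- function(x, ...) {
  cat("Two-point D2O turnover fit\n\n")
  cat(sprintf("Peptide rates: %d valid / %d computed (of %d records)\n",
              x$counts$n_valid_peptide_rates, x$counts$n_peptide_rates,
              x$counts$n_records))
  if (length(x$invalid_reasons)) {
    for (r in names(x$invalid_reasons)) {
      cat(sprintf("  excluded (%s): %d\n", r, x$invalid_reasons[[r]]))
    }
  }
  cat(sprintf("Proteins: %d quantified, %d complete-case\n\n",
              x$counts$n_proteins_quantified, x$counts$n_proteins_complete))
  if (!is.null(x$mixed_by_condition)) {
    cat("Mixed-protein FSR (%/h), complete-case proteins:\n")
    for (i in seq_len(nrow(x$mixed_by_condition))) {
      cat(sprintf("  %-6s %.3f +/- %.3f\n", x$mixed_by_condition$condition[i],
                  x$mixed_by_condition$mean_mixed_fsr[i],
                  x$mixed_by_condition$sd_mixed_fsr[i]))
    }
    if (!is.na(x$mixed_anova_p)) {
      cat(sprintf("  one-way ANOVA across conditions: p = %.3g\n", x$mixed_anova_p))
    }
  }
  invisible(x)
}

#' Protein FSR coefficients of a turnover fit
#'
#' @param object A `"turnover_fit"`.
#' @param ... Unused.
#' @return Matrix of protein FSR (percent/h): the median across replicates of
#'   the per-replicate protein median FSR, proteins x conditions. `NA` where a
#'   protein was not quantified in a condition.
#' @export
coef.turnover_fit <- function(object, ...) {
  pr <- object$proteins
  if (!nrow(pr)) return(matrix(numeric(0), 0, 0))
  accs <- sort(unique(pr$protein_accession))
  conds <- sort(unique(pr$condition))
  m <- matrix(NA_real_, length(accs), length(conds),
              dimnames = list(accs, conds))
  med <- tapply(pr$median_fsr, list(pr$protein_accession, pr$condition),
                stats::median)
  m[rownames(med), colnames(med)] <- med
  m
}

predict_ria <- function(peptides, time_h, t0) {
  r0 <- peptides$ria_t0; pl <- peptides$ria_plateau
  k <- peptides$k_deg; a <- peptides$abundance_ratio
  sapply(time_h, function(tt) {
    r0 + (pl - r0) * (1 - exp(-k * (tt - t0))) / a
  })
}

#' Predicted RIA trajectories from a turnover fit
#'
#' Evaluates the fitted rise-to-plateau curve of every valid peptide record at
#' requested times (hours since labeling start).
#'
#' @param object A `"turnover_fit"`.
#' @param time_h Numeric vector of times (hours); default the end of the
#'   fitted labeling window.
#' @param ... Unused.
#' @return Data frame of peptide identifiers plus one `ria_at_<t>` column per
#'   requested time.
#' @export
predict.turnover_fit <- function(object, time_h = NULL, ...) {
  if (is.null(time_h)) time_h <- object$settings$t1
  pp <- object$peptides[object$peptides$valid, , drop = FALSE]
  pred <- predict_ria(pp, time_h, object$settings$t0)
  pred <- matrix(pred, nrow = nrow(pp))
  colnames(pred) <- paste0("ria_at_", time_h)
  cbind(pp[, c("peptide_id", "protein_accession", "condition", "replicate")],
        as.data.frame(pred))
}

#' @export
fitted.turnover_fit <- function(object, ...) {
  pp <- object$peptides[object$peptides$valid, , drop = FALSE]
  as.numeric(predict_ria(pp, object$settings$t1, object$settings$t0))
}

#' Residuals of a turnover fit
#'
#' The two-point closed form interpolates each peptide exactly, so RIA
#' residuals (`type = "ria"`) are zero by construction and mainly useful as a
#' self-consistency check. `type = "peptide"` (default) instead returns the
#' within-protein dispersion: each valid unique peptide's FSR minus its
#' protein's median FSR in the same condition and replicate.
#'
#' @param object A `"turnover_fit"`.
#' @param type `"peptide"` or `"ria"`.
#' @param ... Unused.
#' @return Numeric vector of residuals.
#' @export
residuals.turnover_fit <- function(object, type = c("peptide", "ria"), ...) {
  type <- match.arg(type)
  if (type == "ria") {
    pp <- object$peptides[object$peptides$valid, , drop = FALSE]
    return(pp$ria_t1 - fitted(object))
  }
  vu <- object$peptides[object$peptides$valid & object$peptides$unique_peptide, ,
                        drop = FALSE]
  pk <- paste(vu$protein_accession, vu$condition, vu$replicate, sep = "\r")
  prk <- paste(object$proteins$protein_accession, object$proteins$condition,
               object$proteins$replicate, sep = "\r")
  vu$fsr_pct_per_h - object$proteins$median_fsr[match(pk, prk)]
}

#' Plot a turnover fit
#'
#' Left panel: density of log2 protein FSR per condition (complete-case
#' proteins). Right panel: per-sample mixed-protein FSR by condition.
#'
#' @param x A `"turnover_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.turnover_fit <- function(x, ...) {
  pr <- x$proteins[x$proteins$protein_accession %in% x$complete$retained, ,
                   drop = FALSE]
  if (!nrow(pr)) {
    warning("no complete-case proteins to plot")
    return(invisible(x))
  }
  conds <- sort(unique(pr$condition))
  cols <- grDevices::hcl.colors(max(3L, length(conds)), "Dark 3")[seq_along(conds)]
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  dens <- lapply(conds, function(cn) {
    stats::density(log2(pr$median_fsr[pr$condition == cn & pr$median_fsr > 0]))
  })
  xr <- range(sapply(dens, function(d) range(d$x)))
  yr <- range(sapply(dens, function(d) range(d$y)))
  plot(NA, xlim = xr, ylim = yr, xlab = "log2 protein FSR (%/h)",
       ylab = "density", main = "Protein FSR", ...)
  for (i in seq_along(conds)) graphics::lines(dens[[i]], col = cols[i], lwd = 2)
  graphics::legend("topright", legend = conds, col = cols, lwd = 2, bty = "n")
  graphics::boxplot(mixed_fsr ~ condition, data = x$mixed, col = cols,
                    xlab = "condition", ylab = "mixed-protein FSR (%/h)",
                    main = "Mixed FSR")
  invisible(x)
}

#' Mixed-protein FSR per sample
#'
#' The per-sample median FSR across complete-case proteins: one value per
#' condition and replicate, the experiment-level summary used to compare
#' global synthesis between conditions.
#'
#' @param fit A `"turnover_fit"`.
#' @return Data frame `condition`, `replicate`, `mixed_fsr`.
#' @export
mixed_fsr <- function(fit) {
  stopifnot(inherits(fit, "turnover_fit"))
  fit$mixed
}
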