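#' Classify ribosomal proteins from description text
#'
#' Case-insensitive substring matching on `"ribosom"` (so both "ribosome" and
#' "ribosomal" hit) selects candidate proteins; the subunit is then read from
#' the first `40S`/`60S`/`28S`/`39S` token in the description. 40S/60S imply
#' the cytosolic ribosome, 28S/39S the mitochondrial one. Candidates without a
#' subunit token (e.g. ribosome biogenesis factors) stay `unclassified` and
#' are excluded from subunit summaries.
#'
#' @param descriptions Data frame with `protein_accession` and `description`
#'   columns (see [read_description_table()]).
#' @param pattern Candidate-selection substring (default `"ribosom"`).
#' @return Data frame: `protein_accession`, `description`, `is_candidate`,
#'   `compartment` (`cytosolic`/`mitochondrial`/`unclassified`), `subunit`
#'   (`40S`/`60S`/`28S`/`39S`/`unclassified`).
#' @export
#' @examples
#' classify_ribosomal(data.frame(protein_accession = "P1",
#'                               description = "40S ribosomal protein S14"))
classify_ribosomal <- function(descriptions, pattern = "ribosom") {
  require_columns(descriptions, c("protein_accession", "description"),
                  "description table")
  desc <- descriptions$description
  if (any(is.na(desc) | !nzchar(desc))) stop("empty protein description")
  cand <- grepl(pattern, desc, ignore.case = TRUE)
  token <- rep(NA_character_, length(desc))
  hit <- regmatches(desc, regexpr("\\b(40S|60S|28S|39S)\\b", desc,
                                  ignore.case = TRUE))
  token[grepl("\\b(40S|60S|28S|39S)\\b", desc, ignore.case = TRUE)] <- toupper(hit)
  subunit <- ifelse(cand & !is.na(token), token, "unclassified")
  compartment <- rep("unclassified", length(desc))
  compartment[subunit %in% c("40S", "60S")] <- "cytosolic"
  compartment[subunit %in% c("28S", "39S")] <- "mitochondrial"
  data.frame(protein_accession = descriptions$protein_accession,
             description = desc, is_candidate = cand,
             compartment = compartment, subunit = subunit,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-replicate ribosomal subunit summaries
#'
#' For every classified subunit, condition and replicate, computes the median
#' FSR over member proteins and the total (summed) member abundance at the
#' end of the labeling window, then derives condition-level percent changes
#' versus control from the replicate means.
#'
#' @param fit A [turnover_fit()] object.
#' @param annotation Output of [classify_ribosomal()].
#' @param mat Optional normalized abundance matrix (defaults to the fit's).
#' @param control Control condition (default `"VC"`).
#' @param abundance_stat `"sum"` (default, "total abundance") or `"median"`.
#' @param time_h Abundance time point (default the fit's `t1`).
#' @return List with `summaries` (replicate-level: `subunit`, `condition`,
#'   `replicate`, `median_fsr`, `total_abundance`) and `changes`
#'   (condition-level percent change vs control for FSR and abundance).
#'   Subunits with zero classified members are omitted with a warning.
#' @export
subunit_summaries <- function(fit, annotation, mat = NULL, control = "VC",
                              abundance_stat = c("sum", "median"),
                              time_h = NULL) {
  stopifnot(inherits(fit, "turnover_fit"))
  abundance_stat <- match.arg(abundance_stat)
  if (is.null(mat)) mat <- fit$abundance
  if (is.null(time_h)) time_h <- fit$settings$t1
  members <- annotation[annotation$subunit != "unclassified", , drop = FALSE]
  subunits <- c("40S", "60S", "28S", "39S")
  present <- intersect(subunits, unique(members$subunit))
  if (!length(present)) {
    warning("no classified ribosomal subunit members")
    return(list(summaries = NULL, changes = NULL))
  }
  lab <- fit$design[fit$design$labeled, , drop = FALSE]
  cells <- unique(lab[, c("condition", "replicate")])
  cells <- cells[order(cells$condition, cells$replicate), , drop = FALSE]
  pr <- fit$proteins
  rows <- list()
  for (su in present) {
    accs <- members$protein_accession[members$subunit == su]
    for (i in seq_len(nrow(cells))) {
      cond <- cells$condition[i]; rp <- cells$replicate[i]
      fv <- pr$median_fsr[pr$protein_accession %in% accs &
                          pr$condition == cond & pr$replicate == rp]
      med <- if (length(fv)) stats::median(fv) else NA_real_
      tot <- NA_real_
      if (!is.null(mat)) {
        sid <- lab$sample_id[lab$condition == cond & lab$replicate == rp &
                             lab$time_h == time_h]
        if (length(sid) == 1L && sid %in% colnames(mat)) {
          av <- mat[rownames(mat) %in% accs, sid]
          av <- av[!is.na(av)]
          if (length(av)) {
            tot <- if (abundance_stat == "sum") sum(av) else stats::median(av)
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subunit = su, condition = cond, replicate = rp, median_fsr = med,
        total_abundance = tot, n_members = length(accs),
        stringsAsFactors = FALSE)
    }
  }
  summaries <- do.call(rbind, rows)
  rownames(summaries) <- NULL

  conds <- sort(unique(summaries$condition))
  trts <- setdiff(conds, control)
  chg <- list()
  for (su in present) {
    s <- summaries[summaries$subunit == su, , drop = FALSE]
    for (meas in c("median_fsr", "total_abundance")) {
      mc <- mean(s[[meas]][s$condition == control], na.rm = TRUE)
      for (trt in trts) {
        mt <- mean(s[[meas]][s$condition == trt], na.rm = TRUE)
        chg[[length(chg) + 1L]] <- data.frame(
          subunit = su, condition = trt,
          measure = if (meas == "median_fsr") "fsr" else "abundance",
          pct_change_vs_control = if (is.finite(mc) && mc != 0)
            100 * (mt - mc) / mc else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  changes <- do.call(rbind, chg)
  rownames(changes) <- NULL
  list(summaries = summaries, changes = changes)
}

#' Treatment contrasts on subunit summaries
#'
#' One-way ANOVA across conditions on the replicate-level subunit summaries
#' (median FSR and total abundance), with Tukey-adjusted pairwise p-values for
#' each treatment against control. The Tukey step is gated on the omnibus
#' p-value (default 0.05) but all pairwise results are reported with the gate
#' recorded.
#'
#' @param summaries Replicate-level data frame from [subunit_summaries()].
#' @param control Control condition (default `"VC"`).
#' @param gate_alpha Omnibus significance gate (default 0.05).
#' @return Data frame: `subunit`, `measure`, `f_stat`, `p_value`,
#'   `gate_passed`, `contrast`, `tukey_p`.
#' @export
subunit_contrasts <- function(summaries, control = "VC", gate_alpha = 0.05) {
  out <- list()
  for (su in unique(summaries$subunit)) {
    s <- summaries[summaries$subunit == su, , drop = FALSE]
    for (meas in c("median_fsr", "total_abundance")) {
      v <- s[[meas]]
      if (anyNA(v)) next
      a <- one_way_anova(v, s$condition)
      tk <- tukey_hsd(v, s$condition)
      want <- grepl(paste0("(^", control, "-)|(-", control, "$)"), tk$contrast)
      tk <- tk[want, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        subunit = su, measure = if (meas == "median_fsr") "fsr" else "abundance",
        f_stat = a$f_stat, p_value = a$p_value,
        gate_passed = a$p_value < gate_alpha,
        contrast = tk$contrast, diff = tk$diff, tukey_p = tk$p_adj,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no subunit with complete replicate summaries")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
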