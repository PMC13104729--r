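# Treatment-versus-control statistical layer on top of a turnover fit and an
# abundance matrix: per-protein one-way ANOVAs with Storey q-values, the
# condition x time interaction analysis with profile clustering, and the
# synthesis-abundance coupling correlations.

contrast_table <- function(values_long, design, treatments, control, label_suffix) {
  flt <- filter_complete_cases(values_long, design)
  dat <- flt$data
  res <- lapply(treatments, function(trt) {
    sub <- dat[dat$condition %in% c(trt, control), , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    chunks <- split(sub, sub$protein_accession)
    rows <- lapply(names(chunks)[order(names(chunks))], function(acc) {
      d <- chunks[[acc]]
      a <- one_way_anova(d$value, d$condition)
      mt <- mean(d$value[d$condition == trt])
      mc <- mean(d$value[d$condition == control])
      l2 <- if (mt > 0 && mc > 0) log2(mt / mc) else NA_real_
      data.frame(protein_accession = acc,
                 contrast = paste0(trt, "-vs-", control, label_suffix),
                 f_stat = a$f_stat, p_value = a$p_value,
                 log2_fc = l2,
                 direction = if (mt >= mc) "up" else "down",
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    # p = 0 (zero within-group variance) is clipped into (0,1] for the
    # q-value machinery
    pq <- pmax(out$p_value, .Machine$double.xmin)
    out$q_value <- as.numeric(storey_qvalues(pq))
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_complete") <- flt$n_retained
  out
}

#' Treatment-versus-control contrasts of protein synthesis rates
#'
#' For every protein quantified in the full condition x replicate grid, runs
#' an independent one-way ANOVA of each treatment against the control on the
#' per-replicate protein FSR values, attaches Storey q-values per contrast,
#' and reports the log2 fold change of mean FSR.
#'
#' @param fit A [turnover_fit()] object.
#' @param treatments Treatment condition names (default: all non-control
#'   conditions in the design).
#' @param control Control condition name (default `"VC"`).
#' @return Data frame with one row per protein x contrast: accession,
#'   contrast label, F, p, q, log2 fold change and direction. Attribute
#'   `"n_complete"` carries the complete-case protein count.
#' @export
fsr_contrasts <- function(fit, treatments = NULL, control = "VC") {
  stopifnot(inherits(fit, "turnover_fit"))
  conds <- unique(fit$design$condition[fit$design$labeled])
  if (!control %in% conds) stop("control condition not in design: ", control)
  if (is.null(treatments)) treatments <- setdiff(conds, control)
  long <- fit$proteins[, c("protein_accession", "condition", "replicate")]
  long$value <- fit$proteins$median_fsr
  contrast_table(long, fit$design, treatments, control, " FSR")
}

#' Treatment-versus-control contrasts of protein abundance
#'
#' Same procedure as [fsr_contrasts()] applied to normalized protein
#' abundances at one time point (default the end of the labeling window).
#'
#' @param mat Normalized abundance matrix.
#' @param design Design table.
#' @param time_h Time point at which abundances are compared (default 36).
#' @inheritParams fsr_contrasts
#' @return As [fsr_contrasts()].
#' @export
abundance_contrasts <- function(mat, design, treatments = NULL, control = "VC",
                                time_h = 36) {
  lab <- design[design$labeled & design$time_h == time_h, , drop = FALSE]
  conds <- unique(lab$condition)
  if (!control %in% conds) stop("control condition not in design: ", control)
  if (is.null(treatments)) treatments <- setdiff(conds, control)
  cols <- intersect(lab$sample_id, colnames(mat))
  li <- match(cols, lab$sample_id)
  long <- data.frame(
    protein_accession = rep(rownames(mat), times = length(cols)),
    condition = rep(lab$condition[li], each = nrow(mat)),
    replicate = rep(lab$replicate[li], each = nrow(mat)),
    value = as.vector(mat[, cols]),
    stringsAsFactors = FALSE)
  grid_design <- lab[li, , drop = FALSE]
  contrast_table(long, grid_design, treatments, control, " abundance")
}

#' Cluster standardized condition x time profiles
#'
#' Hierarchical clustering (Ward linkage on Euclidean distances) of per-protein
#' standardized mean-abundance profiles, cut at `k` groups. Rows are ordered by
#' accession before clustering so the partition is independent of input order;
#' cluster ids are relabeled by decreasing cluster size (ties broken by the
#' lexicographically smallest member accession).
#'
#' @param profiles Numeric matrix, proteins x condition-time cells, rownames
#'   are accessions. Each row is z-scored internally (constant rows map to 0).
#' @param k Number of clusters (`2 <= k <= nrow(profiles)`).
#' @return Data frame `protein_accession`, `cluster_id`, plus the z-scored
#'   profile columns.
#' @export
cluster_interaction_profiles <- function(profiles, k) {
  if (k < 2L) stop("k must be at least 2")
  if (k > nrow(profiles)) stop("k exceeds the number of profiles")
  if (is.null(rownames(profiles))) stop("profiles need accession rownames")
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  z <- t(apply(profiles, 1L, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  colnames(z) <- colnames(profiles)
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  size <- table(raw)
  first_acc <- tapply(rownames(z), raw, min)
  ord <- order(-as.integer(size), first_acc)
  relabel <- integer(length(size))
  relabel[as.integer(names(size))[ord]] <- seq_along(ord)
  out <- data.frame(protein_accession = rownames(z),
                    cluster_id = relabel[raw],
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, as.data.frame(z, row.names = NULL))
}

#' Condition x time interaction analysis with profile clustering
#'
#' Runs a balanced two-way ANOVA (condition, time, interaction) per
#' complete-case protein on normalized abundances, then clusters the
#' standardized condition x time mean profiles of interaction-significant
#' proteins into `k` groups.
#'
#' @param mat Normalized abundance matrix covering both time points.
#' @param design Design table.
#' @param k Number of clusters (default 5).
#' @param alpha Interaction significance gate (default 0.05).
#' @return List with `anova` (per-protein two-way results), `clusters`
#'   (assignments for interaction-significant proteins, `NULL` when fewer
#'   than `k` qualify), `n_significant` and `n_complete`.
#' @export
interaction_clusters <- function(mat, design, k = 5, alpha = 0.05) {
  lab <- design[design$labeled, , drop = FALSE]
  flt <- filter_complete_cases(mat, design)
  m <- flt$data[order(rownames(flt$data)), , drop = FALSE]
  cols <- intersect(lab$sample_id, colnames(m))
  li <- match(cols, lab$sample_id)
  cond <- lab$condition[li]; tm <- lab$time_h[li]
  res <- lapply(rownames(m), function(acc) {
    a <- two_way_anova(as.numeric(m[acc, cols]), cond, tm)
    data.frame(protein_accession = acc, f_condition = a$f_condition,
               f_time = a$f_time, f_interaction = a$f_interaction,
               p_condition = a$p_condition, p_time = a$p_time,
               p_interaction = a$p_interaction, stringsAsFactors = FALSE)
  })
  anova_df <- do.call(rbind, res)
  rownames(anova_df) <- NULL
  sig <- anova_df$protein_accession[anova_df$p_interaction < alpha]
  clusters <- NULL
  if (length(sig) >= k) {
    cell <- paste(cond, tm, sep = ".")
    cell_levels <- unique(cell[order(cond, tm)])
    prof <- t(apply(m[sig, cols, drop = FALSE], 1L, function(v) {
      as.numeric(tapply(v, cell, mean)[cell_levels])
    }))
    colnames(prof) <- cell_levels
    rownames(prof) <- sig
    clusters <- cluster_interaction_profiles(prof, k)
  }
  list(anova = anova_df, clusters = clusters, n_significant = length(sig),
       n_complete = flt$n_retained, k = k, alpha = alpha)
}

log2fc_by_protein <- function(values_long, treatment, control) {
  sub <- values_long[values_long$condition %in% c(treatment, control), ,
                     drop = FALSE]
  mt <- tapply(sub$value[sub$condition == treatment],
               sub$protein_accession[sub$condition == treatment], mean)
  mc <- tapply(sub$value[sub$condition == control],
               sub$protein_accession[sub$condition == control], mean)
  common <- intersect(names(mt), names(mc))
  x <- log2(as.numeric(mt[common]) / as.numeric(mc[common]))
  stats::setNames(x, common)
}

#' Correlation between synthesis and abundance responses
#'
#' For each treatment, correlates per-protein log2 fold changes (treatment /
#' control) in FSR against log2 fold changes in abundance at the end of the
#' labeling window, over proteins complete in both data sets.
#'
#' @param fit A [turnover_fit()] object (its normalized abundance matrix is
#'   used unless `mat` is supplied).
#' @param mat Optional normalized abundance matrix.
#' @inheritParams fsr_contrasts
#' @param time_h Abundance time point (default 36).
#' @return Data frame with one row per treatment: `contrast`, `r`,
#'   `r_squared`, `p_value`, `n`, `n_dropped`.
#' @export
synthesis_abundance_correlation <- function(fit, mat = NULL, treatments = NULL,
                                            control = "VC", time_h = 36) {
  stopifnot(inherits(fit, "turnover_fit"))
  if (is.null(mat)) mat <- fit$abundance
  if (is.null(mat)) stop("no abundance matrix available")
  conds <- unique(fit$design$condition[fit$design$labeled])
  if (is.null(treatments)) treatments <- setdiff(conds, control)
  fsr_long <- fit$proteins[, c("protein_accession", "condition", "replicate")]
  fsr_long$value <- fit$proteins$median_fsr
  fsr_long <- filter_complete_cases(fsr_long, fit$design)$data
  lab <- fit$design[fit$design$labeled & fit$design$time_h == time_h, ,
                    drop = FALSE]
  cols <- intersect(lab$sample_id, colnames(mat))
  li <- match(cols, lab$sample_id)
  ab_long <- data.frame(
    protein_accession = rep(rownames(mat), times = length(cols)),
    condition = rep(lab$condition[li], each = nrow(mat)),
    replicate = rep(lab$replicate[li], each = nrow(mat)),
    value = as.vector(mat[, cols]), stringsAsFactors = FALSE)
  ab_long <- ab_long[!is.na(ab_long$value), , drop = FALSE]
  rows <- lapply(treatments, function(trt) {
    x <- log2fc_by_protein(fsr_long, trt, control)
    y <- log2fc_by_protein(ab_long, trt, control)
    ct <- correlate_log2fc(x, y)
    data.frame(contrast = paste0(trt, "-vs-", control), r = ct$r,
               r_squared = ct$r_squared, p_value = ct$p_value, n = ct$n,
               n_dropped = ct$n_dropped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
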