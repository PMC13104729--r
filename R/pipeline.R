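# File-based pipeline: read tables -> turnover fit -> statistical layer,
# writing CSV outputs plus a deterministic JSON manifest (package version,
# config hash, input hashes, stage counts) so a rerun on identical inputs is
# byte-identical.

#' Pipeline configuration
#'
#' Collects file paths and analysis settings for [run_fsr()] and
#' [run_stats()]. Any setting omitted keeps its documented default.
#'
#' @param isotopomer,abundance,design,descriptions Input file paths
#'   (`abundance` and `descriptions` optional).
#' @param out_dir Output directory (created if absent).
#' @param dh_exp,dh_nat,t0,t1,ria_t0_mode,abundance_pairing Passed to
#'   [turnover_fit()].
#' @param control Control condition (default `"VC"`).
#' @param alpha Significance gate for downstream sets (default 0.05).
#' @param cluster_k Interaction-profile cluster count (default 5).
#' @param subunit_abundance `"sum"` or `"median"` (see [subunit_summaries()]).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(isotopomer, design, abundance = NULL,
                            descriptions = NULL, out_dir = ".",
                            dh_exp = 0.04, dh_nat = 1.5576e-4,
                            t0 = 12, t1 = 36,
                            ria_t0_mode = "control",
                            abundance_pairing = "replicate",
                            control = "VC", alpha = 0.05, cluster_k = 5,
                            subunit_abundance = "sum") {
  cfg <- list(isotopomer = isotopomer, design = design, abundance = abundance,
              descriptions = descriptions, out_dir = out_dir,
              dh_exp = dh_exp, dh_nat = dh_nat, t0 = t0, t1 = t1,
              ria_t0_mode = ria_t0_mode, abundance_pairing = abundance_pairing,
              control = control, alpha = alpha, cluster_k = cluster_k,
              subunit_abundance = subunit_abundance)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

input_hashes <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  hashes <- vapply(paths, function(p) unname(tools::md5sum(p)), character(1))
  as.list(hashes)
}

write_manifest <- function(path, config, stage, counts, inputs, outputs) {
  manifest <- list(
    tool = "proteoturn",
    version = as.character(utils::packageVersion("proteoturn")),
    stage = stage,
    config_hash = config_hash(config),
    inputs = input_hashes(inputs),
    outputs = as.list(outputs),
    counts = counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

require_input <- function(path, what) {
  if (is.null(path)) stop("pipeline config lacks a ", what, " path")
  if (!file.exists(path)) stop(what, " file not found: ", path)
  path
}

#' Run the kinetic stage of the pipeline
#'
#' Reads the isotopomer, abundance and design tables, fits two-point turnover
#' kinetics ([turnover_fit()]), applies complete-case filtering and writes
#' the peptide-kinetics table, the protein-FSR table, the mixed-FSR table and
#' a run manifest with stage counts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted `"turnover_fit"` and the output
#'   paths.
#' @export
run_fsr <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- read_design(require_input(config$design, "design"))
  iso <- read_isotopomer_table(require_input(config$isotopomer, "isotopomer"),
                               design)
  ab <- NULL
  if (!is.null(config$abundance)) {
    ab <- read_abundance_table(require_input(config$abundance, "abundance"),
                               design)
  }
  fit <- turnover_fit(iso, design, abundance = ab,
                      dh_exp = config$dh_exp, dh_nat = config$dh_nat,
                      t0 = config$t0, t1 = config$t1,
                      ria_t0_mode = config$ria_t0_mode,
                      abundance_pairing = config$abundance_pairing)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(peptides = file.path(config$out_dir, "peptide_kinetics.csv"),
             proteins = file.path(config$out_dir, "protein_fsr.csv"),
             mixed = file.path(config$out_dir, "mixed_fsr.csv"),
             manifest = file.path(config$out_dir, "manifest_fsr.json"))
  write_delim_precise(fit$peptides, paths["peptides"])
  prot <- fit$proteins
  prot$complete_case <- prot$protein_accession %in% fit$complete$retained
  write_delim_precise(prot, paths["proteins"])
  write_delim_precise(fit$mixed, paths["mixed"])
  if (!is.null(fit$abundance)) {
    paths <- c(paths, abundance_normalized =
                 file.path(config$out_dir, "abundance_normalized.csv"))
    write_abundance_table(fit$abundance, paths["abundance_normalized"])
  }
  write_manifest(paths["manifest"], config, "fsr", fit$counts,
                 list(isotopomer = config$isotopomer, design = config$design,
                      abundance = config$abundance),
                 basename(paths[names(paths) != "manifest"]))
  invisible(list(fit = fit, paths = paths))
}

#' Run the statistical stage of the pipeline
#'
#' On top of [run_fsr()] (re-run internally), computes the treatment-versus-
#' control FSR and abundance contrasts with Storey q-values, the condition x
#' time interaction analysis with profile clustering, the synthesis-abundance
#' correlations, and (when a description table is configured) ribosomal
#' subunit summaries and contrasts. All results are written as CSV plus a
#' manifest.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all result tables and output paths.
#' @export
run_stats <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage1 <- run_fsr(config)
  fit <- stage1$fit
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  paths <- character(0)

  res$fsr_contrasts <- fsr_contrasts(fit, control = config$control)
  paths["fsr_contrasts"] <- file.path(config$out_dir, "fsr_contrasts.csv")
  write_delim_precise(res$fsr_contrasts, paths["fsr_contrasts"])

  counts <- list(n_fsr_complete = attr(res$fsr_contrasts, "n_complete"))

  if (!is.null(fit$abundance)) {
    res$abundance_contrasts <- abundance_contrasts(
      fit$abundance, fit$design, control = config$control, time_h = config$t1)
    paths["abundance_contrasts"] <- file.path(config$out_dir,
                                              "abundance_contrasts.csv")
    write_delim_precise(res$abundance_contrasts, paths["abundance_contrasts"])
    counts$n_abundance_complete <- attr(res$abundance_contrasts, "n_complete")

    res$interaction <- interaction_clusters(fit$abundance, fit$design,
                                            k = config$cluster_k,
                                            alpha = config$alpha)
    paths["interaction_anova"] <- file.path(config$out_dir,
                                            "interaction_anova.csv")
    write_delim_precise(res$interaction$anova, paths["interaction_anova"])
    if (!is.null(res$interaction$clusters)) {
      paths["interaction_clusters"] <- file.path(config$out_dir,
                                                 "interaction_clusters.csv")
      write_delim_precise(res$interaction$clusters,
                          paths["interaction_clusters"])
    }
    counts$n_interaction_significant <- res$interaction$n_significant

    res$correlations <- synthesis_abundance_correlation(
      fit, control = config$control, time_h = config$t1)
    paths["correlations"] <- file.path(config$out_dir, "correlations.csv")
    write_delim_precise(res$correlations, paths["correlations"])
  }

  if (!is.null(config$descriptions)) {
    desc <- read_description_table(require_input(config$descriptions,
                                                 "description"))
    res$annotation <- classify_ribosomal(desc)
    paths["ribosome_annotation"] <- file.path(config$out_dir,
                                              "ribosome_annotation.csv")
    write_delim_precise(res$annotation, paths["ribosome_annotation"])
    su <- subunit_summaries(fit, res$annotation, control = config$control,
                            abundance_stat = config$subunit_abundance)
    res$subunit_summaries <- su$summaries
    res$subunit_changes <- su$changes
    if (!is.null(su$summaries)) {
      paths["subunit_summaries"] <- file.path(config$out_dir,
                                              "subunit_summaries.csv")
      write_delim_precise(su$summaries, paths["subunit_summaries"])
      paths["subunit_changes"] <- file.path(config$out_dir,
                                            "subunit_changes.csv")
      write_delim_precise(su$changes, paths["subunit_changes"])
      res$subunit_contrasts <- subunit_contrasts(su$summaries,
                                                 control = config$control,
                                                 gate_alpha = config$alpha)
      paths["subunit_contrasts"] <- file.path(config$out_dir,
                                              "subunit_contrasts.csv")
      write_delim_precise(res$subunit_contrasts, paths["subunit_contrasts"])
      counts$n_ribosomal_classified <-
        sum(res$annotation$subunit != "unclassified")
    }
  }

  paths["manifest"] <- file.path(config$out_dir, "manifest_stats.json")
  write_manifest(paths["manifest"], config, "stats",
                 c(fit$counts, counts),
                 list(isotopomer = config$isotopomer, design = config$design,
                      abundance = config$abundance,
                      descriptions = config$descriptions),
                 basename(paths[names(paths) != "manifest"]))
  invisible(list(fit = fit, results = res, paths = c(stage1$paths, paths)))
}
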