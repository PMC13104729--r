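# Ground-truth synthetic data generator. The forward model is the exact
# algebraic inverse of the two-point kinetic estimator, so that with noise
# switched off the pipeline must recover every true rate to numerical
# precision; multiplicative log-normal noise on isotopomer intensities and
# abundances then degrades recovery in a controlled, testable way.

AA_CODES <- c("A","C","D","E","F","G","H","I","K","L",
              "M","N","P","Q","R","S","T","V","W","Y")

# average m1:m0 contribution per residue of the natural isotope envelope,
# used to place each peptide's natural baseline RIA at a realistic value
# that grows with peptide length (~5 carbons + ~1.3 nitrogens per residue)
NATURAL_M1_PER_RESIDUE <- 0.0586

lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Configuration for the synthetic labeling experiment
#'
#' Defines the generative conditions: a 3-condition x 3-replicate x 2-time
#' design labeled with 4% D2O, protein turnover centered on a 0.88 %/h
#' baseline FSR with log-normal protein-to-protein spread, treatment FSR
#' effects concentrated in a ribosomal subset (1.8x by default), modest
#' ribosomal abundance gains, and multiplicative measurement noise on
#' isotopomer intensities and abundances.
#'
#' @param n_proteins Number of proteins.
#' @param peptides_per_protein Integer range (min, max) of peptides per
#'   protein, drawn uniformly.
#' @param baseline_fsr Median FSR (%/h) of the control proteome.
#' @param fsr_sigma Log-normal sdlog of protein-to-protein FSR spread.
#' @param ribosomal_fraction Proportion of proteins that are ribosomal.
#' @param subunit_probs Sampling probabilities of ribosomal subunits.
#' @param fsr_multipliers Named per-condition global FSR multipliers.
#' @param ribosomal_fsr_multipliers Extra per-condition multipliers applied to
#'   ribosomal proteins only.
#' @param abundance_baseline Range (fmol/ug) of protein baselines, drawn
#'   log-uniformly.
#' @param abundance_drift Multiplicative change of every protein's abundance
#'   across the labeling window (P(t1)/P(t0)); scalar.
#' @param abundance_multipliers,ribosomal_abundance_multipliers Named
#'   per-condition multipliers on abundance at the end of the window (global
#'   and ribosomal-specific).
#' @param abundance_cv Coefficient of variation of abundance measurement
#'   noise.
#' @param missing_rate Probability that a protein x sample abundance cell is
#'   missing.
#' @param intensity_cv Coefficient of variation of the multiplicative noise
#'   applied independently to m0 and m1.
#' @param intensity_scale,intensity_sigma Median and log-normal sdlog of
#'   per-peptide total intensity.
#' @param dh_exp,dh_nat Precursor D:H ratios.
#' @param t0,t1 Labeling window (hours).
#' @param conditions Condition names; the first is the control.
#' @param n_replicates Labeled replicates per condition.
#' @param n_control_replicates Unlabeled (H2O) control replicates per time
#'   point.
#' @param seed Integer seed; structure (sequences, membership, true rates)
#'   and measurement noise draw from separate streams derived from it, so
#'   noise re-runs preserve the proteome.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = 300,
                       peptides_per_protein = c(2L, 8L),
                       baseline_fsr = 0.88,
                       fsr_sigma = 0.5,
                       ribosomal_fraction = 0.05,
                       subunit_probs = c("40S" = 0.35, "60S" = 0.45,
                                         "28S" = 0.10, "39S" = 0.10),
                       fsr_multipliers = c(VC = 1, IBU = 1, PEA = 1),
                       ribosomal_fsr_multipliers = c(VC = 1, IBU = 1.8, PEA = 1.8),
                       abundance_baseline = c(5, 150),
                       abundance_drift = 1,
                       abundance_multipliers = c(VC = 1, IBU = 1, PEA = 1),
                       ribosomal_abundance_multipliers = c(VC = 1, IBU = 1.17,
                                                           PEA = 1.18),
                       abundance_cv = 0.05,
                       missing_rate = 0,
                       intensity_cv = 0.05,
                       intensity_scale = 1e6,
                       intensity_sigma = 1,
                       dh_exp = 0.04, dh_nat = 1.5576e-4,
                       t0 = 12, t1 = 36,
                       conditions = c("VC", "IBU", "PEA"),
                       n_replicates = 3L,
                       n_control_replicates = 3L,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              peptides_per_protein = as.integer(peptides_per_protein),
              baseline_fsr = baseline_fsr, fsr_sigma = fsr_sigma,
              ribosomal_fraction = ribosomal_fraction,
              subunit_probs = subunit_probs,
              fsr_multipliers = fsr_multipliers,
              ribosomal_fsr_multipliers = ribosomal_fsr_multipliers,
              abundance_baseline = abundance_baseline,
              abundance_drift = abundance_drift,
              abundance_multipliers = abundance_multipliers,
              ribosomal_abundance_multipliers = ribosomal_abundance_multipliers,
              abundance_cv = abundance_cv, missing_rate = missing_rate,
              intensity_cv = intensity_cv, intensity_scale = intensity_scale,
              intensity_sigma = intensity_sigma,
              dh_exp = dh_exp, dh_nat = dh_nat, t0 = t0, t1 = t1,
              conditions = conditions, n_replicates = as.integer(n_replicates),
              n_control_replicates = as.integer(n_control_replicates),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_proteins < 1L) stop("infeasible config: need at least one protein")
  if (length(cfg$peptides_per_protein) != 2L ||
      any(cfg$peptides_per_protein < 1L) ||
      cfg$peptides_per_protein[1L] > cfg$peptides_per_protein[2L]) {
    stop("peptides_per_protein must be an increasing positive range")
  }
  if (cfg$baseline_fsr <= 0 || cfg$fsr_sigma < 0) stop("invalid FSR parameters")
  if (cfg$ribosomal_fraction < 0 || cfg$ribosomal_fraction > 1) {
    stop("ribosomal_fraction must lie in [0, 1]")
  }
  for (nm in c("fsr_multipliers", "ribosomal_fsr_multipliers",
               "abundance_multipliers", "ribosomal_abundance_multipliers")) {
    v <- cfg[[nm]]
    if (!all(cfg$conditions %in% names(v)) || any(v <= 0)) {
      stop(nm, " must be positive and named for every condition")
    }
  }
  if (any(cfg$abundance_drift <= 0)) stop("abundance_drift must be positive")
  if (cfg$intensity_cv < 0 || cfg$abundance_cv < 0) stop("negative noise CV")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1) stop("invalid missing_rate")
  if (cfg$dh_nat < 0 || cfg$dh_exp < cfg$dh_nat || cfg$dh_exp >= 1) {
    stop("invalid precursor enrichment")
  }
  if (!(cfg$t1 > cfg$t0)) stop("invalid labeling window")
  invisible(cfg)
}

random_tryptic_sequences <- function(n, len_range = c(7L, 25L)) {
  lens <- sample(seq(len_range[1L], len_range[2L]), n, replace = TRUE)
  vapply(lens, function(L) {
    body <- sample(AA_CODES, L - 1L, replace = TRUE)
    paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
  }, character(1))
}

#' Generate the ground-truth proteome
#'
#' Draws protein identities (including a ribosomal subset whose descriptions
#' carry subunit tokens), true per-condition degradation rates, abundance
#' baselines and tryptic-like peptides with exchangeable-hydrogen counts and
#' natural baseline RIAs. Rate/abundance combinations that would drive the
#' end-of-window RIA to or past the plateau are re-drawn (bounded retries)
#' with a warning.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_truth"` with data frames `proteins`,
#'   `kinetics` (protein x condition true `k_deg`, FSR and abundance ratio)
#'   and `peptides`.
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  np <- config$n_proteins
  acc <- sprintf("SIMP%05d", seq_len(np))
  n_ribo <- round(config$ribosomal_fraction * np)
  is_ribo <- rep(FALSE, np)
  if (n_ribo > 0) is_ribo[sample.int(np, n_ribo)] <- TRUE
  subunit <- rep(NA_character_, np)
  if (n_ribo > 0) {
    subunit[is_ribo] <- sample(names(config$subunit_probs), n_ribo,
                               replace = TRUE, prob = config$subunit_probs)
  }
  description <- sprintf("Synthetic cytosolic protein %d", seq_len(np))
  ri <- which(is_ribo)
  for (i in seq_along(ri)) {
    su <- subunit[ri[i]]
    description[ri[i]] <- switch(su,
      "40S" = sprintf("40S ribosomal protein S%d", i),
      "60S" = sprintf("60S ribosomal protein L%d", i),
      "28S" = sprintf("28S ribosomal protein S%d, mitochondrial", i),
      "39S" = sprintf("39S ribosomal protein L%d, mitochondrial", i))
  }
  k_base <- stats::rlnorm(np, meanlog = log(config$baseline_fsr / 100),
                          sdlog = config$fsr_sigma)
  baseline_ab <- exp(stats::runif(np, log(config$abundance_baseline[1L]),
                                  log(config$abundance_baseline[2L])))

  # peptides
  npep <- sample(seq(config$peptides_per_protein[1L],
                     config$peptides_per_protein[2L]),
                 np, replace = TRUE)
  total <- sum(npep)
  seqs <- random_tryptic_sequences(total)
  for (tries in 1:20) {
    dup <- duplicated(seqs)
    if (!any(dup)) break
    seqs[dup] <- random_tryptic_sequences(sum(dup))
  }
  if (anyDuplicated(seqs)) stop("could not generate unique peptide sequences")
  pep_protein <- rep(acc, times = npep)
  pep_id <- paste0(pep_protein, "_p",
                   unlist(lapply(npep, seq_len), use.names = FALSE))
  n_ex <- count_exchangeable_hydrogens(seqs)
  lens <- nchar(seqs)
  m1m0 <- NATURAL_M1_PER_RESIDUE * lens *
    stats::rlnorm(total, meanlog = 0, sdlog = 0.05)
  ria_nat <- m1m0 / (1 + m1m0)
  intensity <- stats::rlnorm(total, meanlog = log(config$intensity_scale),
                             sdlog = config$intensity_sigma)

  conds <- config$conditions
  mult <- config$fsr_multipliers[conds]
  rmult <- config$ribosomal_fsr_multipliers[conds]
  amult <- config$abundance_multipliers[conds]
  armult <- config$ribosomal_abundance_multipliers[conds]
  eff <- outer(rep(1, np), mult)
  eff[is_ribo, ] <- sweep(eff[is_ribo, , drop = FALSE], 2L, rmult, `*`)
  k_true <- k_base * eff
  a_eff <- outer(rep(1, np), amult)
  a_eff[is_ribo, ] <- sweep(a_eff[is_ribo, , drop = FALSE], 2L, armult, `*`)
  a_ratio <- config$abundance_drift * a_eff   # P(t1)/P(t0), true

  # guard: the forward model needs (1 - exp(-k dt)) / a_ratio < 1
  dt <- config$t1 - config$t0
  n_redrawn <- 0L
  for (tries in 1:10) {
    bad <- which(rowSums((1 - exp(-k_true * dt)) / a_ratio >= 1) > 0)
    if (!length(bad)) break
    n_redrawn <- n_redrawn + length(bad)
    k_base[bad] <- stats::rlnorm(length(bad),
                                 meanlog = log(config$baseline_fsr / 100),
                                 sdlog = config$fsr_sigma)
    k_true <- k_base * eff
  }
  if (n_redrawn > 0L) {
    warning(n_redrawn, " rate draw(s) re-drawn: labeling would reach plateau")
  }
  if (any((1 - exp(-k_true * dt)) / a_ratio >= 1)) {
    stop("infeasible config: labeling reaches plateau for some proteins")
  }

  colnames(k_true) <- conds
  kin <- data.frame(protein_accession = rep(acc, times = length(conds)),
                    condition = rep(conds, each = np),
                    k_true = as.vector(k_true),
                    fsr_true = 100 * as.vector(k_true),
                    abundance_ratio_true = as.vector(a_ratio),
                    stringsAsFactors = FALSE)
  structure(list(
    proteins = data.frame(protein_accession = acc, description = description,
                          is_ribosomal = is_ribo, subunit = subunit,
                          k_base = k_base, abundance_baseline = baseline_ab,
                          stringsAsFactors = FALSE),
    kinetics = kin,
    peptides = data.frame(peptide_id = pep_id, protein_accession = pep_protein,
                          sequence = seqs, n_exchangeable = n_ex,
                          ria_nat = ria_nat, intensity = intensity,
                          stringsAsFactors = FALSE),
    config = config), class = "sim_truth")
}

sim_design <- function(config) {
  conds <- config$conditions
  lab <- expand.grid(replicate = seq_len(config$n_replicates),
                     condition = conds, time_h = c(config$t0, config$t1),
                     stringsAsFactors = FALSE)
  lab <- lab[order(lab$condition, lab$replicate, lab$time_h), , drop = FALSE]
  lab$labeled <- TRUE
  d <- lab
  if (config$n_control_replicates > 0L) {
    ctl <- expand.grid(replicate = seq_len(config$n_control_replicates),
                       condition = conds[1L], time_h = c(config$t0, config$t1),
                       stringsAsFactors = FALSE)
    ctl$labeled <- FALSE
    d <- rbind(lab, ctl)
  }
  d$sample_id <- sprintf("%s_R%d_T%02g%s", d$condition, d$replicate, d$time_h,
                         ifelse(d$labeled, "L", "U"))
  rownames(d) <- NULL
  d[, c("sample_id", "condition", "replicate", "time_h", "labeled")]
}

#' Simulate the peptide mass-isotopomer time course
#'
#' Emits one (peptide, sample) intensity pair per cell of the design. Labeled
#' end-of-window samples carry RIA values from the exact inverse of the
#' two-point kinetic model; start-of-window and unlabeled control samples sit
#' at the peptide's natural RIA. Intensities are
#' `m0 = S (1 - RIA)`, `m1 = S RIA` with independent multiplicative
#' log-normal noise of coefficient of variation `intensity_cv` on each
#' channel.
#'
#' @param truth A `"sim_truth"` from [simulate_proteome()].
#' @param config The same [sim_config()].
#' @return List with `isotopomer` (long data frame) and `design`.
#' @export
simulate_isotopomer <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  design <- sim_design(config)
  pep <- truth$peptides
  kin <- truth$kinetics
  dt <- config$t1 - config$t0
  plateau <- compute_ria_plateau(pep$ria_nat, pep$n_exchangeable,
                                 dh_exp = config$dh_exp, dh_nat = config$dh_nat)
  rows <- lapply(seq_len(nrow(design)), function(si) {
    s <- design[si, ]
    if (!s$labeled || s$time_h == config$t0) {
      ria <- pep$ria_nat
    } else {
      kk <- paste(pep$protein_accession, s$condition, sep = "\r")
      mk <- match(kk, paste(kin$protein_accession, kin$condition, sep = "\r"))
      k <- kin$k_true[mk]; a <- kin$abundance_ratio_true[mk]
      ria <- pep$ria_nat + (plateau - pep$ria_nat) * (1 - exp(-k * dt)) / a
    }
    data.frame(peptide_id = pep$peptide_id, sequence = pep$sequence,
               protein_accession = pep$protein_accession,
               sample_id = s$sample_id, time_h = s$time_h,
               ria_clean = ria, intensity = pep$intensity,
               stringsAsFactors = FALSE)
  })
  iso <- do.call(rbind, rows)
  set.seed(config$seed + 1000003L)
  iso$m0 <- iso$intensity * (1 - iso$ria_clean) *
    lnorm_noise(nrow(iso), config$intensity_cv)
  iso$m1 <- iso$intensity * iso$ria_clean *
    lnorm_noise(nrow(iso), config$intensity_cv)
  iso <- iso[, c("peptide_id", "sequence", "protein_accession", "sample_id",
                 "time_h", "m0", "m1")]
  rownames(iso) <- NULL
  list(isotopomer = iso, design = design)
}

#' Simulate the protein abundance matrix
#'
#' Protein abundances for every labeled sample: the baseline at the start of
#' the window and `baseline x drift x treatment multiplier` at its end, with
#' multiplicative log-normal measurement noise (`abundance_cv`) and optional
#' missingness.
#'
#' @inheritParams simulate_isotopomer
#' @return Numeric matrix proteins x labeled samples (attribute
#'   `normalized = FALSE`), with `NA` for missing cells.
#' @export
simulate_abundance <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  design <- sim_design(config)
  lab <- design[design$labeled, , drop = FALSE]
  pr <- truth$proteins
  kin <- truth$kinetics
  kkey <- paste(kin$protein_accession, kin$condition, sep = "\r")
  set.seed(config$seed + 2000003L)
  mat <- matrix(NA_real_, nrow(pr), nrow(lab),
                dimnames = list(pr$protein_accession, lab$sample_id))
  for (j in seq_len(nrow(lab))) {
    base <- pr$abundance_baseline
    if (lab$time_h[j] == config$t1) {
      mk <- match(paste(pr$protein_accession, lab$condition[j], sep = "\r"), kkey)
      base <- base * kin$abundance_ratio_true[mk]
    }
    mat[, j] <- base * lnorm_noise(nrow(pr), config$abundance_cv)
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(mat)) < config$missing_rate,
                   nrow(mat), ncol(mat))
    mat[drop] <- NA_real_
  }
  attr(mat, "normalized") <- FALSE
  mat
}

#' Simulate a complete labeling experiment
#'
#' Convenience wrapper producing all pipeline inputs (isotopomer, abundance,
#' design and description tables) plus the ground truth, optionally writing
#' them as CSV files.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes
#'   `isotopomer.csv`, `abundance.csv`, `design.csv`, `descriptions.csv`,
#'   `truth_proteins.csv`, `truth_kinetics.csv` and `truth_peptides.csv`.
#' @return (Invisibly when writing) a list with elements `isotopomer`,
#'   `abundance`, `design`, `descriptions`, `truth` and `paths`.
#' @export
simulate_dpp <- function(config, dir = NULL) {
  truth <- simulate_proteome(config)
  iso <- simulate_isotopomer(truth, config)
  ab <- simulate_abundance(truth, config)
  desc <- truth$proteins[, c("protein_accession", "description")]
  out <- list(isotopomer = iso$isotopomer, abundance = ab,
              design = iso$design, descriptions = desc, truth = truth,
              paths = NULL)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(isotopomer = file.path(dir, "isotopomer.csv"),
               abundance = file.path(dir, "abundance.csv"),
               design = file.path(dir, "design.csv"),
               descriptions = file.path(dir, "descriptions.csv"),
               truth_proteins = file.path(dir, "truth_proteins.csv"),
               truth_kinetics = file.path(dir, "truth_kinetics.csv"),
               truth_peptides = file.path(dir, "truth_peptides.csv"))
    write_isotopomer_table(iso$isotopomer, paths["isotopomer"])
    write_abundance_table(ab, paths["abundance"])
    write_design(iso$design, paths["design"])
    write_delim_precise(desc, paths["descriptions"])
    write_delim_precise(truth$proteins, paths["truth_proteins"])
    write_delim_precise(truth$kinetics, paths["truth_kinetics"])
    write_delim_precise(truth$peptides, paths["truth_peptides"])
    out$paths <- paths
    return(invisible(out))
  }
  out
}
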