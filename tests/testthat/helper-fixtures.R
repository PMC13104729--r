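# Shared fixture builders: everything is generated in code at test time.

noise_free_config <- function(n_proteins = 50, seed = 1L, ...) {
  sim_config(n_proteins = n_proteins, intensity_cv = 0, abundance_cv = 0,
             missing_rate = 0, seed = seed, ...)
}

null_effect_config <- function(n_proteins = 200, seed = 1L, ...) {
  sim_config(n_proteins = n_proteins,
             fsr_multipliers = c(VC = 1, IBU = 1, PEA = 1),
             ribosomal_fsr_multipliers = c(VC = 1, IBU = 1, PEA = 1),
             abundance_multipliers = c(VC = 1, IBU = 1, PEA = 1),
             ribosomal_abundance_multipliers = c(VC = 1, IBU = 1, PEA = 1),
             seed = seed, ...)
}

fit_simulated <- function(cfg, ...) {
  dat <- simulate_dpp(cfg)
  fit <- turnover_fit(dat$isotopomer, dat$design, abundance = dat$abundance, ...)
  list(dat = dat, fit = fit)
}

# condition-level recovered FSR (median across replicate-level protein
# medians) joined against the simulation truth
recovery_table <- function(dat, fit) {
  co <- coef(fit)
  kin <- dat$truth$kinetics
  est <- co[cbind(match(kin$protein_accession, rownames(co)),
                  match(kin$condition, colnames(co)))]
  npep <- table(dat$truth$peptides$protein_accession)
  data.frame(protein_accession = kin$protein_accession,
             condition = kin$condition, fsr_true = kin$fsr_true,
             fsr_est = est,
             n_peptides = as.integer(npep[kin$protein_accession]),
             rel_err = (est - kin$fsr_true) / kin$fsr_true,
             stringsAsFactors = FALSE)
}

# tiny hand-built design: 3 conditions x n replicates x 2 times (+ controls)
tiny_design <- function(conditions = c("VC", "IBU", "PEA"), n_rep = 3,
                        times = c(12, 36), n_control = 0) {
  lab <- expand.grid(replicate = seq_len(n_rep), condition = conditions,
                     time_h = times, stringsAsFactors = FALSE)
  lab$labeled <- TRUE
  d <- lab
  if (n_control > 0) {
    ctl <- expand.grid(replicate = seq_len(n_control),
                       condition = conditions[1], time_h = times,
                       stringsAsFactors = FALSE)
    ctl$labeled <- FALSE
    d <- rbind(lab, ctl)
  }
  d$sample_id <- sprintf("%s_R%d_T%g%s", d$condition, d$replicate, d$time_h,
                         ifelse(d$labeled, "L", "U"))
  d[, c("sample_id", "condition", "replicate", "time_h", "labeled")]
}
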