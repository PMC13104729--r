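test_that("description matching assigns compartments and subunits", {
  desc <- data.frame(
    protein_accession = paste0("P", 1:6),
    description = c("40S ribosomal protein S14",
                    "60S ribosomal protein L7a",
                    "39S ribosomal protein L28, mitochondrial",
                    "28S ribosomal protein S18b, mitochondrial",
                    "Ribosome biogenesis protein BOP1",
                    "Myosin light chain 1"),
    stringsAsFactors = FALSE)
  ann <- classify_ribosomal(desc)
  expect_equal(ann$subunit, c("40S", "60S", "39S", "28S",
                              "unclassified", "unclassified"))
  expect_equal(ann$compartment, c("cytosolic", "cytosolic", "mitochondrial",
                                  "mitochondrial", "unclassified",
                                  "unclassified"))
  expect_equal(ann$is_candidate, c(rep(TRUE, 5), FALSE))
  # pure function of the description: adding rows never changes earlier ones
  more <- rbind(desc, data.frame(protein_accession = "P7",
                                 description = "60S ribosomal protein L10"))
  ann2 <- classify_ribosomal(more)
  expect_identical(ann2[1:6, ], ann)
  # case-insensitive "ribosom" substring
  lower <- data.frame(protein_accession = "P8",
                      description = "40s RIBOSOMAL protein s3")
  expect_equal(classify_ribosomal(lower)$subunit, "40S")
})

test_that("subunit summaries aggregate members and scale as expected", {
  z <- fit_simulated(noise_free_config(n_proteins = 80, seed = 3,
                                       ribosomal_fraction = 0.3))
  ann <- classify_ribosomal(z$dat$descriptions)
  su <- subunit_summaries(z$fit, ann)
  s <- su$summaries
  expect_true(all(c("subunit", "condition", "replicate", "median_fsr",
                    "total_abundance") %in% names(s)))
  expect_true(all(s$total_abundance >= 0, na.rm = TRUE))
  # one-protein subunit: summary equals that protein's own values
  one <- ann[ann$subunit == "40S", ][1, ]
  ann1 <- ann
  ann1$subunit[ann1$protein_accession != one$protein_accession] <- "unclassified"
  su1 <- subunit_summaries(z$fit, ann1)
  pr <- z$fit$proteins
  mine <- pr[pr$protein_accession == one$protein_accession &
             pr$condition == "VC" & pr$replicate == 1, ]
  got <- su1$summaries[su1$summaries$condition == "VC" &
                       su1$summaries$replicate == 1, ]
  expect_equal(got$median_fsr, mine$median_fsr)
  # doubling member abundances doubles the total, leaves median FSR alone
  mat2 <- z$fit$abundance * 2
  attr(mat2, "normalized") <- TRUE
  su2 <- subunit_summaries(z$fit, ann, mat = mat2)
  expect_equal(su2$summaries$total_abundance, 2 * s$total_abundance)
  expect_equal(su2$summaries$median_fsr, s$median_fsr)
  # member order invariance
  ann_rev <- ann[rev(seq_len(nrow(ann))), ]
  su3 <- subunit_summaries(z$fit, ann_rev)
  expect_equal(su3$summaries$median_fsr, s$median_fsr)
})

test_that("identical replicate summaries give omnibus p = 1; planted effects are caught", {
  s <- expand.grid(condition = c("VC", "IBU", "PEA"), replicate = 1:3,
                   stringsAsFactors = FALSE)
  s$subunit <- "40S"; s$median_fsr <- 0.9; s$total_abundance <- 50
  sc <- subunit_contrasts(s)
  expect_true(all(sc$p_value == 1))
  expect_true(all(sc$tukey_p == 1))
  # strong planted effect (x3 FSR, zero noise) -> treatment Tukey p < 0.01
  cfg <- noise_free_config(n_proteins = 60, seed = 9, ribosomal_fraction = 0.3,
                           ribosomal_fsr_multipliers = c(VC = 1, IBU = 3, PEA = 3))
  z <- fit_simulated(cfg)
  ann <- classify_ribosomal(z$dat$descriptions)
  su <- subunit_summaries(z$fit, ann)
  sc2 <- subunit_contrasts(su$summaries)
  r <- sc2[sc2$subunit %in% c("40S", "60S") & sc2$measure == "fsr" &
           grepl("VC-", sc2$contrast), ]
  expect_true(all(r$tukey_p < 0.01))
  expect_true(all(r$diff < 0))  # VC minus treatment: increase under treatment
  # determinism: identical rerun gives byte-identical results
  z2 <- fit_simulated(cfg)
  su2 <- subunit_summaries(z2$fit, classify_ribosomal(z2$dat$descriptions))
  expect_identical(subunit_contrasts(su2$summaries), sc2)
})

test_that("with no treatment effect, subunit percent change centers on zero", {
  pcs <- c()
  for (s in 1:50) {
    cfg <- null_effect_config(n_proteins = 120, seed = 400 + s,
                              ribosomal_fraction = 0.25)
    z <- fit_simulated(cfg)
    ann <- classify_ribosomal(z$dat$descriptions)
    su <- subunit_summaries(z$fit, ann)
    ch <- su$changes
    pcs <- c(pcs, ch$pct_change_vs_control[ch$measure == "fsr" &
                                           ch$subunit %in% c("40S", "60S")])
  }
  expect_lt(abs(mean(pcs, na.rm = TRUE)), 5)
})
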