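test_that("RIA is m1 over summed isotopomers and rejects bad inputs", {
  expect_equal(compute_ria(100, 0), 0)
  expect_equal(compute_ria(50, 50), 0.5)
  expect_equal(compute_ria(80, 20), 0.2)
  expect_equal(compute_ria(c(80, 50), c(20, 50)), c(0.2, 0.5))
  expect_error(compute_ria(0, 0), "zero isotopomer signal")
  expect_error(compute_ria(-1, 5), "negative")
  set.seed(1)
  r <- compute_ria(runif(500, 0, 1e6), runif(500, 0, 1e6))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("plateau RIA collapses to baseline without sites or enrichment", {
  set.seed(2)
  r0 <- runif(1e4, 0, 0.95)
  expect_equal(compute_ria_plateau(r0, 0, dh_exp = 0.04), r0)
  n <- runif(1e4, 0, 60)
  expect_equal(compute_ria_plateau(r0, n, dh_exp = 0.02, dh_nat = 0.02), r0)
})

test_that("plateau RIA matches the closed form and is monotone in N and enrichment", {
  # independent hand evaluation: 1 - 1/(1/(1-0.2) + 10*0.04) = 1 - 1/1.65
  expect_equal(compute_ria_plateau(0.2, 10, dh_exp = 0.04, dh_nat = 0),
               1 - 1 / (1.25 + 0.4))
  expect_equal(compute_ria_plateau(0.2, 10, dh_exp = 0.04, dh_nat = 0),
               0.393939393939394, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:50) {
    r0 <- runif(1, 0, 0.9)
    ns <- sort(runif(20, 0, 80))
    pl <- compute_ria_plateau(r0, ns)
    expect_true(all(diff(pl) >= 0))       # non-decreasing in N
    expect_true(all(pl >= r0 & pl < 1))
    ex <- sort(runif(20, 1.5576e-4, 0.2))
    pl2 <- vapply(ex, function(e) compute_ria_plateau(r0, 30, dh_exp = e),
                  numeric(1))
    expect_true(all(diff(pl2) >= 0))      # non-decreasing in enrichment
  }
  expect_error(compute_ria_plateau(1, 10), "degenerate baseline")
  expect_error(compute_ria_plateau(0.2, 10, dh_exp = 0.01, dh_nat = 0.02),
               "enrichment")
})

test_that("k_deg matches the simple rise-to-plateau form when abundance is stable", {
  # hand evaluation: f = 0.5, Delta t = 24 h -> -ln(0.5)/24
  kd <- compute_kdeg(ria_t0 = 0.1, ria_t1 = 0.3, ria_plateau = 0.5,
                     t0 = 12, t1 = 36)
  expect_true(kd$valid)
  expect_equal(kd$k_deg, -log(0.5) / 24)
  expect_equal(kd$k_deg, 0.028881132523331, tolerance = 1e-10)
  expect_equal(compute_fsr(kd$k_deg), 2.8881132523331, tolerance = 1e-10)
  # no incorporation -> zero rate
  kd0 <- compute_kdeg(0.3, 0.3, 0.6)
  expect_equal(kd0$k_deg, 0)
  # general agreement with -ln(1-f)/dt at abundance_ratio 1
  set.seed(4)
  for (i in 1:200) {
    r0 <- runif(1, 0, 0.5); pl <- r0 + runif(1, 0.05, 0.4)
    f <- runif(1, 0, 0.99)
    r1 <- r0 + f * (pl - r0)
    kd <- compute_kdeg(r0, r1, pl, t0 = 0, t1 = 24)
    expect_equal(kd$k_deg, -log(1 - f) / 24, tolerance = 1e-10)
  }
})

test_that("k_deg domain violations are flagged, not silently imputed", {
  kd <- compute_kdeg(0.2, 0.5, 0.6, abundance_ratio = 2)  # f*A = 1.5
  expect_false(kd$valid)
  expect_equal(kd$reason, "labeling at/above plateau")
  expect_true(is.na(kd$k_deg))
  kd2 <- compute_kdeg(0.3, 0.2, 0.6)
  expect_equal(kd2$reason, "RIA decreased")
  expect_error(compute_kdeg(0.5, 0.6, 0.4), "no labeling headroom")
  expect_error(compute_kdeg(0.1, 0.2, 0.5, t0 = 36, t1 = 12), "window")
  expect_error(compute_kdeg(0.1, 0.2, 0.5, abundance_ratio = -1), "positive")
  expect_error(compute_fsr(-0.1), "negative")
})

test_that("forward-inverse round trip recovers k_deg to 1e-10 relative error", {
  set.seed(5)
  for (i in 1:500) {
    r0 <- runif(1, 0, 0.6)
    pl <- r0 + runif(1, 0.05, 0.35)
    k <- exp(runif(1, log(1e-4), log(0.08)))
    a <- exp(runif(1, log(0.7), log(1.4)))
    dt <- 24
    fa <- 1 - exp(-k * dt)
    if (fa / a >= 1) next
    r1 <- r0 + (pl - r0) * fa / a      # inverse model
    kd <- compute_kdeg(r0, r1, pl, t0 = 12, t1 = 36, abundance_ratio = a)
    expect_true(kd$valid)
    expect_equal(kd$k_deg, k, tolerance = 1e-10)
  }
})

test_that("protein FSR is the median over peptides with support count", {
  expect_equal(protein_fsr(1), list(median_fsr = 1, n_peptides = 1L))
  expect_equal(protein_fsr(c(1, 3, 100)),
               list(median_fsr = 3, n_peptides = 3L))
  expect_equal(protein_fsr(c(1, 2, 3, 4)),
               list(median_fsr = 2.5, n_peptides = 4L))
  expect_error(protein_fsr(numeric(0)), "no valid peptides")
  expect_error(protein_fsr(NA_real_), "no valid peptides")
  # brute-force sort-and-pick oracle
  oracle_median <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  set.seed(6)
  for (i in 1:100) {
    x <- rlnorm(sample(1:50, 1))
    got <- protein_fsr(x)
    expect_identical(got$median_fsr, oracle_median(x))
    expect_identical(got$n_peptides, length(x))
  }
})

test_that("exchangeable hydrogen counts sum per-residue table values", {
  tab <- read_exchangeable_table()
  expect_true(all(c(LETTERS[1:1]) %in% names(tab) ||
                  all(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]] %in% names(tab))))
  expect_equal(count_exchangeable_hydrogens("G", tab), unname(tab[["G"]]))
  expect_equal(count_exchangeable_hydrogens("GG", tab), 2 * unname(tab[["G"]]))
  # independent per-character lookup-and-sum oracle over the same CSV file
  csv <- read.csv(system.file("extdata", "exchangeable_hydrogens.csv",
                              package = "proteoturn"))
  oracle <- function(s) {
    total <- 0
    for (ch in strsplit(s, "")[[1]]) {
      total <- total + csv$n_exchangeable[csv$residue == ch]
    }
    total
  }
  for (s in c("AGK", "PEPTIDER", "WYSTVHK")) {
    expect_equal(count_exchangeable_hydrogens(s, tab), oracle(s))
  }
  expect_error(count_exchangeable_hydrogens("", tab), "empty peptide")
  expect_error(count_exchangeable_hydrogens("AXZ", tab), "X")
})
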