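test_that("pure scaling between samples is removed exactly", {
  set.seed(20)
  a <- rlnorm(50, 3)
  mat <- cbind(A = a, B = 2 * a, C = a)
  attr(mat, "normalized") <- FALSE
  rownames(mat) <- sprintf("P%02d", 1:50)
  out <- normalize_intersample(mat)
  f <- attr(out, "scaling_factors")
  expect_equal(unname(f[["B"]]), 0.5)
  expect_equal(out[, "A"], out[, "B"])
  expect_equal(out[, "A"], out[, "C"])
  # already-equal samples: all factors 1
  mat2 <- cbind(A = a, B = a)
  attr(mat2, "normalized") <- FALSE
  rownames(mat2) <- rownames(mat)
  expect_true(all(attr(normalize_intersample(mat2), "scaling_factors") == 1))
})

test_that("normalization drives every sample's median ratio to 1 and is idempotent", {
  set.seed(21)
  mat <- matrix(rlnorm(200 * 8, 3, 1), 200,
                dimnames = list(sprintf("P%03d", 1:200), paste0("S", 1:8)))
  mat <- sweep(mat, 2, exp(runif(8, -1, 1)), `*`)   # sample loading biases
  attr(mat, "normalized") <- FALSE
  out <- normalize_intersample(mat)
  ref <- attr(out, "reference_sample")
  for (j in colnames(out)) {
    expect_equal(median(out[, j] / out[, ref]), 1, tolerance = 1e-12)
  }
  expect_error(normalize_intersample(out), "already normalized")
  # idempotency: when samples share one profile up to scaling (the structure
  # the factors model), a second pass is an exact no-op
  a <- rlnorm(100, 3)
  pure <- sapply(exp(runif(6, -1, 1)), function(f) f * a)
  rownames(pure) <- sprintf("P%03d", 1:100); colnames(pure) <- paste0("S", 1:6)
  attr(pure, "normalized") <- FALSE
  p1 <- normalize_intersample(pure)
  p2 <- p1
  attr(p2, "normalized") <- FALSE
  f2 <- attr(normalize_intersample(p2), "scaling_factors")
  expect_equal(unname(f2), rep(1, 6), tolerance = 1e-12)
})

test_that("a sample sharing no nonzero proteins with the reference errors", {
  mat <- cbind(A = c(1, 2, 3, 4), B = c(1.1, 2.2, 3.1, 4.2),
               C = c(0, 0, 0, NA))
  rownames(mat) <- paste0("P", 1:4)
  attr(mat, "normalized") <- FALSE
  expect_error(normalize_intersample(mat), "positive|nonzero")
})

test_that("complete-case filtering matches a brute-force all-cells scan", {
  d <- tiny_design()
  lab <- d[d$labeled, ]
  set.seed(22)
  n <- 500
  mat <- matrix(rlnorm(n * nrow(lab)), n,
                dimnames = list(sprintf("P%03d", 1:n), lab$sample_id))
  mat[runif(length(mat)) < 0.10] <- NA
  attr(mat, "normalized") <- FALSE
  got <- filter_complete_cases(mat, d)
  # brute force: scan every protein x sample cell
  keep <- character(0)
  for (i in rownames(mat)) {
    all_there <- TRUE
    for (j in lab$sample_id) if (is.na(mat[i, j])) all_there <- FALSE
    if (all_there) keep <- c(keep, i)
  }
  expect_identical(got$retained, sort(keep))
  expect_identical(got$n_retained, length(keep))
  # never increases row count; order-invariant
  perm <- sample(nrow(mat))
  got2 <- filter_complete_cases(mat[perm, ], d)
  expect_identical(got2$retained, got$retained)
  expect_lte(got$n_retained, nrow(mat))
})

test_that("long-format filtering keeps only full condition x replicate grids", {
  d <- tiny_design()
  lab <- unique(d[d$labeled, c("condition", "replicate")])
  long <- do.call(rbind, lapply(c("P1", "P2"), function(acc) {
    data.frame(protein_accession = acc, condition = lab$condition,
               replicate = lab$replicate, value = 1)
  }))
  long$value[long$protein_accession == "P2" &
             long$condition == "IBU" & long$replicate == 2] <- NA
  got <- filter_complete_cases(long, d)
  expect_identical(got$retained, "P1")
  expect_identical(got$n_retained, 1L)
})

test_that("abundance ratios pair replicates across the window", {
  d <- tiny_design()
  lab <- d[d$labeled, ]
  set.seed(23)
  base <- rlnorm(20, 3)
  mat <- sapply(lab$sample_id, function(s) {
    i <- match(s, lab$sample_id)
    base * if (lab$time_h[i] == 36) 1.25 else 1
  })
  rownames(mat) <- sprintf("P%02d", 1:20)
  attr(mat, "normalized") <- TRUE
  rt <- abundance_ratio_table(mat, d)
  expect_equal(unique(round(rt$abundance_ratio, 12)), 1.25)
  rt2 <- abundance_ratio_table(mat, d, pairing = "condition_mean")
  expect_equal(unique(round(rt2$abundance_ratio, 12)), 1.25)
  # missing abundance -> NA ratio
  mat[1, 1] <- NA
  rt3 <- abundance_ratio_table(mat, d)
  cell <- rt3[rt3$protein_accession == "P01" &
              paste0(rt3$condition, "_R", rt3$replicate) ==
              sub("_T.*", "", colnames(mat)[1]), ]
  expect_true(anyNA(cell$abundance_ratio))
})
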