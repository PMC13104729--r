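test_that("one-way ANOVA reduces to t-squared for two groups", {
  set.seed(30)
  for (i in 1:50) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), mean = runif(1))
    a <- one_way_anova(c(x, y), rep(c("a", "b"), c(length(x), length(y))))
    # independently coded pooled-variance t statistic
    sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
      (length(x) + length(y) - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    expect_equal(a$f_stat, tstat^2, tolerance = 1e-10)
    expect_equal(a$p_value,
                 2 * pt(abs(tstat), length(x) + length(y) - 2, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("one-way ANOVA handles degenerate variance structure explicitly", {
  a <- one_way_anova(c(1, 2, 3, 3, 1, 2), rep(c("a", "b"), each = 3))
  expect_equal(a$f_stat, 0)
  expect_equal(a$p_value, 1)
  b <- one_way_anova(c(1, 1, 2, 2), rep(c("a", "b"), each = 2))
  expect_equal(b$p_value, 0)
  expect_error(one_way_anova(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("one-way ANOVA p agrees with a permutation oracle", {
  set.seed(31)
  vals <- c(rnorm(5), rnorm(5, 0.8), rnorm(5, 0.3))
  grp <- rep(c("a", "b", "c"), each = 5)
  a <- one_way_anova(vals, grp)
  fstat <- function(v) {
    m <- tapply(v, grp, mean); n <- tapply(v, grp, length)
    ssb <- sum(n * (m - mean(v))^2)
    ssw <- sum((v - m[grp])^2)
    (ssb / 2) / (ssw / 12)
  }
  perm <- replicate(10000, fstat(sample(vals)))
  p_perm <- mean(perm >= a$f_stat - 1e-12)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / 10000)
  expect_lt(abs(a$p_value - p_perm), 4 * mc_sd + 0.01)
})

test_that("Storey q-values reduce to BH under pi0 = 1 and behave under the null", {
  expect_equal(as.numeric(storey_qvalues(rep(1, 20))), rep(1, 20))
  set.seed(32)
  p <- runif(100)
  q <- storey_qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q), p.adjust(p, "BH"), tolerance = 1e-12)
  # pi0 estimated on uniform p-values is near 1
  p2 <- runif(10000)
  q2 <- storey_qvalues(p2)
  expect_gte(attr(q2, "pi0"), 0.9)
  expect_lte(attr(q2, "pi0"), 1.0)
  # q monotone in sorted p, bounded by 1
  o <- order(p2)
  expect_true(all(diff(as.numeric(q2)[o]) >= -1e-15))
  expect_lte(max(q2), 1)
  expect_error(storey_qvalues(c(0.5, 0)), "\\(0, 1\\]")
  # < 10 p-values falls back to pi0 = 1 (BH)
  p3 <- runif(5)
  expect_equal(as.numeric(storey_qvalues(p3)), p.adjust(p3, "BH"))
})

test_that("two-way ANOVA matches a direct sum-of-squares oracle", {
  ss_oracle <- function(y, cf, tf) {
    # balanced decomposition from cell/margin/grand means
    n <- length(y); gm <- mean(y)
    mc <- tapply(y, cf, mean); mt <- tapply(y, tf, mean)
    mct <- tapply(y, list(cf, tf), mean)
    nc <- table(cf)[1]; nt <- table(tf)[1]; nct <- table(cf, tf)[1]
    ssa <- sum(table(cf) * (mc - gm)^2)
    ssb <- sum(table(tf) * (mt - gm)^2)
    sscells <- sum(table(cf, tf) * (mct - gm)^2)
    ssab <- sscells - ssa - ssb
    sse <- sum((y - mct[cbind(cf, tf)])^2)
    dfa <- nlevels(factor(cf)) - 1; dfb <- nlevels(factor(tf)) - 1
    dfab <- dfa * dfb; dfe <- n - nlevels(factor(cf)) * nlevels(factor(tf))
    f <- c(ssa / dfa, ssb / dfb, ssab / dfab) / (sse / dfe)
    list(f = f, p = pf(f, c(dfa, dfb, dfab), dfe, lower.tail = FALSE))
  }
  set.seed(33)
  for (i in 1:30) {
    cf <- rep(c("VC", "IBU", "PEA"), each = 6)
    tf <- rep(rep(c(12, 36), each = 3), 3)
    y <- rnorm(18, mean = as.numeric(factor(cf)) + 0.3 * (tf == 36))
    a <- two_way_anova(y, cf, tf)
    o <- ss_oracle(y, factor(cf), factor(tf))
    expect_equal(c(a$f_condition, a$f_time, a$f_interaction), unname(o$f),
                 tolerance = 1e-10)
    expect_equal(c(a$p_condition, a$p_time, a$p_interaction), unname(o$p),
                 tolerance = 1e-10)
  }
  # identical cell means -> all F = 0, p = 1
  y0 <- rep(rep(c(5, 5, 5), each = 6), 1) + rep(c(-1, 0, 1), 6)
  cf <- rep(c("a", "b", "c"), each = 6); tf <- rep(rep(c(1, 2), each = 3), 3)
  y0 <- rep(0, 18) + rep(c(-1, 0, 1), 6)
  a0 <- two_way_anova(y0, cf, tf)
  expect_equal(a0$p_condition, 1)
  expect_equal(a0$p_interaction, 1)
  expect_error(two_way_anova(y0[-1], cf[-1], tf[-1]), "unbalanced")
})

test_that("interaction p-values are uniform under an additive truth", {
  set.seed(34)
  cf <- rep(c("VC", "IBU", "PEA"), each = 8)
  tf <- rep(rep(c(12, 36), each = 4), 3)
  p <- replicate(2000, {
    y <- rnorm(24, mean = as.numeric(factor(cf)) * 0.5 + 0.4 * (tf == 36))
    two_way_anova(y, cf, tf)$p_interaction
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("Tukey HSD dominates pairwise t and collapses correctly", {
  # identical groups -> adjusted p = 1
  tk <- tukey_hsd(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(tk$p_adj == 1))
  set.seed(35)
  for (i in 1:100) {
    y <- rnorm(9, mean = rep(runif(3, 0, 1), each = 3))
    g <- rep(c("a", "b", "c"), each = 3)
    tk <- tukey_hsd(y, g)
    mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / 6
    means <- tapply(y, g, mean)
    for (j in seq_len(nrow(tk))) {
      pair <- strsplit(tk$contrast[j], "-")[[1]]
      # unadjusted pairwise pooled-t p on the shared ANOVA error df
      tstat <- (means[pair[1]] - means[pair[2]]) / sqrt(mse * (2 / 3))
      p_unadj <- 2 * pt(abs(tstat), 6, lower.tail = FALSE)
      expect_gte(tk$p_adj[j] + 1e-12, p_unadj)
    }
  }
  # with 2 groups the studentized range collapses to the pooled t test
  for (i in 1:20) {
    y <- rnorm(10, mean = rep(c(0, runif(1)), each = 5))
    g <- rep(c("a", "b"), each = 5)
    tk2 <- tukey_hsd(y, g)
    expect_lt(abs(tk2$p_adj - t.test(y ~ g, var.equal = TRUE)$p.value), 1e-8)
  }
})

test_that("Pearson correlation matches its definitional computation", {
  x <- setNames(rnorm(10), paste0("P", 1:10))
  expect_equal(correlate_log2fc(x, x)$r, 1)
  expect_equal(correlate_log2fc(x, -x)$r, -1)
  expect_equal(correlate_log2fc(x, -x)$r_squared, 1)
  set.seed(36)
  x <- rnorm(1000); y <- 0.4 * x + rnorm(1000)
  names(x) <- names(y) <- sprintf("P%04d", 1:1000)
  got <- correlate_log2fc(x, y)
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_def, tolerance = 1e-12)
  expect_equal(got$r_squared, r_def^2, tolerance = 1e-12)
  expect_identical(got$n, 1000L)
  # non-finite pairs dropped with count
  y[3] <- NA; x[5] <- Inf
  got2 <- correlate_log2fc(x, y)
  expect_identical(got2$n_dropped, 2L)
  expect_identical(got2$n, 998L)
  expect_error(correlate_log2fc(setNames(rep(1, 5), letters[1:5]),
                                setNames(rnorm(5), letters[1:5])),
               "zero variance")
})

test_that("profile clustering recovers planted partitions deterministically", {
  set.seed(37)
  n <- 30
  prof <- rbind(
    matrix(rnorm(n * 6, mean = rep(c(2, 2, 2, -2, -2, -2), each = n), sd = 0.2), n),
    matrix(rnorm(n * 6, mean = rep(c(-2, -2, -2, 2, 2, 2), each = n), sd = 0.2), n))
  rownames(prof) <- sprintf("P%03d", 1:(2 * n))
  got <- cluster_interaction_profiles(prof, k = 2)
  truth <- rep(1:2, each = n)
  tab <- table(got$cluster_id[match(sprintf("P%03d", 1:(2 * n)),
                                    got$protein_accession)], truth)
  expect_equal(sum(apply(tab, 1, max)), 2 * n)  # perfect recovery up to labels
  # permuting row order leaves the partition unchanged
  perm <- sample(nrow(prof))
  got2 <- cluster_interaction_profiles(prof[perm, ], k = 2)
  expect_identical(got[order(got$protein_accession), ],
                   got2[order(got2$protein_accession), ])
  # k = n gives singletons; invalid k errors
  got3 <- cluster_interaction_profiles(prof[1:5, ], k = 5)
  expect_identical(sort(got3$cluster_id), 1:5)
  expect_error(cluster_interaction_profiles(prof[1:3, ], k = 4), "exceeds")
  expect_error(cluster_interaction_profiles(prof, k = 1), "at least 2")
})
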