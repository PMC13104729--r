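#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA computed through [stats::lm()]/[stats::anova()].
#' With two groups the F statistic equals the square of the pooled-variance t
#' statistic. Degenerate inputs are resolved explicitly: zero between-group
#' and zero within-group variance gives `F = 0, p = 1`; zero within-group
#' variance with distinct means gives `F = Inf, p = 0`.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor); every group needs >= 2
#'   values.
#' @return List with `f_stat`, `p_value`, `df` (numerator, denominator).
#' @export
one_way_anova <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 values")
  if (anyNA(values)) stop("missing values in ANOVA input")
  an <- suppressWarnings(stats::anova(stats::lm(values ~ g)))
  ssb <- an$`Sum Sq`[1L]; ssw <- an$`Sum Sq`[2L]
  f <- an$`F value`[1L]; p <- an$`Pr(>F)`[1L]
  # degenerate variance structure, judged relative to the data's scale so
  # that rounding residue (~1e-30) from constant inputs is treated as zero
  tot <- ssb + ssw
  eps <- 1e-20 * (1 + mean(values)^2) * length(values)
  if (tot <= eps) {
    f <- 0; p <- 1
  } else if (ssw <= 1e-12 * tot) {
    f <- Inf; p <- 0
  }
  list(f_stat = f, p_value = p, df = c(an$Df[1L], an$Df[2L]))
}

#' Storey q-values with smoother-based pi0 estimation
#'
#' Estimates the null proportion pi0 on a lambda grid via
#' `mean(p > lambda) / (1 - lambda)`, smooths it with a cubic smoothing spline
#' (df = 3) and extrapolates to lambda = 1, clipping to (0, 1]. Q-values are
#' then `pi0 * m * p / rank(p)` made monotone from the largest p downward.
#' With fewer than 10 p-values (or `pi0 = 1`) the procedure reduces exactly to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p P-values in (0, 1].
#' @param lambda Grid for pi0 estimation (default 0.05 to 0.95 by 0.05).
#' @param pi0 Optional fixed pi0 overriding estimation.
#' @return Numeric vector of q-values with attribute `"pi0"`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  if (anyNA(p) || any(p <= 0) || any(p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 10L) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = 1)$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  }
  r <- rank(p, ties.method = "max")
  q <- pi0 * m * p / r
  o <- order(p, decreasing = TRUE)
  q[o] <- cummin(q[o])
  q <- pmin(q, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Balanced two-way fixed-effects ANOVA with interaction
#'
#' Condition x time ANOVA on a balanced design (the labeling experiment's
#' 3 conditions x 2 time points x n replicates), via the standard balanced
#' sum-of-squares decomposition as computed by [stats::lm()]/[stats::anova()].
#'
#' @param values Numeric response.
#' @param condition,time Cell factors (coerced); every condition x time cell
#'   must contain the same number (>= 2) of replicates.
#' @return List with per-effect F statistics and p-values:
#'   `f_condition`, `f_time`, `f_interaction`, `p_condition`, `p_time`,
#'   `p_interaction`.
#' @export
two_way_anova <- function(values, condition, time) {
  cf <- factor(condition); tf <- factor(time)
  if (anyNA(values)) stop("missing values in ANOVA input")
  counts <- table(cf, tf)
  if (any(counts < 2L)) stop("every condition x time cell needs >= 2 replicates")
  if (length(unique(as.vector(counts))) != 1L) {
    stop("unbalanced design: cell counts differ")
  }
  an <- suppressWarnings(stats::anova(stats::lm(values ~ cf * tf)))
  ss <- an$`Sum Sq`; f <- an$`F value`; p <- an$`Pr(>F)`
  if (ss[4L] == 0) {
    fix <- function(i) if (ss[i] == 0) c(0, 1) else c(Inf, 0)
    for (i in 1:3) { z <- fix(i); f[i] <- z[1L]; p[i] <- z[2L] }
  }
  list(f_condition = f[1L], f_time = f[2L], f_interaction = f[3L],
       p_condition = p[1L], p_time = p[2L], p_interaction = p[3L])
}

#' Tukey honestly-significant-difference post hoc test
#'
#' Studentized-range adjusted pairwise comparisons via [stats::TukeyHSD()].
#' Identical groups short-circuit to adjusted p = 1 for all pairs.
#'
#' @inheritParams one_way_anova
#' @return Data frame with `contrast` (e.g. `"IBU-VC"`), `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 values")
  means <- tapply(values, g, mean)
  ssw <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2L)
  if (ssw == 0 && all(abs(means - means[1L]) == 0)) {
    return(data.frame(contrast = paste(pairs[2L, ], pairs[1L, ], sep = "-"),
                      diff = 0, lwr = 0, upr = 0, p_adj = 1,
                      stringsAsFactors = FALSE))
  }
  tk <- stats::TukeyHSD(stats::aov(values ~ g))$g
  data.frame(contrast = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlation of paired log2 fold changes
#'
#' Pairs two per-protein log2 fold-change vectors by name, drops non-finite
#' pairs (reporting the count) and returns the Pearson correlation with its
#' two-sided t-transform p-value.
#'
#' @param x,y Named numeric vectors (names are protein accessions) or
#'   unnamed equal-length vectors already paired.
#' @return List with `r`, `r_squared`, `p_value`, `n`, `n_dropped`.
#' @export
correlate_log2fc <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  } else if (length(x) != length(y)) {
    stop("unnamed inputs must have equal length")
  }
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in correlation input")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = ct$p.value, n = length(x),
       n_dropped = n_dropped)
}
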