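#' Allele-count 2x2 contingency table
#'
#' The unit of all exact inference in the package: alt/ref allele counts in
#' two groups (typically cases and controls).  Row 1 is group 1 (`a` alt,
#' `b` ref), row 2 is group 2 (`c` alt, `d` ref).
#'
#' @param a Alt-allele count in group 1 (integer >= 0).
#' @param b Ref-allele count in group 1.
#' @param c Alt-allele count in group 2.
#' @param d Ref-allele count in group 2.
#' @return An object of class `table2x2`.
#' @examples
#' table2x2(14, 648, 148, 24610)
#' @export
table2x2 <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (length(x) != 4L || any(!is.finite(x)) || any(x < 0) ||
      any(x != round(x))) {
    stop("table2x2 counts must be non-negative integers", call. = FALSE)
  }
  if (a + b == 0 || c + d == 0) {
    stop("each group must contribute at least one allele", call. = FALSE)
  }
  x <- as.integer(round(x))
  structure(list(a = x[1L], b = x[2L], c = x[3L], d = x[4L]),
            class = "table2x2")
}

as_table2x2 <- function(t) {
  if (inherits(t, "table2x2")) return(t)
  if (is.numeric(t) && length(t) == 4L) {
    return(table2x2(t[[1L]], t[[2L]], t[[3L]], t[[4L]]))
  }
  stop("expected a table2x2 or a numeric vector of length 4", call. = FALSE)
}

#' @export
print.table2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("group1", "group2"), c("alt", "ref")))
  print(m)
  invisible(x)
}

# Conditional support of the group-1 alt count A given all margins.
# Returns list(k, logp0) where logp0 are the central (psi = 1) log masses
# up to a constant: log choose(n1, k) + log choose(n2, S - k).
support2x2 <- function(t) {
  n1 <- t$a + t$b
  n2 <- t$c + t$d
  S <- t$a + t$c
  k <- max(0L, S - n2):min(n1, S)
  list(k = k, logp0 = lchoose(n1, k) + lchoose(n2, S - k))
}

# Relative tolerance guarding floating-point ties when comparing point
# probabilities (the convention of the point-probability two-sided test).
.p_rel_tol <- 1e-7

#' Two-sided Fisher exact test on a 2x2 allele-count table
#'
#' Point-probability method: the p-value is the sum of the probabilities,
#' under the central hypergeometric null with all margins fixed, of every
#' table whose point probability does not exceed that of the observed table
#' (up to a relative tolerance of 1e-7 guarding float ties).  Degenerate
#' tables where only one configuration is consistent with the margins
#' (all-zero alt or ref column) return 1.
#'
#' @param t A [table2x2()].
#' @return Two-sided p-value in \[0, 1\].
#' @examples
#' fisher_two_sided(table2x2(14, 648, 148, 24610))  # 9.2e-05
#' @export
fisher_two_sided <- function(t) {
  t <- as_table2x2(t)
  sup <- support2x2(t)
  if (length(sup$k) == 1L) return(1.0)
  p <- exp(sup$logp0 - max(sup$logp0))
  p <- p / sum(p)
  p_obs <- p[match(t$a, sup$k)]
  min(1.0, sum(p[p <= p_obs * (1 + .p_rel_tol)]))
}

# Noncentral hypergeometric conditional masses at log-odds lpsi,
# normalized over the support.
nch_mass <- function(sup, lpsi) {
  lw <- sup$logp0 + sup$k * lpsi
  w <- exp(lw - max(lw))
  w / sum(w)
}

nch_expect <- function(sup, lpsi) sum(support_k(sup) * nch_mass(sup, lpsi))
support_k <- function(sup) sup$k

# Monotone bisection on log psi.  f must be increasing in lpsi.
bisect_lpsi <- function(f, target, lo = -30, hi = 30, tol = 1e-8,
                        max_iter = 200L) {
  # widen until the target is bracketed (extreme tables can need |lpsi| > 30)
  while (f(lo) > target && lo > -745) lo <- lo * 2
  while (f(hi) < target && hi < 745) hi <- hi * 2
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - target) < tol && (hi - lo) < 1e-8) break
    if (fm < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Conditional maximum-likelihood odds ratio
#'
#' The odds ratio maximizing the noncentral hypergeometric likelihood of
#' the observed table given all margins, found by monotone root-finding on
#' the conditional expectation E_psi\[A\] = a (the CMLE, i.e. the estimate
#' reported by exact conditional inference on 2x2 tables).  Returns 0 at the
#' lower boundary of the support (a at its minimum), `Inf` at the upper
#' boundary, and `NA` for degenerate tables (all-zero alt or ref column),
#' where the odds ratio is undefined.
#'
#' @param t A [table2x2()].
#' @return The CMLE odds ratio (possibly 0, `Inf`, or `NA`).
#' @examples
#' cmle_odds_ratio(table2x2(6, 716, 148, 24610))  # 1.39
#' @export
cmle_odds_ratio <- function(t) {
  t <- as_table2x2(t)
  if (t$a + t$c == 0L || t$b + t$d == 0L) return(NA_real_)
  sup <- support2x2(t)
  if (t$a == min(sup$k)) return(0)
  if (t$a == max(sup$k)) return(Inf)
  lpsi <- bisect_lpsi(function(l) nch_expect(sup, l), target = t$a)
  exp(lpsi)
}

#' Exact confidence interval for the odds ratio
#'
#' Bounds obtained by inverting one-sided noncentral hypergeometric tail
#' tests at (1 - level)/2 on each side: the lower bound solves
#' P_psi(A >= a) = (1 - level)/2 and the upper bound solves
#' P_psi(A <= a) = (1 - level)/2.  The lower bound is 0 when a sits at the
#' bottom of its conditional support, and the upper bound is `Inf` at the
#' top of the support.
#'
#' @param t A [table2x2()].
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' exact_ci(table2x2(6, 716, 148, 24610))  # about (0.50, 3.12)
#' @export
exact_ci <- function(t, level = 0.95) {
  t <- as_table2x2(t)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be a probability strictly between 0 and 1", call. = FALSE)
  }
  if (t$a + t$c == 0L || t$b + t$d == 0L) return(c(low = NA_real_, high = NA_real_))
  sup <- support2x2(t)
  alpha <- (1 - level) / 2
  a <- t$a
  # P(A >= a) is increasing in psi; P(A <= a) is decreasing.
  upper_tail <- function(l) sum(nch_mass(sup, l)[sup$k >= a])
  lower_tail <- function(l) sum(nch_mass(sup, l)[sup$k <= a])
  low <- if (a == min(sup$k)) 0 else exp(bisect_lpsi(upper_tail, alpha))
  high <- if (a == max(sup$k)) Inf else
    exp(bisect_lpsi(function(l) 1 - lower_tail(l), 1 - alpha))
  c(low = low, high = high)
}

#' Exact inference bundle on a 2x2 table
#'
#' Convenience wrapper computing the two-sided p-value, the conditional
#' maximum-likelihood odds ratio and its exact confidence interval in one
#' call.
#'
#' @param t A [table2x2()].
#' @param level Confidence level for the interval.
#' @return A list of class `fisher_result` with elements `p_two_sided`,
#'   `or_cmle`, `ci_low`, `ci_high`, `level`, and `or_defined`.
#' @export
fisher_exact <- function(t, level = 0.95) {
  t <- as_table2x2(t)
  or <- cmle_odds_ratio(t)
  ci <- exact_ci(t, level)
  structure(list(p_two_sided = fisher_two_sided(t), or_cmle = or,
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 level = level, or_defined = !is.na(or)),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  or <- if (x$or_defined) formatC(x$or_cmle, format = "fg", digits = 4) else "undefined"
  cat(sprintf("exact 2x2 inference: p = %s, OR (CMLE) = %s, %g%% CI = (%s, %s)\n",
              format(x$p_two_sided, digits = 3), or, 100 * x$level,
              format(x$ci_low, digits = 3), format(x$ci_high, digits = 3)))
  invisible(x)
}

# Log point masses of the exact HWE sampling distribution over heterozygote
# counts h (same parity as the minor-allele count) at fixed allele counts.
hwe_log_masses <- function(n, n_alt) {
  n_ref <- 2L * n - n_alt
  h <- seq.int(n_alt %% 2L, min(n_alt, n_ref), by = 2L)
  lp <- lfactorial(n) -
    lfactorial((n_alt - h) / 2) - lfactorial(h) - lfactorial(n - (n_alt + h) / 2) +
    h * log(2) + lfactorial(n_alt) + lfactorial(n_ref) - lfactorial(2L * n)
  list(h = h, lp = lp)
}

check_hwe_counts <- function(n_hom_ref, n_het, n_hom_alt) {
  g <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(!is.finite(g)) || any(g < 0) || any(g != round(g)) || sum(g) < 1) {
    stop("genotype counts must be non-negative integers summing to >= 1",
         call. = FALSE)
  }
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact HWE p-value for a biallelic site: the sum, over all
#' heterozygote counts consistent with the observed allele counts, of the
#' probabilities of configurations no more likely than the observed one
#' under the exact HWE sampling distribution (levene/haldane distribution;
#' the standard SNP exact test).
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return Exact two-sided p-value; 1 for monomorphic sites.
#' @examples
#' hwe_exact(25, 50, 25)  # counts at exact HWE proportions
#' @export
hwe_exact <- function(n_hom_ref, n_het, n_hom_alt) {
  check_hwe_counts(n_hom_ref, n_het, n_hom_alt)
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2L * n_hom_alt + n_het
  if (n_alt == 0L || n_alt == 2L * n) return(1.0)
  m <- hwe_log_masses(n, n_alt)
  p <- exp(m$lp - max(m$lp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, m$h)]
  min(1.0, sum(p[p <= p_obs * (1 + .p_rel_tol)]))
}

#' One-sided heterozygote-excess exact tail
#'
#' P(H >= observed heterozygote count) under the exact HWE sampling
#' distribution; the tail behind the phred-scaled ExcessHet site annotation
#' (`ExcessHet = -10 log10 p`).
#'
#' @inheritParams hwe_exact
#' @return One-sided upper-tail p-value.
#' @export
hwe_excess_het <- function(n_hom_ref, n_het, n_hom_alt) {
  check_hwe_counts(n_hom_ref, n_het, n_hom_alt)
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2L * n_hom_alt + n_het
  if (n_alt == 0L || n_alt == 2L * n) return(1.0)
  m <- hwe_log_masses(n, n_alt)
  p <- exp(m$lp - max(m$lp))
  p <- p / sum(p)
  min(1.0, sum(p[m$h >= n_het]))
}

#' Fold enrichment of one frequency over another
#'
#' @param freq_a,freq_b Proportions; `freq_b` must be positive.
#' @return `freq_a / freq_b`.
#' @examples
#' fold_enrichment(14 / 662, 148 / 24758)  # 3.5
#' @export
fold_enrichment <- function(freq_a, freq_b) {
  if (!is.numeric(freq_b) || any(freq_b <= 0)) {
    stop("denominator frequency must be > 0", call. = FALSE)
  }
  freq_a / freq_b
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 178)  # 2.81e-04
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(n_tests) || n_tests < 1 || n_tests != round(n_tests)) {
    stop("n_tests must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  alpha / n_tests
}
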