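#' Carrier tally for one allele
#'
#' Exact genotype tallies for a single variant; individuals with a missing
#' call at the variant are excluded from the denominator.
#'
#' @param g Genotype dosage matrix.
#' @param allele_id Column (variant) identifier.
#' @return A list of class `carrier_tally`: `n_individuals`, `n_het`,
#'   `n_hom`, `n_alleles = n_het + 2 n_hom`, and
#'   `allele_freq = n_alleles / (2 n_individuals)`.
#' @export
carrier_tally <- function(g, allele_id) {
  if (!allele_id %in% colnames(g)) {
    stop("unknown allele id: ", allele_id, call. = FALSE)
  }
  v <- g[, allele_id]
  v <- v[!is.na(v)]
  carrier_tally_counts(length(v), sum(v == 1L), sum(v == 2L))
}

#' Carrier tally from explicit counts
#'
#' @param n_individuals,n_het,n_hom Genotyped individuals, heterozygotes,
#'   alt homozygotes.
#' @return A `carrier_tally` (see [carrier_tally()]).
#' @export
carrier_tally_counts <- function(n_individuals, n_het, n_hom) {
  x <- c(n_individuals, n_het, n_hom)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stop("tally counts must be non-negative integers", call. = FALSE)
  }
  if (n_het + n_hom > n_individuals) {
    stop("more carriers than genotyped individuals", call. = FALSE)
  }
  n_alleles <- n_het + 2L * n_hom
  structure(list(n_individuals = as.integer(n_individuals),
                 n_het = as.integer(n_het), n_hom = as.integer(n_hom),
                 n_alleles = as.integer(n_alleles),
                 allele_freq = if (n_individuals > 0)
                   n_alleles / (2 * n_individuals) else NA_real_),
            class = "carrier_tally")
}

#' @export
print.carrier_tally <- function(x, ...) {
  cat(sprintf(
    "carrier tally: %d genotyped, %d het + %d hom = %d alleles (freq %.4g)\n",
    x$n_individuals, x$n_het, x$n_hom, x$n_alleles, x$allele_freq))
  invisible(x)
}

#' Prevalence arithmetic from a carrier tally
#'
#' `homozygote_fraction` is the share of genotyped individuals homozygous
#' for the allele (the single-allele contribution to disease prevalence in
#' a patient cohort for a recessive allele); `allele_fraction` is the
#' allele frequency.
#'
#' @param tally A `carrier_tally`.
#' @param mode `"homozygote_fraction"` or `"allele_fraction"`.
#' @return A proportion.
#' @examples
#' prevalence(carrier_tally_counts(331, 0, 6))  # 0.018
#' @export
prevalence <- function(tally, mode = c("homozygote_fraction", "allele_fraction")) {
  stopifnot(inherits(tally, "carrier_tally"))
  mode <- match.arg(mode)
  if (tally$n_individuals == 0L) stop("empty tally", call. = FALSE)
  switch(mode,
         homozygote_fraction = tally$n_hom / tally$n_individuals,
         allele_fraction = tally$allele_freq)
}

#' Expected genotype counts under Hardy-Weinberg equilibrium
#'
#' @param freq Alt-allele frequency q in \[0, 1\].
#' @param n Number of diploid individuals.
#' @return Named numeric vector `c(hom_ref, het, hom_alt)` =
#'   `(n(1-q)^2, 2nq(1-q), nq^2)`.
#' @examples
#' hwe_expected(0.006, 12379)  # about 0.45 expected homozygotes
#' @export
hwe_expected <- function(freq, n) {
  if (freq < 0 || freq > 1 || n < 1) stop("invalid arguments", call. = FALSE)
  c(hom_ref = n * (1 - freq)^2, het = 2 * n * freq * (1 - freq),
    hom_alt = n * freq^2)
}

#' All pairwise group comparisons of an allele's frequency
#'
#' For every ordered pair of groups, builds the allele-count 2x2 table
#' (2N denominators) and computes the exact two-sided p, the conditional
#' maximum-likelihood odds ratio with its exact confidence interval, and
#' the fold enrichment of group 1 over group 2.
#'
#' @param tallies Named list of `carrier_tally` objects (>= 2 groups).
#' @param level Confidence level.
#' @return Data.frame, one row per unordered pair.
#' @examples
#' compare_groups(list(
#'   cases = carrier_tally_counts(331, 14, 0),
#'   controls = carrier_tally_counts(12379, 142, 3)))
#' @export
compare_groups <- function(tallies, level = 0.95) {
  if (length(tallies) < 2L || is.null(names(tallies))) {
    stop("need a named list of at least two groups", call. = FALSE)
  }
  for (t in tallies) {
    stopifnot(inherits(t, "carrier_tally"))
    if (t$n_individuals == 0L) stop("group with zero individuals", call. = FALSE)
  }
  pairs <- utils::combn(names(tallies), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- tallies[[pairs[1L, i]]]; g2 <- tallies[[pairs[2L, i]]]
    tab <- table2x2(g1$n_alleles, 2L * g1$n_individuals - g1$n_alleles,
                    g2$n_alleles, 2L * g2$n_individuals - g2$n_alleles)
    f <- fisher_exact(tab, level)
    data.frame(group1 = pairs[1L, i], group2 = pairs[2L, i],
               alt1 = tab$a, ref1 = tab$b, alt2 = tab$c, ref2 = tab$d,
               freq1 = g1$allele_freq, freq2 = g2$allele_freq,
               fold = if (g2$allele_freq > 0)
                 fold_enrichment(g1$allele_freq, g2$allele_freq) else NA_real_,
               or = f$or_cmle, ci_low = f$ci_low, ci_high = f$ci_high,
               p = f$p_two_sided, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
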