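#' Identity-by-state counts for a pair of individuals
#'
#' Per jointly non-missing site, IBS is the number of shared alleles:
#' `2 - |dosage_i - dosage_j|`, which scores opposite homozygotes (0 vs 2)
#' as IBS 0.
#'
#' @param x,y Equal-length dosage vectors (0/1/2, `NA` missing).
#' @return List of class `ibs_counts`: `n_ibs0`, `n_ibs1`, `n_ibs2`,
#'   `n_sites` (jointly genotyped sites).
#' @export
ibs_counts <- function(x, y) {
  if (length(x) != length(y)) stop("dosage vectors differ in length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  ibs <- 2L - abs(x[ok] - y[ok])
  structure(list(n_ibs0 = sum(ibs == 0L), n_ibs1 = sum(ibs == 1L),
                 n_ibs2 = sum(ibs == 2L), n_sites = sum(ok)),
            class = "ibs_counts")
}

# Per-site expected IBS-class probabilities given IBD state, with the
# finite-sample correction obtained by drawing the 4 (IBD 0) or 3 (IBD 1)
# underlying alleles without replacement from the 2N alleles observed in
# the frequency sample (the method-of-moments construction used by the
# standard relatedness tooling).
ibs_given_ibd <- function(freq, n_alleles) {
  X <- n_alleles
  if (any(X <= 3)) stop("need more than 3 alleles per site for the correction",
                        call. = FALSE)
  x <- freq * X
  y <- X - x
  D0 <- X * (X - 1) * (X - 2) * (X - 3)
  p00 <- 2 * x * (x - 1) * y * (y - 1) / D0
  p20 <- (x * (x - 1) * (x - 2) * (x - 3) + y * (y - 1) * (y - 2) * (y - 3) +
            4 * x * (x - 1) * y * (y - 1)) / D0
  p10 <- pmax(0, 1 - p00 - p20)
  p11 <- 2 * x * y / (X * (X - 1))
  p21 <- pmax(0, 1 - p11)
  list(e00 = sum(p00), e10 = sum(p10), e20 = sum(p20),
       e11 = sum(p11), e21 = sum(p21), n = length(freq))
}

#' Method-of-moments IBD estimate for one pair
#'
#' Solves the observed IBS class counts against their expectations given
#' IBD state (computed from allele frequencies with a without-replacement
#' small-sample correction): z0 from the IBS0 count, z1 from the IBS1
#' residual, z2 as the remainder; estimates are clipped to \[0, 1\] and
#' renormalized, and `PI_HAT = z2 + z1/2`.
#'
#' @param counts An [ibs_counts()].
#' @param site_freqs Alt-allele frequencies of the sites entering `counts`
#'   (same order, jointly non-missing sites only).
#' @param n_alleles Number of alleles (2N) behind each frequency estimate
#'   (scalar or per-site vector).
#' @return List of class `ibd_estimate`: `z0`, `z1`, `z2`, `pi_hat`.
#' @export
moment_ibd <- function(counts, site_freqs, n_alleles) {
  stopifnot(inherits(counts, "ibs_counts"))
  if (!length(site_freqs) || counts$n_sites == 0L) {
    stop("no informative sites for IBD estimation", call. = FALSE)
  }
  if (any(site_freqs <= 0 | site_freqs >= 1)) {
    stop("site frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  e <- ibs_given_ibd(site_freqs, n_alleles)
  n <- counts$n_sites
  z0 <- counts$n_ibs0 / e$e00
  z1 <- (counts$n_ibs1 - z0 * e$e10) / e$e11
  z2 <- (counts$n_ibs2 - z0 * e$e20 - z1 * e$e21) / n
  z <- pmin(1, pmax(0, c(z0, z1, z2)))
  if (sum(z) == 0) z <- c(1, 0, 0) else z <- z / sum(z)
  structure(list(z0 = z[1], z1 = z[2], z2 = z[3],
                 pi_hat = z[3] + z[2] / 2,
                 # unclipped moment solutions: unbiased but can leave [0,1];
                 # clipping makes the reported PI_HAT non-negative and
                 # slightly positively biased for unrelated pairs
                 z_raw = c(z0 = z0, z1 = z1, z2 = z2),
                 pi_hat_raw = z2 + z1 / 2),
            class = "ibd_estimate")
}

#' @export
print.ibd_estimate <- function(x, ...) {
  cat(sprintf("IBD (method of moments): z0=%.3f z1=%.3f z2=%.3f PI_HAT=%.4f\n",
              x$z0, x$z1, x$z2, x$pi_hat))
  invisible(x)
}

#' Pairwise relatedness screen
#'
#' Computes PI_HAT for all pairs of individuals by method-of-moments IBD
#' estimation.  Allele frequencies default to the analyzed sample itself;
#' sites with in-sample minor-allele frequency below `maf_min` are dropped
#' as uninformative.  Pairs at or above the threshold are flagged as
#' potentially related.
#'
#' @param g Genotype dosage matrix (>= 2 individuals).
#' @param threshold Relatedness flag threshold on PI_HAT (default 0.2).
#' @param maf_min Minimum in-sample minor-allele frequency for a site to
#'   be used (default 0.01).
#' @param site_freqs Optional externally supplied alt-allele frequencies
#'   (named by variant or in column order); when given, `maf_min` is
#'   applied to them and `n_alleles` must be supplied too.
#' @param n_alleles Allele count behind the frequency estimates; defaults
#'   to 2 x the number of individuals in `g`.
#' @return Data.frame of class `relatedness_report`, one row per pair
#'   (id1, id2, z0, z1, z2, pi_hat, flagged), sorted by pi_hat descending.
#' @export
relatedness_screen <- function(g, threshold = 0.2, maf_min = 0.01,
                               site_freqs = NULL, n_alleles = NULL) {
  n <- nrow(g)
  if (is.null(n) || n < 2L) stop("need at least 2 individuals", call. = FALSE)
  if (is.null(site_freqs)) {
    site_freqs <- colMeans(g, na.rm = TRUE) / 2
  }
  if (is.null(n_alleles)) n_alleles <- 2 * n
  maf <- pmin(site_freqs, 1 - site_freqs)
  use <- which(!is.na(maf) & maf >= maf_min)
  if (!length(use)) stop("no informative sites after the MAF filter", call. = FALSE)
  gu <- g[, use, drop = FALSE]
  fu <- site_freqs[use]
  pairs <- utils::combn(n, 2L)
  rows <- apply(pairs, 2L, function(ij) {
    x <- gu[ij[1L], ]; y <- gu[ij[2L], ]
    ok <- !is.na(x) & !is.na(y)
    est <- moment_ibd(ibs_counts(x, y), fu[ok], n_alleles)
    c(est$z0, est$z1, est$z2, est$pi_hat)
  })
  ids <- rownames(g)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  out <- data.frame(id1 = ids[pairs[1L, ]], id2 = ids[pairs[2L, ]],
                    z0 = rows[1L, ], z1 = rows[2L, ], z2 = rows[3L, ],
                    pi_hat = rows[4L, ],
                    flagged = rows[4L, ] >= threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pi_hat, out$id1, out$id2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("relatedness_report", "data.frame")
  out
}
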