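# Independent oracles used across the suite.  These deliberately avoid the
# package's code paths: plain choose()/factorial() enumeration and generic
# optimizers, so agreement with the implementation is evidence, not
# tautology.

# Two-sided point-probability Fisher p by direct enumeration of the
# conditional support with binomial coefficients.
oracle_fisher_p <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; S <- a + c
  k <- max(0, S - n2):min(n1, S)
  pr <- choose(n1, k) * choose(n2, S - k)
  pr <- pr / sum(pr)
  obs <- pr[k == a]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Conditional log-likelihood of psi for the noncentral hypergeometric
# model; maximized by a generic golden-section search over log(psi).
oracle_cmle <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; S <- a + c
  k <- max(0, S - n2):min(n1, S)
  if (a == min(k)) return(0)
  if (a == max(k)) return(Inf)
  lw0 <- lchoose(n1, k) + lchoose(n2, S - k)
  nll <- function(lpsi) {
    lw <- lw0 + k * lpsi
    -(lw0[k == a] + a * lpsi - (max(lw) + log(sum(exp(lw - max(lw))))))
  }
  exp(stats::optimize(nll, c(-40, 40), tol = 1e-10)$minimum)
}

# One-sided noncentral tails, enumerated directly (for CI inversion checks).
oracle_nch_tail <- function(a, b, c, d, psi, side = c("ge", "le")) {
  side <- match.arg(side)
  n1 <- a + b; n2 <- c + d; S <- a + c
  k <- max(0, S - n2):min(n1, S)
  lw <- lchoose(n1, k) + lchoose(n2, S - k) + k * log(psi)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  if (side == "ge") sum(w[k >= a]) else sum(w[k <= a])
}

# CI bound by bisection on the enumerated tail functions.
oracle_ci <- function(a, b, c, d, level = 0.95) {
  alpha <- (1 - level) / 2
  n1 <- a + b; n2 <- c + d; S <- a + c
  k <- max(0, S - n2):min(n1, S)
  solve_psi <- function(f, target, increasing) {
    lo <- 1e-12; hi <- 1e12
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if ((f(mid) < target) == increasing) lo <- mid else hi <- mid
    }
    sqrt(lo * hi)
  }
  low <- if (a == min(k)) 0 else
    solve_psi(function(p) oracle_nch_tail(a, b, c, d, p, "ge"), alpha, TRUE)
  high <- if (a == max(k)) Inf else
    solve_psi(function(p) oracle_nch_tail(a, b, c, d, p, "le"), alpha, FALSE)
  c(low, high)
}

# Exact HWE p by explicit enumeration over heterozygote counts.
oracle_hwe <- function(hom_ref, het, hom_alt) {
  n <- hom_ref + het + hom_alt
  na <- 2 * hom_alt + het
  if (na == 0 || na == 2 * n) return(1)
  h <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  pr <- vapply(h, function(hh) {
    haa <- (na - hh) / 2
    exp(lfactorial(n) - lfactorial(n - hh - haa) - lfactorial(hh) -
          lfactorial(haa) + hh * log(2) + lfactorial(na) +
          lfactorial(2 * n - na) - lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[h == het] * (1 + 1e-7)]))
}

# Random valid 2x2 tables for property tests.
random_tables <- function(n_tables, n_max, seed) {
  set.seed(seed)
  out <- vector("list", n_tables)
  i <- 0L
  while (i < n_tables) {
    x <- as.integer(rmultinom(1, sample(4:n_max, 1), runif(4, 0.05, 1)))
    if (x[1] + x[2] == 0 || x[3] + x[4] == 0) next
    i <- i + 1L
    out[[i]] <- x
  }
  out
}

# Pedigree simulators for relatedness tests: genotypes at known IBD.
sim_unrelated <- function(q, n) {
  matrix(rbinom(n * length(q), 2, rep(q, each = n)), nrow = n,
         dimnames = list(sprintf("U%03d", seq_len(n)), names(q)))
}

sim_parent_child <- function(q) {
  parent <- rbinom(length(q), 2, q)
  child <- rbinom(length(q), 1, parent / 2) + rbinom(length(q), 1, q)
  rbind(parent = parent, child = child)
}

sim_half_sibs <- function(q) {
  shared_parent <- rbinom(length(q), 2, q)
  s1 <- rbinom(length(q), 1, shared_parent / 2) + rbinom(length(q), 1, q)
  s2 <- rbinom(length(q), 1, shared_parent / 2) + rbinom(length(q), 1, q)
  rbind(hs1 = s1, hs2 = s2)
}

# Genotype matrix whose columns sit at (rounded) exact HWE proportions,
# randomly permuted across individuals.  Used by QC-attribution fixtures so
# the HWE rule never removes a site by sampling chance.
hwe_exact_matrix <- function(n, qs, seed) {
  set.seed(seed)
  cols <- lapply(qs, function(q) {
    n_hom <- round(n * q^2)
    n_het <- round(n * 2 * q * (1 - q))
    sample(c(rep(2L, n_hom), rep(1L, n_het), rep(0L, n - n_hom - n_het)))
  })
  g <- do.call(cbind, cols)
  dimnames(g) <- list(sprintf("i%04d", seq_len(n)),
                      sprintf("V%03d", seq_along(qs)))
  g
}

# Small annotation-subset helper mirroring a QC-filtered matrix.
subset_annotations <- function(ann, keep) {
  structure(list(dp = ann$dp[, keep, drop = FALSE],
                 gq = ann$gq[, keep, drop = FALSE],
                 sites = ann$sites[match(keep, ann$sites$variant), ,
                                   drop = FALSE],
                 truth = ann$truth),
            class = "call_annotations")
}
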