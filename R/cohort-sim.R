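#' Build an allele specification table
#'
#' One row per simulated biallelic locus: population alt-allele frequency
#' `q`, severity weight `w` (the allele's contribution per dose to the
#' mutational load), and a class label.  Severe null alleles must carry the
#' full weight 1.
#'
#' @param id Character vector of unique variant identifiers.
#' @param gene Gene symbols.
#' @param q Population alt-allele frequencies, strictly inside (0, 1).
#' @param w Severity weights in \[0, 1\].
#' @param klass One of `"severe_null"`, `"hypomorph"`, `"modifier"`,
#'   `"neutral"` per locus.
#' @return A data.frame of class `allele_table`.
#' @export
allele_table <- function(id, gene, q, w, klass) {
  tab <- data.frame(id = as.character(id), gene = as.character(gene),
                    q = as.numeric(q), w = as.numeric(w),
                    klass = as.character(klass), stringsAsFactors = FALSE)
  if (anyDuplicated(tab$id)) stop("variant ids must be unique", call. = FALSE)
  if (any(tab$q <= 0 | tab$q >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(tab$w < 0 | tab$w > 1)) stop("weights must lie in [0, 1]", call. = FALSE)
  if (!all(tab$klass %in% c("severe_null", "hypomorph", "modifier", "neutral"))) {
    stop("unknown allele class", call. = FALSE)
  }
  if (any(tab$klass == "severe_null" & tab$w != 1)) {
    stop("severe null alleles must have weight 1", call. = FALSE)
  }
  class(tab) <- c("allele_table", "data.frame")
  tab
}

#' Default locus table for the retinal-degeneration demo cohort
#'
#' The package's reference simulation scenario: three RP1 alleles (two
#' severe frameshift nulls and the frequent hypomorphic nonsense variant
#' at population frequency 0.6%), a panel of 84 retinal-disease genes
#' carrying 178 nonsynonymous variants in the 0.1--5% control-frequency
#' window (3 planted high-weight EYS-like modifiers whose frequencies match
#' the reported top association hits, 9 further severe modifiers, 20
#' moderate-weight modifiers, and 146 neutral polymorphisms), plus 24
#' out-of-window neutral variants exercising the frequency filter.
#'
#' The hypomorph frequency (0.006), the planted modifier control
#' frequencies (0.017, 0.002, 0.004) and the severe-null frequency
#' (1/1048, from one carrier among 524 screened controls) are the reported
#' population values; the remaining frequencies and all severity weights
#' are simulation configuration (see the methods vignette for the
#' calibration arithmetic).
#'
#' @return An [allele_table()] with 205 loci.
#' @export
default_hrd_loci <- function() {
  panel <- default_panel_genes()
  sev_genes <- c("USH2A", "PDZD7", "CC2D2A", "RPGRIP1L", "BBIP1",
                 "CRB1", "CNGB1", "RPE65", "CEP290")
  rp1 <- allele_table(
    id = c("RP1_Alu_ins", "RP1_c4196del", "rs118031911"),
    gene = "RP1",
    q = c(1 / 1048, 5.44e-5, 0.006),
    w = c(1, 1, 0.5),
    klass = c("severe_null", "severe_null", "hypomorph"))
  planted <- allele_table(
    id = c("EYS_G843E", "EYS_Y2935X", "EYS_S1653fs"),
    gene = "EYS", q = c(0.017, 0.002, 0.004), w = 1, klass = "modifier")
  severe_mod <- allele_table(
    id = sprintf("SEV%02d", seq_along(sev_genes)),
    gene = sev_genes, q = 0.003, w = 1, klass = "modifier")
  moderate <- allele_table(
    id = sprintf("MOD%02d", 1:20),
    gene = panel[10 + (1:20)],
    q = rep(c(0.004, 0.006, 0.008, 0.010, 0.012), 4),
    w = 0.5, klass = "modifier")
  neutral_q <- exp(seq(log(0.001), log(0.05), length.out = 146))
  neutral_q[1] <- 0.001; neutral_q[146] <- 0.05  # keep exact window bounds
  neutral <- allele_table(
    id = sprintf("NEU%03d", 1:146),
    gene = panel[1 + (seq_len(146) - 1L) %% length(panel)],
    q = neutral_q, w = 0, klass = "neutral")
  rare <- allele_table(
    id = sprintf("RARE%02d", 1:16),
    gene = panel[1 + (seq_len(16) - 1L) %% length(panel)],
    q = seq(1e-4, 8e-4, length.out = 16), w = 0, klass = "neutral")
  common <- allele_table(
    id = sprintf("COM%02d", 1:8),
    gene = panel[1 + (seq_len(8) - 1L) %% length(panel)],
    q = seq(0.06, 0.30, length.out = 8), w = 0, klass = "neutral")
  out <- rbind(rp1, planted, severe_mod, moderate, neutral, rare, common)
  class(out) <- c("allele_table", "data.frame")
  out
}

#' Default 84-gene retinal-disease panel
#'
#' Eleven established retinal-disease gene symbols plus synthetic
#' placeholders, emulating a curated panel list (one symbol per line when
#' written to disk).
#'
#' @return Character vector of 84 gene symbols.
#' @export
default_panel_genes <- function() {
  c("RP1", "EYS", "USH2A", "PDZD7", "CC2D2A", "RPGRIP1L", "BBIP1",
    "CRB1", "CNGB1", "RPE65", "CEP290", sprintf("RETG%02d", 1:73))
}

#' Threshold-penetrance (mutational load) model
#'
#' Affection status is deterministic in the diploid genotype: an individual
#' is affected iff the load `L = sum_v dosage(v) * w(v)` reaches the
#' threshold.  Compound heterozygosity arises naturally because the two
#' alleles at one locus (or at two loci in one gene) both contribute their
#' dose-weighted load.
#'
#' @param loci An [allele_table()] supplying the weights.
#' @param threshold Load threshold T > 0 (default 1.5: two severe-null
#'   doses or one severe null plus one hypomorph dose reach it, a
#'   homozygous hypomorph at 2 x 0.5 = 1 does not).
#' @param phenocopy_rate Probability that an individual below threshold is
#'   affected anyway (default 0: fully deterministic model).
#' @return A list of class `penetrance_model`.
#' @export
penetrance_model <- function(loci, threshold = 1.5, phenocopy_rate = 0) {
  stopifnot(inherits(loci, "data.frame"))
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be > 0", call. = FALSE)
  }
  if (phenocopy_rate < 0 || phenocopy_rate > 1) {
    stop("phenocopy_rate must be in [0, 1]", call. = FALSE)
  }
  w <- stats::setNames(loci$w, loci$id)
  structure(list(threshold = threshold, weights = w,
                 phenocopy_rate = phenocopy_rate),
            class = "penetrance_model")
}

#' Cohort simulation configuration
#'
#' @param n_cases,n_controls Cohort sizes (>= 1).
#' @param loci An [allele_table()].
#' @param penetrance A [penetrance_model()]; default built from `loci`.
#' @param ascertainment Case sampling rule: `"population"` (unselected),
#'   `"affected"` (any affected individual), or
#'   `"affected_m3_het_no_other_rp1"` (affected, heterozygous for the index
#'   hypomorph, no severe allele at the same locus -- the study's
#'   carrier-conditioned design).
#' @param index_id Variant id of the index hypomorph.
#' @param same_gene_ids Variant ids whose carriage disqualifies a case
#'   under the carrier-conditioned ascertainment (the severe alleles of the
#'   index gene).
#' @param seed Integer seed.
#' @param max_draws Rejection-sampling cap per requested case.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 28, n_controls = 3554,
                          loci = default_hrd_loci(),
                          penetrance = penetrance_model(loci),
                          ascertainment = c("affected_m3_het_no_other_rp1",
                                            "affected", "population"),
                          index_id = "rs118031911",
                          same_gene_ids = c("RP1_Alu_ins", "RP1_c4196del"),
                          seed = 1L, max_draws = 1e7) {
  ascertainment <- match.arg(ascertainment)
  if (n_cases < 1 || n_controls < 1) stop("cohort sizes must be >= 1", call. = FALSE)
  if (ascertainment == "affected_m3_het_no_other_rp1" &&
      !index_id %in% loci$id) {
    stop("index variant not present in the locus table", call. = FALSE)
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), loci = loci,
                 penetrance = penetrance, ascertainment = ascertainment,
                 index_id = index_id, same_gene_ids = same_gene_ids,
                 seed = as.integer(seed), max_draws = max_draws),
            class = "cohort_config")
}

#' Sample diploid genotypes under Hardy-Weinberg equilibrium
#'
#' Each genotype is drawn independently as Binomial(2, q) per locus; no
#' linkage disequilibrium is simulated.
#'
#' @param loci An [allele_table()] (or any data.frame with `id` and `q`).
#' @param n Number of individuals.
#' @param seed Integer seed; when `NULL` the current RNG stream is used.
#' @param id_prefix Prefix for row (individual) names.
#' @return Integer matrix (individuals x variants) of dosages 0/1/2 with
#'   individual row names and variant column names.
#' @export
sample_genotypes <- function(loci, n, seed = NULL, id_prefix = "I") {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (nrow(loci) < 1) stop("loci must be non-empty", call. = FALSE)
  if (any(loci$q <= 0 | loci$q >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(stats::rbinom(n * nrow(loci), 2L, rep(loci$q, each = n)),
              nrow = n, ncol = nrow(loci),
              dimnames = list(sprintf("%s%05d", id_prefix, seq_len(n)),
                              loci$id))
  storage.mode(g) <- "integer"
  g
}

#' Mutational load of each individual
#'
#' `L = sum_v dosage(v) * w(v)`; missing dosages contribute no load.
#'
#' @param g Genotype dosage matrix (individuals x variants).
#' @param model A [penetrance_model()].
#' @return Numeric vector of loads, one per individual.
#' @export
mutational_load <- function(g, model) {
  w <- model$weights[colnames(g)]
  if (anyNA(names(w)) || anyNA(w)) {
    stop("penetrance model lacks weights for some variants in the matrix",
         call. = FALSE)
  }
  gg <- g
  gg[is.na(gg)] <- 0L
  as.numeric(gg %*% w)
}

#' Deterministic affection calls under the load-threshold model
#'
#' @inheritParams mutational_load
#' @return Logical vector: `TRUE` iff load >= threshold (plus random
#'   phenocopies when the model's `phenocopy_rate` is positive).
#' @export
assign_phenotype <- function(g, model) {
  load <- mutational_load(g, model)
  aff <- load >= model$threshold
  if (model$phenocopy_rate > 0) {
    aff <- aff | (stats::runif(length(aff)) < model$phenocopy_rate)
  }
  stats::setNames(aff, rownames(g))
}

case_predicate <- function(g, aff, cfg) {
  switch(cfg$ascertainment,
    population = rep(TRUE, nrow(g)),
    affected = aff,
    affected_m3_het_no_other_rp1 = {
      other <- intersect(cfg$same_gene_ids, colnames(g))
      no_other <- if (length(other)) {
        rowSums(g[, other, drop = FALSE], na.rm = TRUE) == 0L
      } else rep(TRUE, nrow(g))
      aff & g[, cfg$index_id] == 1L & no_other
    })
}

causal_string <- function(row, w) {
  idx <- which(row > 0L & w > 0)
  if (!length(idx)) return("")
  paste(names(w)[idx], collapse = ",")
}

#' Simulate an ascertained case/control cohort
#'
#' Individuals are forward-simulated from the population (HWE genotypes,
#' deterministic load-threshold phenotype) and rejection-sampled until
#' `n_cases` satisfy the ascertainment predicate; controls are drawn from
#' the unselected population.  The truth table records every sampled
#' individual's load and positively-weighted carried variants.
#'
#' @param cfg A [cohort_config()].
#' @return List with `cases` and `controls` genotype matrices, `loci`, and
#'   `truth` (data.frame: id, group, load, affected, causal variants).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  model <- cfg$penetrance
  loci <- cfg$loci
  batch <- max(2000L, cfg$n_cases)
  cases <- NULL
  drawn <- 0
  while (is.null(cases) || nrow(cases) < cfg$n_cases) {
    if (drawn >= cfg$max_draws * cfg$n_cases) {
      stop("ascertainment infeasible: no eligible case found within the ",
           "rejection-sampling cap", call. = FALSE)
    }
    g <- sample_genotypes(loci, batch, seed = NULL, id_prefix = "P")
    drawn <- drawn + batch
    aff <- assign_phenotype(g, model)
    keep <- case_predicate(g, aff, cfg)
    if (any(keep)) cases <- rbind(cases, g[keep, , drop = FALSE])
    # fail fast when the predicate looks unsatisfiable
    if (is.null(cases) && drawn >= max(1e6, 200 * batch)) {
      stop("ascertainment infeasible: no eligible case in ", drawn,
           " draws", call. = FALSE)
    }
  }
  cases <- cases[seq_len(cfg$n_cases), , drop = FALSE]
  rownames(cases) <- sprintf("CASE%04d", seq_len(cfg$n_cases))
  controls <- sample_genotypes(loci, cfg$n_controls, seed = NULL,
                               id_prefix = "CTRL")
  w <- model$weights[loci$id]
  truth_of <- function(g, group) {
    load <- mutational_load(g, model)
    data.frame(id = rownames(g), group = group, load = load,
               affected = load >= model$threshold,
               causal = apply(g, 1L, causal_string, w = w),
               stringsAsFactors = FALSE)
  }
  list(cases = cases, controls = controls, loci = loci,
       truth = rbind(truth_of(cases, "case"), truth_of(controls, "control")))
}

default_fail_rates <- function() {
  c(dp = 0, gq = 0, site_mean_gq = 0, site_callrate = 0, site_vqsr = 0,
    site_qd = 0, site_fs = 0, site_mq = 0, site_mqranksum = 0,
    site_readposranksum = 0, site_sor = 0)
}

#' Simulate per-call and per-site QC annotations
#'
#' Draws read depth (DP) and genotype quality (GQ) for every call and the
#' standard hard-filter site metrics (QD, FS, MQ, MQRankSum,
#' ReadPosRankSum, SOR) from distributions that satisfy the QC thresholds,
#' then plants rule violations at the requested rates; every planted
#' failure is recorded in the returned truth so the QC cascade can be
#' audited call-for-call.  ExcessHet is not a knob: it is computed from the
#' genotype matrix as the phred-scaled one-sided heterozygote-excess exact
#' tail ([hwe_excess_het()]).  Site-level failures are planted on disjoint
#' site sets so each planted site fails exactly one rule.
#'
#' @param g Genotype dosage matrix.
#' @param fail_rates Named vector of planting rates in \[0, 1\]; names as in
#'   `default_fail_rates()` (`dp` and `gq` are per-call, `site_*` per-site).
#' @param seed Integer seed; `NULL` keeps the current stream.
#' @param depth_mean Mean sequencing depth for passing calls.
#' @return List of class `call_annotations`: `dp`, `gq` (matrices),
#'   `sites` (data.frame of per-site metrics and `vqsr_pass`), and `truth`
#'   (planted failures: `mask_expected` logical matrix, `n_dp`, `n_gq`,
#'   `sites` data.frame of variant/rule pairs).
#' @export
simulate_annotations <- function(g, fail_rates = default_fail_rates(),
                                 seed = NULL, depth_mean = 80) {
  rates <- default_fail_rates()
  if (length(fail_rates)) {
    unknown <- setdiff(names(fail_rates), names(rates))
    if (length(unknown)) stop("unknown fail rate: ", paste(unknown, collapse = ", "),
                              call. = FALSE)
    rates[names(fail_rates)] <- fail_rates
  }
  if (any(rates < 0 | rates > 1)) stop("fail rates must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(g); L <- ncol(g); nc <- n * L
  dp <- matrix(8L + stats::rpois(nc, depth_mean - 8), n, L, dimnames = dimnames(g))
  gq <- matrix(pmin(99L, 36L + stats::rpois(nc, 30)), n, L, dimnames = dimnames(g))
  # per-call planted failures
  dp_fail <- which(stats::runif(nc) < rates[["dp"]])
  gq_fail <- which(stats::runif(nc) < rates[["gq"]])
  dp[dp_fail] <- sample(0:7, length(dp_fail), replace = TRUE)
  gq[gq_fail] <- sample(0:19, length(gq_fail), replace = TRUE)
  # per-site passing metrics
  sites <- data.frame(
    variant = colnames(g),
    QD = stats::runif(L, 5, 35),
    FS = stats::runif(L, 0, 30),
    MQ = stats::runif(L, 50, 60),
    MQRankSum = stats::runif(L, -3, 3),
    ReadPosRankSum = stats::runif(L, -3, 3),
    SOR = stats::runif(L, 0.3, 2.5),
    ExcessHet = NA_real_,
    vqsr_pass = TRUE,
    stringsAsFactors = FALSE)
  het_p <- vapply(seq_len(L), function(j) {
    v <- g[, j]
    hwe_excess_het(sum(v == 0L, na.rm = TRUE), sum(v == 1L, na.rm = TRUE),
                   sum(v == 2L, na.rm = TRUE))
  }, numeric(1))
  sites$ExcessHet <- -10 * log10(pmax(het_p, 1e-30))
  # disjoint site-level planting
  site_rules <- c(site_mean_gq = "mean_gq", site_callrate = "callrate",
                  site_vqsr = "vqsr", site_qd = "hard_filter",
                  site_fs = "hard_filter", site_mq = "hard_filter",
                  site_mqranksum = "hard_filter",
                  site_readposranksum = "hard_filter",
                  site_sor = "hard_filter")
  avail <- sample.int(L)  # random order; consumed head-first per rule
  planted <- data.frame(variant = character(0), rule = character(0),
                        stringsAsFactors = FALSE)
  take <- function(rate) {
    k <- stats::rbinom(1L, length(avail), rate)
    idx <- utils::head(avail, k)
    avail <<- utils::tail(avail, length(avail) - k)
    idx
  }
  for (rn in names(site_rules)) {
    idx <- take(rates[[rn]])
    if (!length(idx)) next
    for (j in idx) {
      switch(rn,
        site_mean_gq = { gq[, j] <- sample(20:34, n, replace = TRUE) },
        site_callrate = {
          bad <- sample.int(n, ceiling(0.15 * n))
          dp[bad, j] <- sample(0:7, length(bad), replace = TRUE)
        },
        site_vqsr = { sites$vqsr_pass[j] <- FALSE },
        site_qd = { sites$QD[j] <- stats::runif(1, 0, 1.9) },
        site_fs = { sites$FS[j] <- stats::runif(1, 61, 200) },
        site_mq = { sites$MQ[j] <- stats::runif(1, 10, 39.5) },
        site_mqranksum = { sites$MQRankSum[j] <- stats::runif(1, -20, -12.6) },
        site_readposranksum = { sites$ReadPosRankSum[j] <- stats::runif(1, -15, -8.1) },
        site_sor = { sites$SOR[j] <- stats::runif(1, 3.1, 9) })
    }
    planted <- rbind(planted,
                     data.frame(variant = colnames(g)[idx], rule = site_rules[[rn]],
                                stringsAsFactors = FALSE))
  }
  structure(list(dp = dp, gq = gq, sites = sites,
                 truth = list(mask_expected = dp < 8L | gq < 20L,
                              n_dp = length(dp_fail), n_gq = length(gq_fail),
                              sites = planted)),
            class = "call_annotations")
}
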