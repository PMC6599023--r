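#' QC thresholds for the six-step filtering cascade
#'
#' Defaults follow the standard exome hard-filter recipe: per-call DP >= 8
#' and GQ >= 20; exclude sites with mean GQ <= 35 or call rate <= 0.9
#' (both boundaries exclusionary); keep sites in Hardy-Weinberg
#' equilibrium (exact p > alpha after Bonferroni correction over the
#' polymorphic sites tested); require the VQSR pass flag; and the final
#' hard filter QD >= 2, FS <= 60, MQ >= 40, MQRankSum >= -12.5,
#' ReadPosRankSum >= -8, SOR <= 3, ExcessHet <= 20 (all boundaries
#' inclusive for keeping).
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(...) {
  thr <- list(min_dp = 8, min_gq = 20, max_mean_gq_excl = 35,
              max_callrate_excl = 0.9, hwe_alpha = 0.05,
              vqsr_required = TRUE, min_qd = 2, max_fs = 60, min_mq = 40,
              min_mqranksum = -12.5, min_readposranksum = -8, max_sor = 3,
              max_excesshet = 20)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(thr))
  if (length(unknown)) stop("unknown threshold: ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  thr[names(dots)] <- dots
  structure(thr, class = "qc_thresholds")
}

check_annotations <- function(g, ann) {
  if (!all(c("dp", "gq", "sites") %in% names(ann))) {
    stop("annotations must provide dp, gq and sites", call. = FALSE)
  }
  if (!identical(dim(ann$dp), dim(g)) || !identical(dim(ann$gq), dim(g))) {
    stop("annotation matrices must match the genotype matrix shape",
         call. = FALSE)
  }
  if (!identical(ann$sites$variant, colnames(g))) {
    stop("site annotations must cover exactly the variants in the matrix",
         call. = FALSE)
  }
  need <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR",
            "ExcessHet", "vqsr_pass")
  miss <- setdiff(need, names(ann$sites))
  if (length(miss)) stop("missing site annotation: ", paste(miss, collapse = ", "),
                         call. = FALSE)
}

#' Mask low-quality individual calls (cascade step 1)
#'
#' Sets calls with DP < 8 or GQ < 20 to missing; all other calls are
#' untouched (the boundary values 8 and 20 are kept).
#'
#' @param g Genotype dosage matrix.
#' @param ann A `call_annotations` object (or compatible list).
#' @param thr A [qc_thresholds()].
#' @return The genotype matrix with failing calls set to `NA`.
#' @export
mask_calls <- function(g, ann, thr = qc_thresholds()) {
  check_annotations(g, ann)
  g[ann$dp < thr$min_dp | ann$gq < thr$min_gq] <- NA_integer_
  g
}

geno_counts <- function(v) {
  c(sum(v == 0L, na.rm = TRUE), sum(v == 1L, na.rm = TRUE),
    sum(v == 2L, na.rm = TRUE))
}

#' Site-level QC cascade (steps 2--6)
#'
#' Applies, in order and each on the survivors of the previous rule:
#' (2) mean GQ of unmasked calls <= 35 excludes; (3) call rate <= 0.9
#' excludes; (4) Hardy-Weinberg exact p <= alpha/m excludes, with the
#' Bonferroni divisor m the number of polymorphic sites entering the rule;
#' (5) VQSR fail excludes; (6) hard filter on QD, FS, MQ, MQRankSum,
#' ReadPosRankSum, SOR and ExcessHet (boundaries inclusive for keeping;
#' missing metric values pass and are flagged).  Call masking
#' ([mask_calls()]) must already have been applied so that call rate and
#' genotype counts reflect post-mask missingness.  Each removed site is
#' charged to the first rule it fails.
#'
#' @inheritParams mask_calls
#' @return List with `genotypes` (surviving columns) and `report`
#'   (class `qc_report`): per-rule removal counts, the removed sites with
#'   their rule, surviving site ids, and sites that passed rule 6 on a
#'   missing metric.
#' @export
filter_sites <- function(g, ann, thr = qc_thresholds()) {
  check_annotations(g, ann)
  sites <- ann$sites
  alive <- colnames(g)
  removed <- data.frame(variant = character(0), rule = character(0),
                        stringsAsFactors = FALSE)
  log_rule <- function(rule, victims) {
    if (length(victims)) {
      removed <<- rbind(removed, data.frame(variant = victims, rule = rule,
                                            stringsAsFactors = FALSE))
      alive <<- setdiff(alive, victims)
    }
  }

  present <- !is.na(g)
  mean_gq <- vapply(alive, function(v) {
    ok <- present[, v]
    if (!any(ok)) NaN else mean(ann$gq[ok, v])
  }, numeric(1))
  log_rule("mean_gq", alive[!(mean_gq > thr$max_mean_gq_excl) | is.nan(mean_gq)])

  callrate <- colMeans(present[, alive, drop = FALSE])
  log_rule("callrate", alive[!(callrate > thr$max_callrate_excl)])

  counts <- vapply(alive, function(v) geno_counts(g[, v]), numeric(3))
  poly <- apply(counts, 2L, function(cc) {
    na <- 2 * cc[3] + cc[2]
    sum(cc) > 0 && na > 0 && na < 2 * sum(cc)
  })
  m <- sum(poly)
  if (m > 0) {
    cutoff <- bonferroni_threshold(thr$hwe_alpha, m)
    hwe_p <- rep(1, length(alive))
    hwe_p[poly] <- vapply(which(poly), function(i) {
      hwe_exact(counts[1, i], counts[2, i], counts[3, i])
    }, numeric(1))
    log_rule("hwe", alive[hwe_p <= cutoff])
  }

  if (isTRUE(thr$vqsr_required)) {
    vq <- sites$vqsr_pass[match(alive, sites$variant)]
    log_rule("vqsr", alive[!vq])
  }

  s <- sites[match(alive, sites$variant), , drop = FALSE]
  ge <- function(x, lim) !is.na(x) & x >= lim
  le <- function(x, lim) !is.na(x) & x <= lim
  na_pass <- is.na(s$QD) | is.na(s$FS) | is.na(s$MQ) | is.na(s$MQRankSum) |
    is.na(s$ReadPosRankSum) | is.na(s$SOR) | is.na(s$ExcessHet)
  fail6 <- (!is.na(s$QD) & s$QD < thr$min_qd) |
    (!is.na(s$FS) & s$FS > thr$max_fs) |
    (!is.na(s$MQ) & s$MQ < thr$min_mq) |
    (!is.na(s$MQRankSum) & s$MQRankSum < thr$min_mqranksum) |
    (!is.na(s$ReadPosRankSum) & s$ReadPosRankSum < thr$min_readposranksum) |
    (!is.na(s$SOR) & s$SOR > thr$max_sor) |
    (!is.na(s$ExcessHet) & s$ExcessHet > thr$max_excesshet)
  na_flagged <- alive[na_pass & !fail6]
  log_rule("hard_filter", alive[fail6])

  rules <- c("mean_gq", "callrate", "hwe", "vqsr", "hard_filter")
  counts_by_rule <- stats::setNames(
    vapply(rules, function(r) sum(removed$rule == r), numeric(1)), rules)
  report <- structure(list(n_sites_in = ncol(g),
                           n_removed = counts_by_rule,
                           removed = removed,
                           survivors = alive,
                           hwe_bonferroni_m = m,
                           na_passed_hard_filter = na_flagged),
                      class = "qc_report")
  list(genotypes = g[, alive, drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("site QC cascade: %d sites in, %d removed, %d surviving\n",
              x$n_sites_in, nrow(x$removed), length(x$survivors)))
  for (r in names(x$n_removed)) {
    cat(sprintf("  rule %-12s removed %d\n", r, x$n_removed[[r]]))
  }
  if (length(x$na_passed_hard_filter)) {
    cat("  sites passing hard filter on missing metrics:",
        length(x$na_passed_hard_filter), "\n")
  }
  invisible(x)
}

#' Write a QC report to TSV
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @param header Optional comment lines to prepend (each prefixed `#`).
#' @export
write_qc_report <- function(report, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(paste0("# sites_in=", report$n_sites_in,
                    " removed=", nrow(report$removed),
                    " hwe_bonferroni_m=", report$hwe_bonferroni_m), con)
  utils::write.table(report$removed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
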