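#' Association scan configuration
#'
#' @param maf_low,maf_high Control allele-frequency window (inclusive
#'   bounds; defaults 0.001 and 0.05).
#' @param index_variant Variant id excluded from testing (the conditioning
#'   carrier allele).
#' @param alpha Family-wise error rate for Bonferroni calling.
#' @param panel Character vector of panel gene symbols.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(maf_low = 0.001, maf_high = 0.05,
                        index_variant = "rs118031911", alpha = 0.05,
                        panel = default_panel_genes()) {
  if (!(maf_low > 0 && maf_low < maf_high && maf_high < 0.5)) {
    stop("need 0 < maf_low < maf_high < 0.5", call. = FALSE)
  }
  if (!length(panel)) stop("empty gene panel", call. = FALSE)
  structure(list(maf_low = maf_low, maf_high = maf_high,
                 index_variant = index_variant, alpha = alpha,
                 panel = panel),
            class = "scan_config")
}

#' Select variants for the scan
#'
#' Retains candidates whose control allele frequency lies inside the
#' configured window (inclusive), whose gene is in the panel, and which
#' are not the index variant.  If the table carries a logical
#' `nonsynonymous` column, only nonsynonymous candidates are kept
#' (consequence annotation is an input, not computed).
#'
#' @param control_freqs Data.frame with columns `variant`, `gene`, `freq`
#'   (control allele frequency) and optionally `nonsynonymous`.
#' @param cfg A [scan_config()].
#' @return The retained subset, with attribute `n_tested`.
#' @export
select_variants <- function(control_freqs, cfg) {
  stopifnot(inherits(cfg, "scan_config"))
  need <- c("variant", "gene", "freq")
  if (!all(need %in% names(control_freqs))) {
    stop("control_freqs needs columns variant, gene, freq", call. = FALSE)
  }
  keep <- control_freqs$freq >= cfg$maf_low &
    control_freqs$freq <= cfg$maf_high &
    control_freqs$gene %in% cfg$panel &
    control_freqs$variant != cfg$index_variant
  if ("nonsynonymous" %in% names(control_freqs)) {
    keep <- keep & control_freqs$nonsynonymous
  }
  out <- control_freqs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(out)
  out
}

allele_counts_for <- function(g, ids) {
  gg <- g[, ids, drop = FALSE]
  alt <- colSums(gg, na.rm = TRUE)
  tot <- 2 * colSums(!is.na(gg))
  list(alt = alt, total = tot)
}

#' Carrier-conditioned rare-variant association scan
#'
#' Per selected variant, builds the allelic 2x2 table (case alt/ref vs
#' control alt/ref, with missing calls excluded from the denominators) and
#' computes the exact two-sided p-value, plus the conditional
#' maximum-likelihood odds ratio and exact confidence interval when
#' `ci = TRUE`.  Rows are sorted by p ascending; a row is significant iff
#' `p < alpha / n_tested`.
#'
#' @param cases,controls Genotype dosage matrices sharing the selected
#'   variant columns.
#' @param cfg A [scan_config()].
#' @param control_freqs Optional control allele-frequency table for the
#'   window filter (see [select_variants()]); when `NULL` it is derived
#'   from the control matrix, with genes taken from `loci`.
#' @param loci Optional [allele_table()] supplying variant-to-gene
#'   annotation when `control_freqs` is derived.
#' @param ci Compute odds ratios and confidence intervals (default TRUE;
#'   disable for large null simulations).
#' @param level Confidence level.
#' @return Data.frame of class `assoc_scan` (gene, variant, freq_cases,
#'   freq_controls, or, ci_low, ci_high, p, significant), with attributes
#'   `n_tested` and `threshold`.
#' @export
assoc_scan <- function(cases, controls, cfg = scan_config(),
                       control_freqs = NULL, loci = NULL, ci = TRUE,
                       level = 0.95) {
  stopifnot(inherits(cfg, "scan_config"))
  if (is.null(control_freqs)) {
    freq <- colMeans(controls, na.rm = TRUE) / 2
    gene <- if (!is.null(loci)) loci$gene[match(colnames(controls), loci$id)]
            else colnames(controls)
    control_freqs <- data.frame(variant = colnames(controls), gene = gene,
                                freq = freq, stringsAsFactors = FALSE)
  }
  sel <- select_variants(control_freqs, cfg)
  n_tested <- nrow(sel)
  if (n_tested == 0L) {
    out <- data.frame(gene = character(0), variant = character(0),
                      freq_cases = numeric(0), freq_controls = numeric(0),
                      or = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p = numeric(0),
                      significant = logical(0))
  } else {
    missing_case <- setdiff(sel$variant, colnames(cases))
    missing_ctrl <- setdiff(sel$variant, colnames(controls))
    if (length(missing_case) || length(missing_ctrl)) {
      stop("selected variants absent from a genotype matrix: ",
           paste(union(missing_case, missing_ctrl), collapse = ", "),
           call. = FALSE)
    }
    ca <- allele_counts_for(cases, sel$variant)
    co <- allele_counts_for(controls, sel$variant)
    threshold <- bonferroni_threshold(cfg$alpha, n_tested)
    rows <- lapply(seq_len(n_tested), function(i) {
      tab <- table2x2(ca$alt[i], ca$total[i] - ca$alt[i],
                      co$alt[i], co$total[i] - co$alt[i])
      p <- fisher_two_sided(tab)
      if (ci) {
        or <- cmle_odds_ratio(tab)
        bounds <- exact_ci(tab, level)
      } else {
        or <- NA_real_; bounds <- c(low = NA_real_, high = NA_real_)
      }
      data.frame(gene = sel$gene[i], variant = sel$variant[i],
                 freq_cases = ca$alt[i] / ca$total[i],
                 freq_controls = co$alt[i] / co$total[i],
                 or = or, ci_low = bounds[["low"]], ci_high = bounds[["high"]],
                 p = p, significant = p < threshold,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$p, out$variant), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_tested") <- n_tested
  attr(out, "threshold") <- if (n_tested > 0)
    bonferroni_threshold(cfg$alpha, n_tested) else NA_real_
  class(out) <- c("assoc_scan", "data.frame")
  out
}

#' Q-Q plot coordinates for scan p-values
#'
#' @param pvals P-values in (0, 1\].
#' @return Data.frame with `expected = -log10((i - 0.5)/n)` for rank i and
#'   `observed = -log10(p)` sorted to match.
#' @export
qq_data <- function(pvals) {
  if (!length(pvals)) stop("no p-values", call. = FALSE)
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  n <- length(pvals)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = sort(-log10(pvals), decreasing = TRUE))
}

#' Render the top scan hits as a fixed-precision table
#'
#' Frequencies are printed with 3 decimals, odds ratios and confidence
#' bounds with 2, p-values in scientific notation with one decimal of
#' mantissa, and significant rows (p below the Bonferroni threshold) are
#' starred.
#'
#' @param rows An [assoc_scan()] result (sorted by p).
#' @param top_k Number of rows to render.
#' @param format `"tsv"` or `"markdown"`.
#' @return Character vector of lines (header + rows).
#' @export
format_assoc_table <- function(rows, top_k = 10L, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  k <- min(top_k, nrow(rows))
  hdr <- c("Gene", "Variant", "Frequency in cases", "Frequency in controls",
           "OR", "95% CI (OR)", "p-value")
  body <- if (k > 0) {
    r <- rows[seq_len(k), , drop = FALSE]
    cells <- cbind(r$gene, r$variant,
                   sprintf("%.3f", r$freq_cases),
                   sprintf("%.3f", r$freq_controls),
                   sprintf("%.2f", r$or),
                   sprintf("%.2f-%.2f", r$ci_low, r$ci_high),
                   paste0(sprintf("%.1E", r$p),
                          ifelse(r$significant, "*", "")))
    cells
  } else matrix(character(0), 0, length(hdr))
  body_lines <- if (k > 0) apply(body, 1L, paste, collapse = "\t") else character(0)
  if (format == "tsv") {
    c(paste(hdr, collapse = "\t"), body_lines)
  } else {
    c(paste0("| ", paste(hdr, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
      if (k > 0) apply(body, 1L, function(x)
        paste0("| ", paste(x, collapse = " | "), " |")))
  }
}
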