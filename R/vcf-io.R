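#' Write a genotype matrix (with optional annotations) as minimal VCF 4.2
#'
#' The dialect: one synthetic contig, FORMAT `GT:DP:GQ` (or `GT` when no
#' annotations are given), INFO keys QD, FS, MQ, MQRankSum,
#' ReadPosRankSum, SOR, ExcessHet, and FILTER `PASS` or `VQSR_FAIL`.
#' Header comment lines carry the tool version, the seed, and the
#' configuration hash when supplied.
#'
#' @param g Genotype dosage matrix (individuals x variants).
#' @param path Output file.
#' @param ann Optional `call_annotations`.
#' @param seed,config_hash Optional provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(g, path, ann = NULL, seed = NULL,
                             config_hash = NULL) {
  n <- nrow(g); L <- ncol(g)
  ver <- as.character(utils::packageVersion("quasimendel"))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=quasimendel-", ver),
           if (!is.null(seed)) paste0("##quasimendel_seed=", seed),
           if (!is.null(config_hash)) paste0("##quasimendel_config=", config_hash),
           "##contig=<ID=chrS,length=250000000>",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
           "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
           "##INFO=<ID=ExcessHet,Number=1,Type=Float,Description=\"Phred-scaled heterozygote excess\">",
           "##FILTER=<ID=VQSR_FAIL,Description=\"Failed variant quality score recalibration\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], n, L)
  gt[is.na(g)] <- "./."
  if (!is.null(ann)) {
    s <- ann$sites
    info <- sprintf(
      "QD=%.4g;FS=%.4g;MQ=%.4g;MQRankSum=%.4g;ReadPosRankSum=%.4g;SOR=%.4g;ExcessHet=%.4g",
      s$QD, s$FS, s$MQ, s$MQRankSum, s$ReadPosRankSum, s$SOR, s$ExcessHet)
    filt <- ifelse(s$vqsr_pass, "PASS", "VQSR_FAIL")
    fmt <- "GT:DP:GQ"
    sample_cols <- matrix(paste(gt, ann$dp, ann$gq, sep = ":"), n, L)
  } else {
    info <- rep(".", L)
    filt <- rep("PASS", L)
    fmt <- "GT"
    sample_cols <- gt
  }
  body <- vapply(seq_len(L), function(j) {
    paste(c("chrS", 1000L * j, colnames(g)[j], "A", "T", ".", filt[j],
            info[j], fmt, sample_cols[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal-dialect VCF into a genotype matrix and annotations
#'
#' Parsing is delegated to \pkg{vcfR}; the result is re-shaped into the
#' package's individuals-by-variants containers.  DP/GQ and the INFO site
#' metrics are returned only when present in the file.
#'
#' @param path VCF file (plain text).
#' @return List with `genotypes` (integer dosage matrix, individuals x
#'   variants) and `annotations` (a `call_annotations`-shaped list, or
#'   `NULL` when the file carries only GT).
#' @export
read_cohort_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[gt %in% c("0/0", "0|0")] <- 0L
  dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[gt %in% c("1/1", "1|1")] <- 2L
  ids <- v@fix[, "ID"]
  rownames(dose) <- ids
  g <- t(dose)  # individuals x variants
  storage.mode(g) <- "integer"
  fmt <- v@gt[1, "FORMAT"]
  ann <- NULL
  if (grepl("DP", fmt) && grepl("GQ", fmt)) {
    dp <- t(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    gq <- t(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
    colnames(dp) <- colnames(gq) <- ids
    keys <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR",
              "ExcessHet")
    info <- lapply(keys, function(k)
      as.numeric(vcfR::extract.info(v, element = k)))
    names(info) <- keys
    sites <- data.frame(variant = ids, info, stringsAsFactors = FALSE)
    sites$vqsr_pass <- v@fix[, "FILTER"] %in% c("PASS", ".")
    ann <- structure(list(dp = dp, gq = gq, sites = sites, truth = NULL),
                     class = "call_annotations")
  }
  list(genotypes = g, annotations = ann)
}

#' Validate a VCF file against the package's minimal dialect
#'
#' Line-oriented checks: VCF 4.2 file declaration, presence and shape of
#' the `#CHROM` header, constant column count, FORMAT restricted to
#' `GT` or `GT:DP:GQ`, genotype calls of the form `x/y` or `./.`, FILTER
#' vocabulary `PASS`/`VQSR_FAIL`/`.`, and (for annotated files) the seven
#' required INFO keys.
#'
#' @param path File to check.
#' @return Data.frame with columns `line` and `problem`; zero rows when
#'   the file is clean.
#' @export
validate_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  problems <- list()
  note <- function(line, problem) {
    problems[[length(problems) + 1L]] <<- data.frame(
      line = line, problem = problem, stringsAsFactors = FALSE)
  }
  if (!length(lines) || !startsWith(lines[1L], "##fileformat=VCFv4.2")) {
    note(1L, "missing ##fileformat=VCFv4.2 declaration")
  }
  chrom_at <- which(startsWith(lines, "#CHROM"))
  if (!length(chrom_at)) {
    note(length(lines), "missing #CHROM header line")
    return(do.call(rbind, problems))
  }
  chrom_at <- chrom_at[1L]
  cols <- strsplit(lines[chrom_at], "\t", fixed = TRUE)[[1L]]
  fixed_names <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT")
  if (length(cols) < 10L || !identical(cols[1:9], fixed_names)) {
    note(chrom_at, "malformed #CHROM header (expect 9 fixed columns + samples)")
  }
  ncol_expected <- length(cols)
  need_info <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR",
                 "ExcessHet")
  for (i in seq_along(lines)) {
    if (i <= chrom_at || startsWith(lines[i], "#")) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != ncol_expected) {
      note(i, sprintf("expected %d columns, found %d", ncol_expected, length(f)))
      next
    }
    if (!f[7L] %in% c("PASS", "VQSR_FAIL", ".")) {
      note(i, paste0("FILTER outside dialect vocabulary: ", f[7L]))
    }
    if (!f[9L] %in% c("GT", "GT:DP:GQ")) {
      note(i, paste0("FORMAT must be GT or GT:DP:GQ, found ", f[9L]))
    }
    if (f[9L] == "GT:DP:GQ" && f[8L] != ".") {
      keys <- sub("=.*$", "", strsplit(f[8L], ";", fixed = TRUE)[[1L]])
      miss <- setdiff(need_info, keys)
      if (length(miss)) {
        note(i, paste0("missing INFO key(s): ", paste(miss, collapse = ",")))
      }
    }
    calls <- f[10:ncol_expected]
    gt <- sub(":.*$", "", calls)
    bad <- !grepl("^([0-9]+[/|][0-9]+|\\./\\.)$", gt)
    if (any(bad)) note(i, paste0(sum(bad), " malformed genotype call(s)"))
    if (f[9L] == "GT:DP:GQ") {
      nfield <- lengths(strsplit(calls, ":", fixed = TRUE))
      if (any(nfield != 3L)) {
        note(i, paste0(sum(nfield != 3L), " call(s) missing DP/GQ fields"))
      }
    }
  }
  out <- if (length(problems)) do.call(rbind, problems) else
    data.frame(line = integer(0), problem = character(0),
               stringsAsFactors = FALSE)
  out
}
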