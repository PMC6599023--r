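tiny_loci <- function() {
  allele_table(
    id = c("m1", "m2", "m3", "SEV", "MODA", "MODB", "NEU"),
    gene = c("RP1", "RP1", "RP1", "EYS", "G1", "G2", "G3"),
    q = c(0.001, 0.0005, 0.006, 0.017, 0.01, 0.01, 0.02),
    w = c(1, 1, 0.5, 1, 0.5, 0.5, 0),
    klass = c("severe_null", "severe_null", "hypomorph", "modifier",
              "modifier", "modifier", "neutral"))
}

tiny_config <- function(...) {
  loci <- tiny_loci()
  cohort_config(n_cases = 10, n_controls = 50, loci = loci,
                index_id = "m3", same_gene_ids = c("m1", "m2"), ...)
}

test_that("allele table validation enforces the invariants", {
  expect_error(allele_table("v", "G", q = 0, w = 1, klass = "neutral"),
               "strictly in")
  expect_error(allele_table("v", "G", q = 0.1, w = 1.2, klass = "neutral"),
               "\\[0, 1\\]")
  expect_error(allele_table("v", "G", q = 0.1, w = 0.5, klass = "severe_null"),
               "weight 1")
  expect_error(allele_table(c("v", "v"), "G", q = 0.1, w = 0, klass = "neutral"),
               "unique")
  loci <- default_hrd_loci()
  expect_equal(nrow(loci), 205)
  in_window <- loci$q >= 0.001 & loci$q <= 0.05 &
    loci$gene %in% default_panel_genes() & loci$id != "rs118031911"
  expect_equal(sum(in_window), 178)
})

test_that("genotype sampling is reproducible and HWE-consistent", {
  loci <- tiny_loci()
  g1 <- sample_genotypes(loci, 100, seed = 8)
  g2 <- sample_genotypes(loci, 100, seed = 8)
  g3 <- sample_genotypes(loci, 100, seed = 9)
  expect_identical(g1, g2)
  expect_false(identical(g1, g3))

  # q = 0.5: genotype proportions within 4 SE of (0.25, 0.5, 0.25)
  half <- data.frame(id = "h", q = 0.5)
  g <- sample_genotypes(half, 10000, seed = 2)
  counts <- tabulate(g + 1L, 3)
  se <- sqrt(10000 * c(.25, .5, .25) * c(.75, .5, .75))
  expect_true(all(abs(counts - 10000 * c(.25, .5, .25)) < 4 * se))

  # the control-panel scale: heterozygote count near 2nq(1-q) ~ 148
  rare <- data.frame(id = "m3", q = 0.006)
  g <- sample_genotypes(rare, 12379, seed = 3)
  expect_lt(abs(sum(g == 1L) - 2 * 12379 * 0.006 * 0.994),
            4 * sqrt(2 * 12379 * 0.006 * 0.994))

  # q -> 0 limit: essentially all-reference
  tiny <- data.frame(id = "x", q = 1e-9)
  expect_true(all(sample_genotypes(tiny, 100, seed = 1) == 0L))
  expect_error(sample_genotypes(data.frame(id = "x", q = 1.0), 5, seed = 1),
               "strictly in")
})

test_that("load-threshold phenotype reproduces the genotype-phenotype facts", {
  loci <- tiny_loci()
  model <- penetrance_model(loci)
  g <- matrix(0L, nrow = 7, ncol = nrow(loci),
              dimnames = list(c("m1m1", "m1m2", "m1m3", "m3m3", "m3het",
                                "m3_plus_sev", "sev_hom"), loci$id))
  g["m1m1", "m1"] <- 2L
  g["m1m2", c("m1", "m2")] <- 1L
  g["m1m3", c("m1", "m3")] <- 1L
  g["m3m3", "m3"] <- 2L
  g["m3het", "m3"] <- 1L
  g["m3_plus_sev", c("m3", "SEV")] <- 1L
  g["sev_hom", "SEV"] <- 2L
  aff <- assign_phenotype(g, model)
  expect_identical(unname(aff),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  # a single moderate modifier allele alone is benign
  g2 <- matrix(0L, 1, nrow(loci), dimnames = list("modhet", loci$id))
  g2[, "MODA"] <- 1L
  expect_false(assign_phenotype(g2, model)[[1]])
  # two moderate modifiers plus the hypomorph cross the threshold
  g2[, c("MODA", "MODB", "m3")] <- 1L
  expect_true(assign_phenotype(g2, model)[[1]])
  # missing weight is an error
  g3 <- cbind(g2, UNKNOWN = 1L)
  expect_error(assign_phenotype(g3, model), "weights")
})

test_that("ascertained cohorts satisfy the case predicate and are reproducible", {
  cfg <- tiny_config(seed = 5)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$cases), 10)
  expect_equal(nrow(sim$controls), 50)
  expect_true(all(sim$cases[, "m3"] == 1L))
  expect_true(all(sim$cases[, "m1"] == 0L))
  expect_true(all(sim$cases[, "m2"] == 0L))
  expect_true(all(sim$truth$affected[sim$truth$group == "case"]))
  expect_true(all(sim$truth$load[sim$truth$group == "case"] >= 1.5))
  # causal variants recorded for every case
  expect_true(all(nzchar(sim$truth$causal[sim$truth$group == "case"])))
  sim2 <- simulate_cohort(tiny_config(seed = 5))
  expect_identical(sim$cases, sim2$cases)
  expect_identical(sim$controls, sim2$controls)
  sim3 <- simulate_cohort(tiny_config(seed = 6))
  expect_false(identical(sim$cases, sim3$cases))
})

test_that("unsatisfiable ascertainment raises the infeasibility error", {
  loci <- allele_table(id = c("m1", "m2", "m3", "NEU"),
                       gene = c("RP1", "RP1", "RP1", "G1"),
                       q = c(0.001, 0.0005, 0.006, 0.02),
                       w = c(1, 1, 0.5, 0), klass = c("severe_null",
                       "severe_null", "hypomorph", "neutral"))
  cfg <- cohort_config(n_cases = 2, n_controls = 5, loci = loci,
                       index_id = "m3", same_gene_ids = c("m1", "m2"),
                       seed = 1)
  expect_error(simulate_cohort(cfg), "infeasible")
})

test_that("population-mode genotypes show no linkage disequilibrium", {
  loci <- data.frame(id = c("A", "B"), q = c(0.2, 0.3))
  g <- sample_genotypes(loci, 50000, seed = 17)
  expect_lt(cor(g[, 1], g[, 2])^2, 0.01)
})

test_that("annotation simulation plants exactly what it records", {
  g <- sample_genotypes(tiny_loci(), 100, seed = 20)
  clean <- simulate_annotations(g, seed = 21)
  expect_true(all(clean$dp >= 8))
  expect_true(all(clean$gq >= 20))
  expect_true(all(clean$sites$QD >= 2 & clean$sites$FS <= 60 &
                    clean$sites$MQ >= 40 & clean$sites$SOR <= 3 &
                    clean$sites$ExcessHet <= 20 & clean$sites$vqsr_pass))
  expect_equal(sum(clean$truth$mask_expected), 0)
  expect_equal(nrow(clean$truth$sites), 0)

  wide <- sample_genotypes(tiny_loci()[rep(1, 10), ] |>
                             transform(id = sprintf("V%02d", 1:10)),
                           100, seed = 22)
  ann <- simulate_annotations(wide, fail_rates = c(dp = 0.1), seed = 23)
  expect_equal(sum(ann$dp < 8), ann$truth$n_dp)
  expect_equal(sum(ann$truth$mask_expected), ann$truth$n_dp)
  # ExcessHet is an honest function of the genotypes
  j <- 3
  v <- wide[, j]
  expect_equal(ann$sites$ExcessHet[j],
               -10 * log10(hwe_excess_het(sum(v == 0), sum(v == 1),
                                          sum(v == 2))))
  expect_error(simulate_annotations(wide, fail_rates = c(bogus = 0.1)),
               "unknown fail rate")
  expect_error(simulate_annotations(wide, fail_rates = c(dp = 1.5)),
               "\\[0, 1\\]")
})
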