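# The synthetic-cohort generator: determinism, study-condition parameters,
# planted carrier exactness, noise laws.

test_that("cohort has the configured sizes and ages at the study means", {
  spec <- cohort_spec(seed = 7)
  samples <- generate_cohort(spec)
  expect_equal(nrow(samples), 1533)
  expect_equal(sum(samples$phenotype == "case"), 1202)
  expect_equal(sum(samples$phenotype == "control"), 331)
  expect_false(anyDuplicated(samples$sample_id) > 0)
  expect_true(all(samples$age > 0))
  # sample mean within 3 standard errors of the configured mean
  case_age <- samples$age[samples$phenotype == "case"]
  ctrl_age <- samples$age[samples$phenotype == "control"]
  expect_lt(abs(mean(case_age) - 52.9), 3 * 16.4 / sqrt(1202))
  expect_lt(abs(mean(ctrl_age) - 38.7), 3 * 17.2 / sqrt(331))
})

test_that("an empty cohort is an empty data frame, not an error", {
  spec <- cohort_spec(n_cases = 0, n_controls = 0, planted_gene = NULL,
                      planted_case_carriers = 0)
  expect_equal(nrow(generate_cohort(spec)), 0)
})

test_that("generation is deterministic given the seed", {
  spec <- tiny_spec(seed = 99)
  d1 <- simulate_dataset(spec)
  d2 <- simulate_dataset(spec)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(tiny_spec(seed = 100))
  expect_false(identical(d1$genotypes$allele_count,
                         d3$genotypes$allele_count))
})

test_that("invalid specs name the offending field", {
  expect_error(cohort_spec(n_cases = -1), "n_cases")
  expect_error(cohort_spec(stratum_weights = c(0.5, 0.4)), "stratum_weights")
  expect_error(cohort_spec(rare_maf_bounds = c(0, 0.5)), "rare_maf_bounds")
  expect_error(cohort_spec(planted_case_carriers = 2000), "planted_case_carriers")
  expect_error(cohort_spec(missingness_rate = 1.5), "missingness_rate")
  expect_error(generate_variant_sites(
    cohort_spec(n_genes = 0, planted_gene = NULL)), "n_genes")
})

test_that("per-gene site counts follow the configured Poisson law", {
  spec <- cohort_spec(n_genes = 100, variants_per_gene_rate = 30,
                      planted_gene = NULL, n_common_variants = 0, seed = 3)
  sites <- generate_variant_sites(spec)
  # sum of 100 Poisson(30) draws: within 4 SD of 3000
  expect_lt(abs(nrow(sites) - 3000), 4 * sqrt(3000))
  expect_true(all(sites$pop_maf >= 1e-6 & sites$pop_maf <= 1e-2))
})

test_that("zero QC-failure fractions give sites that all pass site filters", {
  spec <- tiny_spec(qc_fail_fractions = list(non_pass = 0, low_call_rate = 0,
                                             decoy = 0, multiallelic = 0,
                                             long_span = 0,
                                             high_missingness = 0))
  sites <- generate_variant_sites(spec)
  expect_true(all(site_passes(sites, rep(0, nrow(sites))) == "pass"))
})

test_that("decoy assignment is a reproducible seeded draw", {
  spec <- cohort_spec(n_genes = 100, variants_per_gene_rate = 10,
                      planted_gene = NULL, n_common_variants = 0,
                      qc_fail_fractions = list(decoy = 0.1), seed = 12)
  s1 <- generate_variant_sites(spec)
  s2 <- generate_variant_sites(spec)
  expect_identical(s1$in_decoy, s2$in_decoy)
  expect_gt(sum(s1$in_decoy), 0)
})

test_that("zero allele frequency and no planting yields no carriers", {
  spec <- tiny_spec(rare_maf_bounds = c(1e-12, 1e-11), planted_gene = NULL,
                    n_common_variants = 0, missingness_rate = 0,
                    qc_fail_fractions = list(high_missingness = 0))
  d <- simulate_dataset(spec)
  expect_true(all(d$genotypes$allele_count == 0))
})

test_that("planted carrier counts are exact after QC, at full cohort scale", {
  spec <- cohort_spec(seed = 19)   # 1202/331, planted 21/0
  d <- simulate_dataset(spec)
  qc <- apply_qc(d$samples, d$sites, d$genotypes)
  qual <- select_qualifying(qc$sites)
  cm <- collapse_carriers(qc$genotypes, qual, d$samples)
  cnt <- cm$counts[cm$counts$gene == "GENE001", ]
  expect_equal(cnt$case_carriers, 21L)
  expect_equal(cnt$control_carriers, 0L)
  # brute-force recount straight from the genotype records
  qvid <- paste(qual$chrom, qual$pos, qual$ref, qual$alt, sep = ":")
  qvid <- qvid[qual$gene == "GENE001"]
  g <- qc$genotypes
  hits <- g[g$variant_id %in% qvid & !is.na(g$allele_count) &
              g$allele_count == 1, "sample_id"]
  pheno <- d$samples$phenotype[match(unique(hits), d$samples$sample_id)]
  expect_equal(sum(pheno == "case"), 21L)
  expect_equal(sum(pheno == "control"), 0L)
})

test_that("planted case carriers follow the younger index-patient age law", {
  spec <- cohort_spec(seed = 23)
  d <- simulate_dataset(spec)
  qc <- apply_qc(d$samples, d$sites, d$genotypes)
  cm <- collapse_carriers(qc$genotypes, select_qualifying(qc$sites), d$samples)
  carriers <- colnames(cm$matrix)[cm$matrix["GENE001", ] == 1]
  ages <- d$samples$age[match(carriers, d$samples$sample_id)]
  # mean 34.4, SD 17.5, n = 21: allow 3 standard errors
  expect_lt(abs(mean(ages) - 34.4), 3 * 17.5 / sqrt(21))
})

test_that("background carrier frequency converges to the site frequency", {
  spec <- cohort_spec(n_cases = 3000, n_controls = 0, n_genes = 1,
                      variants_per_gene_rate = 1, planted_gene = NULL,
                      n_common_variants = 10, missingness_rate = 0,
                      qc_fail_fractions = list(high_missingness = 0),
                      n_strata = 1, stratum_weights = 1, seed = 31)
  d <- simulate_dataset(spec)
  freqs <- attr(d$sites, "stratum_freqs")[, 1]
  vid <- paste(d$sites$chrom, d$sites$pos, d$sites$ref, d$sites$alt, sep = ":")
  for (j in seq_along(vid)) {
    g <- d$genotypes[d$genotypes$variant_id == vid[j], ]
    phat <- mean(g$allele_count)
    se <- sqrt(freqs[j] * (1 - freqs[j]) / 3000)
    expect_lt(abs(phat - freqs[j]), 4 * se + 1e-6)
  }
})

test_that("low-depth call fraction matches the depth law's CDF", {
  gn <- list(dp_mean = 40, dp_size = 20, gq_mean = 85, gq_sd = 10,
             low_dp_rate = 0.05, low_gq_rate = 0, mrr_fail_rate = 0,
             ab_shape = 25, ref_error_rate = 0.002)
  spec <- cohort_spec(n_cases = 500, n_controls = 0, n_genes = 20,
                      variants_per_gene_rate = 10, planted_gene = NULL,
                      n_common_variants = 0, missingness_rate = 0,
                      qc_fail_fractions = list(high_missingness = 0),
                      genotype_noise = gn, seed = 41)
  d <- simulate_dataset(spec)
  p_emp <- mean(d$genotypes$depth < 8)
  p_theory <- (1 - gn$low_dp_rate) * pnbinom(7, size = gn$dp_size, mu = gn$dp_mean) +
    gn$low_dp_rate * ppois(7, 4)
  n <- nrow(d$genotypes)
  expect_lt(abs(p_emp - p_theory), 4 * sqrt(p_theory * (1 - p_theory) / n))
})
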