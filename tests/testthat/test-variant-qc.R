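# Genotype- and site-level filter semantics, boundaries, and accounting.

test_that("genotype filters fail exactly the quoted strict inequalities", {
  cases <- list(
    # depth, gq, ref, alt -> expected reason
    list(7, 99, 4, 3, "depth"),     # coverage < 8X
    list(8, 99, 4, 4, "pass"),      # boundary depth passes
    list(50, 19, 25, 25, "gq"),     # GQ < 20
    list(50, 20, 25, 25, "pass"),   # boundary GQ passes
    list(50, 80, 45, 5, "mrr"),     # MRR = 0.10 < 0.20
    list(8, 20, 6, 2, "pass"),      # MRR = 0.25, both boundaries met
    list(50, 80, 40, 10, "pass"),   # MRR exactly 0.20 passes
    list(50, 80, 5, 45, "mrr"),     # minor allele can be the reference
    list(7, 10, 1, 1, "depth"),     # first reason in order wins
    list(40, 90, 0, 0, "malformed") # no informative reads
  )
  for (cs in cases) {
    expect_equal(genotype_passes(cs[[1]], cs[[2]], cs[[3]], cs[[4]]),
                 cs[[5]], info = paste(unlist(cs), collapse = "/"))
  }
})

test_that("site filters fail exactly the quoted strict inequalities, in order", {
  s <- make_sites(8)
  s$pop_call_rate <- c(0.49, 0.50, 0.99, 0.99, 0.99, 0.99, 0.99, 0.20)
  s$pass_flag <-     c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)
  s$in_decoy <-      c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  s$n_alleles <-     c(2L, 4L, 2L, 2L, 5L, 2L, 2L, 2L)
  s$span_nt <-       c(1L, 20L, 1L, 1L, 1L, 21L, 1L, 1L)
  miss <-            c(0, 0.20, 0, 0, 0, 0, 0.21, 0)
  expect_equal(site_passes(s, miss),
               c("ref_callrate", "pass", "non_pass", "decoy", "multiallelic",
                 "span", "missingness", "ref_callrate"))
})

test_that("missing site annotation fields raise a naming error", {
  s <- make_sites(2)
  s$pass_flag <- NULL
  expect_error(site_passes(s, c(0, 0)), "pass_flag")
  s2 <- make_sites(2)
  s2$n_alleles[2] <- NA
  expect_error(site_passes(s2, c(0, 0)), "n_alleles")
})

test_that("apply_qc masks, recomputes missingness, and reconciles exactly", {
  samples <- make_samples(6, 4)
  # 4 sites: clean / decoy / clean / non-pass
  sites <- make_sites(4)
  sites$in_decoy[2] <- TRUE
  sites$pass_flag[4] <- FALSE
  ac <- matrix(0L, 10, 4)
  ac[1, 1] <- 1L; ac[2, 3] <- 1L
  g <- make_genotypes(samples, sites, ac)
  # one low-depth call, one low-GQ call, one imbalanced carrier call,
  # one malformed, one already missing
  g$depth[1] <- 5L
  g$gq[12] <- 3L
  v3 <- which(g$variant_id == g$variant_id[21] & g$sample_id == "CASE002")
  g$ref_reads[v3] <- 39L; g$alt_reads[v3] <- 1L        # carrier, MRR 0.025
  g$ref_reads[15] <- 0L; g$alt_reads[15] <- 0L
  g$allele_count[30] <- NA_integer_

  qc <- apply_qc(samples, sites, g)
  rep <- qc$report
  expect_equal(rep$genotype_total, 40)
  expect_equal(unname(rep$genotype_masked["depth"]), 1)
  expect_equal(unname(rep$genotype_masked["gq"]), 1)
  expect_equal(unname(rep$genotype_masked["mrr"]), 1)
  expect_equal(unname(rep$genotype_masked["malformed"]), 1)
  expect_equal(rep$genotype_already_missing, 1)
  expect_equal(rep$genotype_retained +
                 rep$genotype_already_missing + sum(rep$genotype_masked),
               rep$genotype_total)
  expect_equal(unname(rep$site_removed["decoy"]), 1)
  expect_equal(unname(rep$site_removed["non_pass"]), 1)
  expect_equal(rep$site_retained + sum(rep$site_removed), rep$site_total)
  # masked calls are missing, not dropped
  expect_equal(nrow(qc$genotypes), 10 * rep$site_retained)
  expect_true(anyNA(qc$genotypes$allele_count))
})

test_that("MRR masking applies to variant calls only by default", {
  samples <- make_samples(2, 1)
  sites <- make_sites(1)
  ac <- matrix(c(0L, 1L, 0L), 3, 1)
  g <- make_genotypes(samples, sites, ac)
  # all calls read-imbalanced: hom-ref legitimately so, the carrier not
  g$ref_reads <- c(39L, 39L, 39L)
  g$alt_reads <- c(1L, 1L, 1L)
  qc <- apply_qc(samples, sites, g)
  expect_equal(unname(qc$report$genotype_masked["mrr"]), 1)
  qc_all <- apply_qc(samples, sites, g, mrr_scope = "all_calls")
  expect_equal(unname(qc_all$report$genotype_masked["mrr"]), 3)
})

test_that("high cohort missingness removes the site after genotype masking", {
  samples <- make_samples(6, 4)
  sites <- make_sites(2)
  ac <- matrix(0L, 10, 2)
  g <- make_genotypes(samples, sites, ac)
  # site 1: 3/10 calls fail depth -> missingness 0.3 > 0.2
  idx <- which(g$variant_id == g$variant_id[1])[1:3]
  g$depth[idx] <- 4L
  qc <- apply_qc(samples, sites, g)
  expect_equal(unname(qc$report$site_removed["missingness"]), 1)
  expect_equal(qc$report$site_retained, 1)
  # with site-first ordering the pre-masking missingness (0) is used
  qc2 <- apply_qc(samples, sites, g, site_filter_order = "site_first")
  expect_equal(unname(qc2$report$site_removed["missingness"]), 0)
})

test_that("QC is idempotent and extreme thresholds disable all filters", {
  spec <- tiny_spec()
  d <- simulate_dataset(spec)
  qc1 <- apply_qc(d$samples, d$sites, d$genotypes)
  qc2 <- apply_qc(d$samples, qc1$sites, qc1$genotypes)
  expect_equal(qc2$genotypes, qc1$genotypes)
  expect_equal(qc2$sites, qc1$sites)
  expect_equal(sum(qc2$report$genotype_masked), 0)
  expect_equal(sum(qc2$report$site_removed), 0)

  # extreme thresholds turn the pipeline into the identity (the boolean
  # non-PASS/decoy flags are annotation, so the fixture keeps them clean)
  spec0 <- tiny_spec(qc_fail_fractions = list(non_pass = 0, low_call_rate = 0,
                                              decoy = 0, multiallelic = 0,
                                              long_span = 0,
                                              high_missingness = 0))
  d0 <- simulate_dataset(spec0)
  off <- qc_thresholds(min_depth = 0, min_gq = 0, min_mrr = 0,
                       min_pop_call_rate = 0, max_cohort_missingness = 1,
                       max_alleles = 10000L, max_span_nt = 100000L)
  qc0 <- apply_qc(d0$samples, d0$sites, d0$genotypes, thresholds = off)
  expect_equal(qc0$genotypes$allele_count, d0$genotypes$allele_count)
  expect_equal(nrow(qc0$sites), nrow(d0$sites))
})

test_that("genotype removal count equals a brute-force recount", {
  spec <- tiny_spec(seed = 77,
                    genotype_noise = list(dp_mean = 12, dp_size = 8,
                                          gq_mean = 85, gq_sd = 10,
                                          low_dp_rate = 0.10, low_gq_rate = 0,
                                          mrr_fail_rate = 0, ab_shape = 400,
                                          ref_error_rate = 0))
  d <- simulate_dataset(spec)
  g <- d$genotypes
  nonmiss <- !is.na(g$allele_count)
  expected_depth <- sum(nonmiss & g$depth < 8 & g$ref_reads + g$alt_reads > 0)
  qc <- apply_qc(d$samples, d$sites, g)
  expect_equal(unname(qc$report$genotype_masked["depth"]), expected_depth)
})

test_that("every filter fires at least once on the default synthetic cohort", {
  spec <- cohort_spec(n_cases = 250, n_controls = 120, n_genes = 30,
                      planted_case_carriers = 5, seed = 400)
  d <- simulate_dataset(spec)
  qc <- apply_qc(d$samples, d$sites, d$genotypes)
  expect_true(all(qc$report$genotype_masked[c("depth", "gq", "mrr")] >= 1))
  expect_true(all(qc$report$site_removed >= 1))
})

test_that("orphan genotype records are a structural error", {
  samples <- make_samples(2, 1)
  sites <- make_sites(1)
  g <- make_genotypes(samples, sites, matrix(0L, 3, 1))
  g$sample_id[1] <- "GHOST"
  expect_error(apply_qc(samples, sites, g), "orphan")
})
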