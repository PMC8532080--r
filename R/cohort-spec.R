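#' Specification of a synthetic male case/control cohort
#'
#' Bundles every parameter of the synthetic-data generator. Defaults mirror
#' the design of a published X-linked screen of critical COVID-19 pneumonia:
#' 1,202 male cases (age mean 52.9 y, SD 16.4) and 331 male controls (age
#' mean 38.7 y, SD 17.2), a planted enriched gene with 21 case carriers and 0
#' control carriers, and per-variant population MAFs drawn log-uniformly over
#' 1e-6..1e-2. Gene architecture (60 genes, Poisson(10) rare variants per
#' gene, 150 common ancestry-informative variants across 3 strata) is the
#' package's own desk-scale default.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param age_case_mean,age_case_sd,age_control_mean,age_control_sd age laws
#'   (normal, truncated at 0.5 years).
#' @param n_strata number of discrete ancestry strata.
#' @param stratum_weights probability vector over strata (sums to 1).
#' @param n_genes number of genes carrying rare variants.
#' @param variants_per_gene_rate Poisson mean of rare variants per gene.
#' @param rare_maf_bounds length-2 bounds of the log-uniform population MAF law.
#' @param planted_gene gene id to enrich, or `NULL` for a null cohort.
#' @param planted_case_carriers,planted_control_carriers exact carrier counts
#'   planted into the enriched gene.
#' @param planted_age_mean,planted_age_sd age law of the planted case
#'   carriers. A highly penetrant X-linked deficiency strikes younger men than
#'   the general critical-disease cohort, so carrier ages are redrawn from
#'   their own truncated normal (defaults 34.4 y mean, 17.5 y SD, the index
#'   patients' age distribution); set to `NULL` to leave carrier ages at the
#'   case law.
#' @param n_common_variants common variants used for ancestry PCA.
#' @param fst Balding-Nichols differentiation of common-variant frequencies
#'   across strata.
#' @param qc_fail_fractions named list of per-site failure fractions:
#'   `non_pass`, `low_call_rate`, `decoy`, `multiallelic`, `long_span`,
#'   `high_missingness` (sites whose cohort genotypes are missing at an
#'   elevated 40% rate, so the site-missingness filter has work to do).
#' @param genotype_noise named list: `dp_mean`, `dp_size` (negative-binomial
#'   depth law), `gq_mean`, `gq_sd`, `low_dp_rate`, `low_gq_rate`,
#'   `mrr_fail_rate`, `ab_shape` (Beta(ab_shape, ab_shape) carrier allelic
#'   balance), `ref_error_rate` (alt reads on non-carrier calls).
#' @param missingness_rate probability a genotype call is missing outright.
#' @param seed integer seed; every generator draw is a deterministic function
#'   of the spec including this seed.
#' @return An object of class `cohort_spec` (validated list).
#' @export
cohort_spec <- function(n_cases = 1202, n_controls = 331,
                        age_case_mean = 52.9, age_case_sd = 16.4,
                        age_control_mean = 38.7, age_control_sd = 17.2,
                        n_strata = 3,
                        stratum_weights = rep(1 / n_strata, n_strata),
                        n_genes = 60,
                        variants_per_gene_rate = 10,
                        rare_maf_bounds = c(1e-6, 1e-2),
                        planted_gene = "GENE001",
                        planted_case_carriers = 21,
                        planted_control_carriers = 0,
                        planted_age_mean = 34.4,
                        planted_age_sd = 17.5,
                        n_common_variants = 150,
                        fst = 0.15,
                        qc_fail_fractions = list(non_pass = 0.02,
                                                 low_call_rate = 0.02,
                                                 decoy = 0.02,
                                                 multiallelic = 0.02,
                                                 long_span = 0.02,
                                                 high_missingness = 0.02),
                        genotype_noise = list(dp_mean = 40, dp_size = 20,
                                              gq_mean = 85, gq_sd = 10,
                                              low_dp_rate = 0.002,
                                              low_gq_rate = 0.002,
                                              mrr_fail_rate = 0.002,
                                              ab_shape = 25,
                                              ref_error_rate = 0.002),
                        missingness_rate = 0.002,
                        seed = 1L) {
  spec <- list(n_cases = check_count(n_cases, "n_cases"),
               n_controls = check_count(n_controls, "n_controls"),
               age_case_mean = age_case_mean, age_case_sd = age_case_sd,
               age_control_mean = age_control_mean,
               age_control_sd = age_control_sd,
               n_strata = check_count(n_strata, "n_strata", positive = TRUE),
               stratum_weights = stratum_weights,
               n_genes = check_count(n_genes, "n_genes"),
               variants_per_gene_rate = variants_per_gene_rate,
               rare_maf_bounds = rare_maf_bounds,
               planted_gene = planted_gene,
               planted_case_carriers =
                 check_count(planted_case_carriers, "planted_case_carriers"),
               planted_control_carriers =
                 check_count(planted_control_carriers, "planted_control_carriers"),
               planted_age_mean = planted_age_mean,
               planted_age_sd = planted_age_sd,
               n_common_variants = check_count(n_common_variants, "n_common_variants"),
               fst = fst,
               qc_fail_fractions = qc_fail_fractions,
               genotype_noise = genotype_noise,
               missingness_rate = check_prob(missingness_rate, "missingness_rate"),
               seed = check_count(seed, "seed"))

  if (length(spec$stratum_weights) != spec$n_strata) {
    stop_config("stratum_weights", "must have one weight per stratum")
  }
  if (any(spec$stratum_weights < 0) ||
      abs(sum(spec$stratum_weights) - 1) > 1e-12) {
    stop_config("stratum_weights", "must be non-negative and sum to 1 (within 1e-12)")
  }
  if (length(spec$rare_maf_bounds) != 2 ||
      any(spec$rare_maf_bounds <= 0) || any(spec$rare_maf_bounds >= 1) ||
      spec$rare_maf_bounds[1] > spec$rare_maf_bounds[2]) {
    stop_config("rare_maf_bounds", "must be increasing bounds in (0,1)")
  }
  if (spec$planted_case_carriers > spec$n_cases) {
    stop_config("planted_case_carriers", "exceeds n_cases")
  }
  if (spec$planted_control_carriers > spec$n_controls) {
    stop_config("planted_control_carriers", "exceeds n_controls")
  }
  if (!is.null(spec$planted_gene) && spec$n_genes < 1) {
    stop_config("planted_gene", "requires n_genes >= 1")
  }
  if (spec$variants_per_gene_rate < 0) {
    stop_config("variants_per_gene_rate", "must be non-negative")
  }
  for (f in c("non_pass", "low_call_rate", "decoy", "multiallelic",
              "long_span", "high_missingness")) {
    check_prob(spec$qc_fail_fractions[[f]] %||% 0, paste0("qc_fail_fractions$", f))
  }
  for (f in c("low_dp_rate", "low_gq_rate", "mrr_fail_rate", "ref_error_rate")) {
    check_prob(spec$genotype_noise[[f]] %||% 0, paste0("genotype_noise$", f))
  }
  if ((spec$genotype_noise$dp_mean %||% 0) <= 0) {
    stop_config("genotype_noise$dp_mean", "must be positive")
  }
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: %d cases / %d controls, %d genes, %d strata, seed %d\n",
              x$n_cases, x$n_controls, x$n_genes, x$n_strata, x$seed))
  if (!is.null(x$planted_gene)) {
    cat(sprintf("  planted: %s with %d case / %d control carriers\n",
                x$planted_gene, x$planted_case_carriers, x$planted_control_carriers))
  }
  invisible(x)
}
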