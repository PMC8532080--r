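# Synthetic-cohort generator. Emulates the statistical structure the burden
# analysis assumes: male-only hemizygous genotypes (0/1), case/control age
# laws, discrete ancestry strata with differentiated common-variant
# frequencies (so that PCA covariates are meaningful), per-gene rare-variant
# architecture with a planted enriched gene, and genotype-level noise
# (depth, GQ, allelic read counts, missingness) rich enough to exercise every
# QC filter. All draws are deterministic functions of the spec's seed.

rtnorm_pos <- function(n, mean, sd, lower = 0.5) {
  # truncated-at-lower normal by rejection; vectorized resampling
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

#' Generate the samples of a synthetic cohort
#'
#' Ages are drawn from normal laws truncated at 0.5 years (the youngest
#' plausible patient); strata are assigned by the spec's stratum weights.
#'
#' @param spec a [cohort_spec()].
#' @return Data frame: `sample_id`, `phenotype` ("case"/"control"), `age`,
#'   `stratum`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_cases + spec$n_controls
    if (n == 0) {
      return(data.frame(sample_id = character(), phenotype = character(),
                        age = numeric(), stratum = character(),
                        stringsAsFactors = FALSE))
    }
    ids <- c(sprintf("CASE%05d", seq_len(spec$n_cases)),
             sprintf("CTRL%05d", seq_len(spec$n_controls)))
    pheno <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
    age <- c(rtnorm_pos(spec$n_cases, spec$age_case_mean, spec$age_case_sd),
             rtnorm_pos(spec$n_controls, spec$age_control_mean, spec$age_control_sd))
    stratum <- sprintf("S%d", sample.int(spec$n_strata, n, replace = TRUE,
                                         prob = spec$stratum_weights))
    data.frame(sample_id = ids, phenotype = pheno, age = age,
               stratum = stratum, stringsAsFactors = FALSE)
  })
}

#' Generate synthetic X-chromosome variant sites
#'
#' Rare variants per gene follow a Poisson law with the spec's rate; their
#' population MAFs are log-uniform over the spec's bounds, and a configurable
#' fraction of rare sites is given QC-failing metadata (non-PASS, low
#' reference call rate, decoy overlap, >4 alleles, >20 nt span) so every site
#' filter can fire. Common ancestry-informative sites (consequence "other",
#' QC-clean) get Balding-Nichols stratum-specific frequencies, returned as the
#' `"stratum_freqs"` attribute used by [generate_genotypes()].
#'
#' If a planted gene is configured, at least three of its sites are forced to
#' be clean qualifying missense sites so planting always has a target.
#'
#' @param spec a [cohort_spec()].
#' @return Data frame with one row per site: chrom, pos, ref, alt, gene,
#'   consequence, pop_maf, male_maf, pop_call_rate, pass_flag, n_alleles,
#'   span_nt, in_decoy; attribute `stratum_freqs` (sites x strata).
#' @export
generate_variant_sites <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_genes < 1) stop_config("n_genes", "must be >= 1 to generate sites")
  withr::with_seed(spec$seed + 1L, {
    genes <- sprintf("GENE%03d", seq_len(spec$n_genes))
    n_per_gene <- stats::rpois(spec$n_genes, spec$variants_per_gene_rate)

    if (!is.null(spec$planted_gene)) {
      if (!spec$planted_gene %in% genes) {
        stop_config("planted_gene", "not among generated genes")
      }
      gi <- match(spec$planted_gene, genes)
      n_per_gene[gi] <- max(n_per_gene[gi], 3L)
    }

    gene_of <- rep(genes, n_per_gene)
    n_rare <- length(gene_of)
    bases <- c("A", "C", "G", "T")
    qf <- spec$qc_fail_fractions

    make_rare <- function() {
      lo <- log10(spec$rare_maf_bounds[1]); hi <- log10(spec$rare_maf_bounds[2])
      pop_maf <- 10^stats::runif(n_rare, lo, hi)
      long <- stats::runif(n_rare) < (qf$long_span %||% 0)
      span <- ifelse(long, sample(21:40, n_rare, replace = TRUE), 1L)
      ref <- vapply(span, function(s) paste(sample(bases, s, replace = TRUE),
                                            collapse = ""), character(1))
      alt <- vapply(substr(ref, 1, 1), function(b) sample(setdiff(bases, b), 1),
                    character(1))
      cons <- sample(c("lof_annotation", "missense", "inframe_indel",
                       "synonymous", "other"),
                     n_rare, replace = TRUE,
                     prob = c(0.10, 0.55, 0.05, 0.25, 0.05))
      low_cr <- stats::runif(n_rare) < (qf$low_call_rate %||% 0)
      data.frame(
        gene = gene_of,
        consequence = cons,
        pop_maf = pop_maf,
        male_maf = pmin(1, pop_maf * stats::runif(n_rare, 0.8, 1.2)),
        pop_call_rate = ifelse(low_cr, stats::runif(n_rare, 0.20, 0.499),
                               stats::runif(n_rare, 0.97, 1)),
        pass_flag = stats::runif(n_rare) >= (qf$non_pass %||% 0),
        n_alleles = ifelse(stats::runif(n_rare) < (qf$multiallelic %||% 0),
                           sample(5:8, n_rare, replace = TRUE), 2L),
        span_nt = as.integer(span),
        in_decoy = stats::runif(n_rare) < (qf$decoy %||% 0),
        ref = ref, alt = alt,
        stringsAsFactors = FALSE
      )
    }
    rare <- if (n_rare > 0) make_rare() else NULL

    if (!is.null(spec$planted_gene) && n_rare > 0) {
      # guarantee >=3 clean qualifying missense sites in the planted gene
      idx <- which(rare$gene == spec$planted_gene)[1:3]
      rare$consequence[idx] <- "missense"
      rare$pop_maf[idx] <- 10^stats::runif(3, log10(spec$rare_maf_bounds[1]), -4.05)
      rare$male_maf[idx] <- rare$pop_maf[idx]
      rare$pop_call_rate[idx] <- 0.999
      rare$pass_flag[idx] <- TRUE
      rare$n_alleles[idx] <- 2L
      rare$span_nt[idx] <- 1L
      rare$in_decoy[idx] <- FALSE
      rare$ref[idx] <- sample(bases, 3, replace = TRUE)
      rare$alt[idx] <- vapply(rare$ref[idx],
                              function(b) sample(setdiff(bases, b), 1),
                              character(1))
    }

    n_common <- spec$n_common_variants
    common <- NULL
    freqs_common <- NULL
    if (n_common > 0) {
      p_anc <- stats::runif(n_common, 0.05, 0.5)
      fst <- spec$fst
      a <- p_anc * (1 - fst) / fst
      b <- (1 - p_anc) * (1 - fst) / fst
      freqs_common <- matrix(stats::rbeta(n_common * spec$n_strata,
                                          rep(a, spec$n_strata),
                                          rep(b, spec$n_strata)),
                             nrow = n_common, ncol = spec$n_strata)
      fbar <- drop(freqs_common %*% spec$stratum_weights)
      ref <- sample(bases, n_common, replace = TRUE)
      common <- data.frame(
        gene = sample(genes, n_common, replace = TRUE),
        consequence = "other",
        pop_maf = pmin(fbar, 1 - fbar),
        male_maf = pmin(fbar, 1 - fbar),
        pop_call_rate = 0.999,
        pass_flag = TRUE,
        n_alleles = 2L,
        span_nt = 1L,
        in_decoy = FALSE,
        ref = ref,
        alt = vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1)),
        stringsAsFactors = FALSE
      )
    }

    sites <- rbind(rare, common)
    if (is.null(sites) || nrow(sites) == 0) {
      sites <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gene = character(), consequence = character(),
                          pop_maf = numeric(), male_maf = numeric(),
                          pop_call_rate = numeric(), pass_flag = logical(),
                          n_alleles = integer(), span_nt = integer(),
                          in_decoy = logical(), stringsAsFactors = FALSE)
      attr(sites, "stratum_freqs") <- matrix(0, 0, spec$n_strata)
      return(sites)
    }
    n_v <- nrow(sites)
    sites$chrom <- "X"
    # spread positions so sites (including multi-nt spans) never overlap
    sites$pos <- cumsum(sample(50:500, n_v, replace = TRUE) +
                          c(0L, sites$span_nt[-n_v]))
    sites <- sites[, c("chrom", "pos", "ref", "alt", "gene", "consequence",
                       "pop_maf", "male_maf", "pop_call_rate", "pass_flag",
                       "n_alleles", "span_nt", "in_decoy")]
    rownames(sites) <- NULL

    freqs <- matrix(rep(sites$pop_maf, spec$n_strata), ncol = spec$n_strata)
    if (!is.null(freqs_common)) {
      freqs[(n_rare + 1):n_v, ] <- freqs_common
    }
    attr(sites, "stratum_freqs") <- freqs
    sites
  })
}

qc_clean_sites <- function(sites, thresholds = qc_thresholds()) {
  sites$pop_call_rate >= thresholds$min_pop_call_rate &
    sites$pass_flag &
    !sites$in_decoy &
    sites$n_alleles <= thresholds$max_alleles &
    sites$span_nt <= thresholds$max_span_nt
}

#' Generate noisy hemizygous genotype calls
#'
#' Background carrier status per sample x site is Bernoulli with the site's
#' (stratum-specific, for common sites) allele frequency. If the spec plants
#' an enriched gene, exactly `planted_case_carriers` cases and
#' `planted_control_carriers` controls — chosen by a seeded shuffle of sample
#' order — are each assigned one qualifying variant of that gene (site chosen
#' uniformly among the gene's clean qualifying sites), all other carriers of
#' those sites are cleared, and the planted calls are drawn conditional on
#' passing the genotype QC filters so the planted counts are exact rather
#' than expected values.
#'
#' Read-level noise: depth is negative-binomial, GQ truncated normal, carrier
#' allelic balance Beta-distributed around 0.5 (upstream diploid calling on
#' chrX yields heterozygous-style read support for hemizygous carriers, which
#' is what the minor-read-ratio filter screens), with small contamination
#' rates producing low-depth, low-GQ and allele-imbalanced calls plus outright
#' missingness.
#'
#' @param samples from [generate_cohort()].
#' @param sites from [generate_variant_sites()].
#' @param spec the [cohort_spec()].
#' @return Long-format data frame (site-major, sample varying fastest):
#'   `sample_id`, `variant_id`, `allele_count` (0/1/NA), `depth`, `gq`,
#'   `ref_reads`, `alt_reads`.
#' @export
generate_genotypes <- function(samples, sites, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_s <- nrow(samples); n_v <- nrow(sites)
  vid <- variant_id(sites$chrom, sites$pos, sites$ref, sites$alt)
  empty <- data.frame(sample_id = character(), variant_id = character(),
                      allele_count = integer(), depth = integer(),
                      gq = integer(), ref_reads = integer(),
                      alt_reads = integer(), stringsAsFactors = FALSE)
  if (n_s == 0 || n_v == 0) return(empty)

  freqs <- attr(sites, "stratum_freqs")
  if (is.null(freqs)) {
    freqs <- matrix(rep(sites$pop_maf, spec$n_strata), ncol = spec$n_strata)
  }
  stratum_idx <- as.integer(sub("^S", "", samples$stratum))

  withr::with_seed(spec$seed + 2L, {
    # carrier draws: p[s, v] = freq of site v in the stratum of sample s
    p_mat <- t(freqs)[stratum_idx, , drop = FALSE]          # n_s x n_v
    A <- matrix(stats::rbinom(n_s * n_v, 1L, as.vector(p_mat)), n_s, n_v)

    planted_cells <- NULL
    if (!is.null(spec$planted_gene)) {
      rule <- selection_rule()
      qual <- which(sites$gene == spec$planted_gene &
                      sites$pop_maf < rule$max_pop_maf &
                      sites$consequence %in% rule$included_consequences &
                      qc_clean_sites(sites))
      if (length(qual) == 0) {
        stop_config("planted_gene", "has no clean qualifying sites to plant into")
      }
      A[, qual] <- 0L
      case_idx <- which(samples$phenotype == "case")
      ctrl_idx <- which(samples$phenotype == "control")
      if (spec$planted_case_carriers > length(case_idx) ||
          spec$planted_control_carriers > length(ctrl_idx)) {
        stop_config("planted_case_carriers", "exceeds available samples")
      }
      chosen_cases <- sample(case_idx)[seq_len(spec$planted_case_carriers)]
      chosen <- c(chosen_cases,
                  sample(ctrl_idx)[seq_len(spec$planted_control_carriers)])
      if (length(chosen) > 0) {
        site_choice <- qual[sample.int(length(qual), length(chosen), replace = TRUE)]
        A[cbind(chosen, site_choice)] <- 1L
        planted_cells <- (site_choice - 1L) * n_s + chosen  # column-major index
      }
    }

    N <- n_s * n_v
    gn <- spec$genotype_noise
    ac <- as.vector(A)
    dp <- stats::rnbinom(N, size = gn$dp_size, mu = gn$dp_mean)
    low_dp <- stats::runif(N) < (gn$low_dp_rate %||% 0)
    dp[low_dp] <- stats::rpois(sum(low_dp), 4)
    gq <- pmin(99L, pmax(0L, as.integer(round(stats::rnorm(N, gn$gq_mean, gn$gq_sd)))))
    low_gq <- stats::runif(N) < (gn$low_gq_rate %||% 0)
    gq[low_gq] <- sample(0:19, sum(low_gq), replace = TRUE)

    # allelic balance: carriers het-like, non-carriers near all-reference
    af <- rep(gn$ref_error_rate %||% 0.002, N)
    is_carrier <- ac == 1L
    n1 <- sum(is_carrier)
    if (n1 > 0) {
      af[is_carrier] <- stats::rbeta(n1, gn$ab_shape, gn$ab_shape)
      bad_ab <- is_carrier & stats::runif(N) < (gn$mrr_fail_rate %||% 0)
      af[bad_ab] <- stats::runif(sum(bad_ab), 0.01, 0.15)
    }
    alt <- stats::rbinom(N, dp, af)
    ref <- dp - alt

    miss <- stats::runif(N) < spec$missingness_rate
    # a small fraction of sites is badly genotyped across the cohort so the
    # site-missingness filter has something to remove
    hi_rate <- spec$qc_fail_fractions$high_missingness %||% 0
    if (hi_rate > 0) {
      hi_sites <- stats::runif(n_v) < hi_rate
      if (any(hi_sites)) {
        hi_cells <- rep(hi_sites, each = n_s)
        miss <- miss | (hi_cells & stats::runif(N) < 0.4)
      }
    }
    ac[miss] <- NA_integer_
    dp[miss] <- 0L; gq[miss] <- 0L; ref[miss] <- 0L; alt[miss] <- 0L

    if (!is.null(planted_cells)) {
      # planted carrier calls are clamped to QC-passing values: exact counts
      dp[planted_cells] <- pmax(dp[planted_cells], 10L)
      gq[planted_cells] <- pmax(gq[planted_cells], 30L)
      ref[planted_cells] <- dp[planted_cells] %/% 2L
      alt[planted_cells] <- dp[planted_cells] - ref[planted_cells]
      ac[planted_cells] <- 1L
    }

    out <- data.frame(
      sample_id = rep(samples$sample_id, times = n_v),
      variant_id = rep(vid, each = n_s),
      allele_count = as.integer(ac),
      depth = as.integer(dp),
      gq = as.integer(gq),
      ref_reads = as.integer(ref),
      alt_reads = as.integer(alt),
      stringsAsFactors = FALSE
    )
    if (!is.null(planted_cells)) {
      attr(out, "planted_case_samples") <-
        samples$sample_id[chosen[seq_len(spec$planted_case_carriers)]]
    }
    out
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_cohort()], [generate_variant_sites()]
#' and [generate_genotypes()] from one spec. If the spec plants carriers and
#' sets a planted age law, the planted case carriers' ages are redrawn from it
#' (a penetrant X-linked deficiency presents at younger ages than the overall
#' critical-disease cohort).
#'
#' @param spec a [cohort_spec()].
#' @return List with `samples`, `sites`, `genotypes`.
#' @export
simulate_dataset <- function(spec) {
  samples <- generate_cohort(spec)
  sites <- generate_variant_sites(spec)
  genotypes <- generate_genotypes(samples, sites, spec)
  planted <- attr(genotypes, "planted_case_samples")
  if (!is.null(planted) && length(planted) > 0 &&
      !is.null(spec$planted_age_mean)) {
    idx <- match(planted, samples$sample_id)
    samples$age[idx] <- withr::with_seed(
      spec$seed + 3L,
      rtnorm_pos(length(idx), spec$planted_age_mean, spec$planted_age_sd)
    )
  }
  list(samples = samples, sites = sites, genotypes = genotypes)
}
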