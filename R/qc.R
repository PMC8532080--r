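# Genotype-level and site-level quality control.
#
# Genotype filters (strict inequalities): depth < 8X, GQ < 20, or minor read
# ratio MRR = min(ref, alt) / (ref + alt) < 20%. Failing calls are masked to
# missing (GATK-style), not dropped, so they count toward site missingness.
# Site filters, applied after genotype masking and in this attribution order:
# (i) reference-population call rate < 50%, (ii) non-PASS in the reference
# database, (iii) decoy/low-complexity overlap, (iv) more than 4 alleles,
# (v) more than 20% missing genotypes in the cohort, (vi) span > 20 nt.
# Boundary values (DP=8, GQ=20, MRR=0.20, 4 alleles, 20 nt, 20% missing) pass;
# call rate exactly 50% passes ("< 50%" fails).

#' Quality-control thresholds
#'
#' @param min_depth minimum read depth; calls with `depth < min_depth` fail.
#' @param min_gq minimum genotype quality (strict).
#' @param min_mrr minimum minor read ratio (strict).
#' @param min_pop_call_rate sites with reference-population call rate strictly
#'   below this fail.
#' @param max_cohort_missingness sites with cohort missingness strictly above
#'   this (after genotype masking) fail.
#' @param max_alleles sites with strictly more alleles fail.
#' @param max_span_nt sites spanning strictly more nucleotides fail.
#' @return Validated list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_depth = 8, min_gq = 20, min_mrr = 0.20,
                          min_pop_call_rate = 0.50,
                          max_cohort_missingness = 0.20,
                          max_alleles = 4, max_span_nt = 20) {
  check_prob(min_mrr, "min_mrr")
  check_prob(min_pop_call_rate, "min_pop_call_rate")
  check_prob(max_cohort_missingness, "max_cohort_missingness")
  if (min_depth < 0 || min_gq < 0) stop_config("min_depth/min_gq", "must be >= 0")
  check_count(max_alleles, "max_alleles", positive = TRUE)
  check_count(max_span_nt, "max_span_nt", positive = TRUE)
  structure(list(min_depth = min_depth, min_gq = min_gq, min_mrr = min_mrr,
                 min_pop_call_rate = min_pop_call_rate,
                 max_cohort_missingness = max_cohort_missingness,
                 max_alleles = max_alleles, max_span_nt = max_span_nt),
            class = "qc_thresholds")
}

#' Evaluate the genotype-level filters for calls
#'
#' Vectorized over calls. A call fails on the first violated predicate in the
#' order depth, GQ, MRR; a call whose informative reads sum to zero while a
#' genotype is recorded is flagged `"malformed"` (treated as missing
#' downstream). Boundary values pass: depth 8, GQ 20, MRR 0.20.
#'
#' @param depth,gq,ref_reads,alt_reads call fields (equal-length vectors).
#' @param thresholds a [qc_thresholds()].
#' @return Character vector: `"pass"`, `"depth"`, `"gq"`, `"mrr"` or
#'   `"malformed"`.
#' @examples
#' genotype_passes(7, 99, 4, 3)                     # "depth"
#' genotype_passes(8, 20, 6, 2)                     # "pass" (MRR = 0.25)
#' genotype_passes(50, 80, 45, 5)                   # "mrr"  (MRR = 0.10)
#' @export
genotype_passes <- function(depth, gq, ref_reads, alt_reads,
                            thresholds = qc_thresholds()) {
  t <- thresholds
  n_inf <- ref_reads + alt_reads
  mrr <- ifelse(n_inf > 0, pmin(ref_reads, alt_reads) / n_inf, NA_real_)
  out <- rep("pass", length(depth))
  out[!is.na(mrr) & mrr < t$min_mrr] <- "mrr"
  out[gq < t$min_gq] <- "gq"
  out[depth < t$min_depth] <- "depth"
  out[n_inf == 0] <- "malformed"
  out
}

#' Evaluate the site-level filters
#'
#' Vectorized over sites; the first failing reason in the documented order is
#' reported. `cohort_missingness` must be computed after genotype masking
#' (masked calls count as missing).
#'
#' @param sites data frame with pop_call_rate, pass_flag, in_decoy, n_alleles,
#'   span_nt.
#' @param cohort_missingness per-site missing fraction in the cohort.
#' @param thresholds a [qc_thresholds()].
#' @return Character vector: `"pass"`, `"ref_callrate"`, `"non_pass"`,
#'   `"decoy"`, `"multiallelic"`, `"missingness"` or `"span"`.
#' @export
site_passes <- function(sites, cohort_missingness, thresholds = qc_thresholds()) {
  req <- c("pop_call_rate", "pass_flag", "in_decoy", "n_alleles", "span_nt")
  missing_cols <- req[!req %in% names(sites)]
  if (length(missing_cols)) {
    stop("site annotation lacks required field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in req) {
    if (anyNA(sites[[col]])) {
      stop("site annotation field '", col, "' has missing values", call. = FALSE)
    }
  }
  t <- thresholds
  out <- rep("pass", nrow(sites))
  out[sites$span_nt > t$max_span_nt] <- "span"
  out[cohort_missingness > t$max_cohort_missingness] <- "missingness"
  out[sites$n_alleles > t$max_alleles] <- "multiallelic"
  out[sites$in_decoy] <- "decoy"
  out[!sites$pass_flag] <- "non_pass"
  out[sites$pop_call_rate < t$min_pop_call_rate] <- "ref_callrate"
  out
}

#' Apply genotype and site quality control
#'
#' Genotype filters run first and mask failing calls to missing; per-site
#' cohort missingness is then recomputed and the site filters applied. Every
#' input genotype and site is either retained or attributed to exactly one
#' removal reason, and the report reconciles by construction.
#'
#' @param samples sample sheet data frame.
#' @param sites site annotation data frame (with `in_decoy`, or supply
#'   `decoy_bed`).
#' @param genotypes long genotype data frame.
#' @param thresholds a [qc_thresholds()].
#' @param decoy_bed optional BED path or GRanges; when given, `in_decoy` is
#'   recomputed from it.
#' @param mrr_scope `"variant_calls"` (default) applies the minor-read-ratio
#'   filter to calls carrying the variant allele only — reference calls
#'   legitimately have near-zero minor read ratio; `"all_calls"` applies it
#'   unconditionally.
#' @param site_filter_order `"genotype_first"` (default) recomputes site
#'   missingness after genotype masking; `"site_first"` uses pre-masking
#'   missingness.
#' @return List of class `xlb_qc`: `samples`, `sites` (retained), `genotypes`
#'   (masked, restricted to retained sites), `site_missingness`, and `report`
#'   (class `qc_report`).
#' @export
apply_qc <- function(samples, sites, genotypes, thresholds = qc_thresholds(),
                     decoy_bed = NULL,
                     mrr_scope = c("variant_calls", "all_calls"),
                     site_filter_order = c("genotype_first", "site_first")) {
  mrr_scope <- match.arg(mrr_scope)
  site_filter_order <- match.arg(site_filter_order)
  vid <- variant_id(sites$chrom, sites$pos, sites$ref, sites$alt)
  if (nrow(genotypes) > 0) {
    orphan_s <- setdiff(unique(genotypes$sample_id), samples$sample_id)
    orphan_v <- setdiff(unique(genotypes$variant_id), vid)
    if (length(orphan_s) || length(orphan_v)) {
      stop("orphan genotype records reference unknown ",
           if (length(orphan_s)) paste0("samples: ",
             paste(utils::head(orphan_s, 3), collapse = ", ")) else "",
           if (length(orphan_v)) paste0(" sites: ",
             paste(utils::head(orphan_v, 3), collapse = ", ")) else "",
           call. = FALSE)
    }
  }
  if (!is.null(decoy_bed)) sites$in_decoy <- flag_decoy(sites, decoy_bed)
  if (!"in_decoy" %in% names(sites)) {
    stop("site annotation lacks required field(s): in_decoy ",
         "(supply decoy_bed or an in_decoy column)", call. = FALSE)
  }

  g <- genotypes
  already_missing <- is.na(g$allele_count)
  pre_missingness <- site_missing_fraction(g, vid, nrow(samples))

  reason <- genotype_passes(g$depth, g$gq, g$ref_reads, g$alt_reads, thresholds)
  if (mrr_scope == "variant_calls") {
    reason[reason == "mrr" & !is.na(g$allele_count) & g$allele_count == 0] <- "pass"
  }
  reason[already_missing] <- "missing_input"
  masked <- !already_missing & reason != "pass"
  g$allele_count[masked] <- NA_integer_

  geno_counts <- c(depth = sum(reason == "depth"),
                   gq = sum(reason == "gq"),
                   mrr = sum(reason == "mrr"),
                   malformed = sum(reason == "malformed"))

  post_missingness <- site_missing_fraction(g, vid, nrow(samples))
  miss_for_filter <- if (site_filter_order == "genotype_first") {
    post_missingness
  } else {
    pre_missingness
  }
  site_reason <- site_passes(sites, miss_for_filter, thresholds)
  keep <- site_reason == "pass"

  site_counts <- c(ref_callrate = sum(site_reason == "ref_callrate"),
                   non_pass = sum(site_reason == "non_pass"),
                   decoy = sum(site_reason == "decoy"),
                   multiallelic = sum(site_reason == "multiallelic"),
                   missingness = sum(site_reason == "missingness"),
                   span = sum(site_reason == "span"))

  g_out <- g[g$variant_id %in% vid[keep], , drop = FALSE]
  rownames(g_out) <- NULL

  report <- structure(list(
    genotype_total = nrow(genotypes),
    genotype_already_missing = sum(already_missing),
    genotype_masked = geno_counts,
    genotype_retained = nrow(genotypes) - sum(already_missing) - sum(geno_counts),
    site_total = nrow(sites),
    site_removed = site_counts,
    site_retained = sum(keep),
    genotype_records_after_site_filter = nrow(g_out)
  ), class = "qc_report")

  stopifnot(report$genotype_retained + report$genotype_already_missing +
              sum(report$genotype_masked) == report$genotype_total,
            report$site_retained + sum(report$site_removed) == report$site_total)

  structure(list(samples = samples,
                 sites = sites[keep, , drop = FALSE],
                 genotypes = g_out,
                 site_missingness = post_missingness[keep],
                 report = report),
            class = "xlb_qc")
}

site_missing_fraction <- function(genotypes, vid, n_samples) {
  if (n_samples == 0 || length(vid) == 0) return(rep(0, length(vid)))
  nonmiss <- table(factor(genotypes$variant_id[!is.na(genotypes$allele_count)],
                          levels = vid))
  1 - as.numeric(nonmiss) / n_samples
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype-level QC:\n")
  cat(sprintf("  input calls: %d (already missing: %d)\n",
              x$genotype_total, x$genotype_already_missing))
  for (r in names(x$genotype_masked)) {
    cat(sprintf("  masked [%s]: %d\n", r, x$genotype_masked[[r]]))
  }
  cat(sprintf("  retained non-missing calls: %d\n", x$genotype_retained))
  cat("Site-level QC:\n")
  cat(sprintf("  input sites: %d\n", x$site_total))
  for (r in names(x$site_removed)) {
    cat(sprintf("  removed [%s]: %d\n", r, x$site_removed[[r]]))
  }
  cat(sprintf("  retained sites: %d\n", x$site_retained))
  invisible(x)
}

qc_report_df <- function(report) {
  data.frame(
    level = c("genotype", "genotype",
              rep("genotype", length(report$genotype_masked)), "genotype",
              "site", rep("site", length(report$site_removed)), "site"),
    category = c("input", "already_missing",
                 paste0("masked_", names(report$genotype_masked)), "retained",
                 "input", paste0("removed_", names(report$site_removed)),
                 "retained"),
    count = c(report$genotype_total, report$genotype_already_missing,
              unname(report$genotype_masked), report$genotype_retained,
              report$site_total, unname(report$site_removed),
              report$site_retained),
    stringsAsFactors = FALSE
  )
}
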