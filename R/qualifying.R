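# Qualifying-variant selection and gene-level carrier collapsing. A variant
# qualifies if it is very rare (population MAF strictly below the threshold;
# variants absent from the reference population qualify) and non-synonymous
# (predicted loss-of-function, missense, or in-frame indel). The synonymous
# selection is the negative control used to check test calibration.

NONSYN_CONSEQUENCES <- c("lof_annotation", "missense", "inframe_indel")

#' Qualifying-variant selection rule
#'
#' @param max_pop_maf strict upper bound on population MAF (default 1e-4).
#' @param included_consequences consequence classes that qualify (default the
#'   non-synonymous classes).
#' @param control_mode if TRUE, select rare synonymous variants instead (the
#'   negative-control analysis).
#' @return Validated list of class `selection_rule`.
#' @export
selection_rule <- function(max_pop_maf = 1e-4,
                           included_consequences = NONSYN_CONSEQUENCES,
                           control_mode = FALSE) {
  check_prob(max_pop_maf, "max_pop_maf", open_left = TRUE, open_right = TRUE)
  if (control_mode) {
    included_consequences <- "synonymous"
  } else {
    if (length(included_consequences) == 0) {
      stop_config("included_consequences", "must be non-empty")
    }
    if ("synonymous" %in% included_consequences) {
      stop_config("included_consequences",
                  "may not contain 'synonymous' unless control_mode = TRUE")
    }
  }
  structure(list(max_pop_maf = max_pop_maf,
                 included_consequences = included_consequences,
                 control_mode = control_mode),
            class = "selection_rule")
}

#' Select qualifying variant sites
#'
#' A site qualifies iff its population MAF is strictly below the rule's bound
#' (so private variants recorded as 0 qualify) and its consequence class is in
#' the rule's included set. Sites should already be QC-passed.
#'
#' @param sites site annotation data frame.
#' @param rule a [selection_rule()].
#' @return The qualifying subset of `sites`.
#' @export
select_qualifying <- function(sites, rule = selection_rule()) {
  stopifnot(inherits(rule, "selection_rule"))
  keep <- sites$pop_maf < rule$max_pop_maf &
    sites$consequence %in% rule$included_consequences
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse qualifying variants to per-gene carrier indicators
#'
#' A sample is a carrier of a gene iff it has allele count 1 at one or more of
#' the gene's qualifying sites; carrying several qualifying variants still
#' counts once (binary collapsing). Samples whose calls are missing at every
#' qualifying site of a gene are counted as non-carriers (a conservative,
#' documented choice) and tallied in `counts$n_all_missing`. Genes with zero
#' qualifying sites are omitted.
#'
#' @param genotypes QC-masked long genotype data frame.
#' @param qualifying_sites data frame from [select_qualifying()].
#' @param samples sample sheet (order defines matrix columns).
#' @param mode `"binary"` (default, at-least-one indicator) or `"count"`
#'   (number of qualifying variant alleles, CMC-style).
#' @return Object of class `carrier_matrix`: `matrix` (genes x samples),
#'   `counts` (gene, case_carriers, control_carriers, n_all_missing), `mode`.
#' @export
collapse_carriers <- function(genotypes, qualifying_sites, samples,
                              mode = c("binary", "count")) {
  mode <- match.arg(mode)
  genes <- sort(unique(qualifying_sites$gene))
  qvid <- variant_id(qualifying_sites$chrom, qualifying_sites$pos,
                     qualifying_sites$ref, qualifying_sites$alt)
  # duplicated qualifying site records must not double-count carriers
  dup <- duplicated(qvid)
  qvid <- qvid[!dup]
  gene_of <- qualifying_sites$gene[!dup]

  M <- matrix(0L, nrow = length(genes), ncol = nrow(samples),
              dimnames = list(genes, samples$sample_id))
  Miss <- matrix(0L, nrow = length(genes), ncol = nrow(samples),
                 dimnames = list(genes, samples$sample_id))
  n_sites_per_gene <- table(factor(gene_of, levels = genes))

  g <- genotypes[genotypes$variant_id %in% qvid, , drop = FALSE]
  if (nrow(g) > 0) {
    gi <- match(gene_of[match(g$variant_id, qvid)], genes)
    si <- match(g$sample_id, samples$sample_id)
    carrier <- !is.na(g$allele_count) & g$allele_count == 1L
    if (any(carrier)) {
      idx <- cbind(gi[carrier], si[carrier])
      if (mode == "binary") {
        M[idx] <- 1L
      } else {
        tab <- tapply(rep(1L, sum(carrier)),
                      list(factor(gi[carrier], levels = seq_along(genes)),
                           factor(si[carrier], levels = seq_len(nrow(samples)))),
                      sum, default = 0L)
        M <- matrix(as.integer(tab), nrow = length(genes),
                    dimnames = dimnames(M))
      }
    }
    is_miss <- is.na(g$allele_count)
    if (any(is_miss)) {
      mtab <- tapply(rep(1L, sum(is_miss)),
                     list(factor(gi[is_miss], levels = seq_along(genes)),
                          factor(si[is_miss], levels = seq_len(nrow(samples)))),
                     sum, default = 0L)
      Miss <- matrix(as.integer(mtab), nrow = length(genes),
                     dimnames = dimnames(Miss))
    }
  }

  is_case <- samples$phenotype == "case"
  carrier_bin <- M >= 1L
  all_missing <- sweep(Miss, 1, as.numeric(n_sites_per_gene), "==") & !carrier_bin
  counts <- data.frame(
    gene = genes,
    case_carriers = as.integer(carrier_bin[, is_case, drop = FALSE] %*%
                                 rep(1, sum(is_case))),
    control_carriers = as.integer(carrier_bin[, !is_case, drop = FALSE] %*%
                                    rep(1, sum(!is_case))),
    n_all_missing = as.integer(rowSums(all_missing)),
    stringsAsFactors = FALSE
  )
  structure(list(matrix = M, counts = counts, mode = mode),
            class = "carrier_matrix")
}

#' @export
print.carrier_matrix <- function(x, ...) {
  cat(sprintf("carrier_matrix: %d genes x %d samples (%s collapsing)\n",
              nrow(x$matrix), ncol(x$matrix), x$mode))
  print(utils::head(x$counts))
  invisible(x)
}

#' Genes eligible for the burden test
#'
#' A gene enters the multiple-testing family iff enough case samples carry at
#' least one of its qualifying variants; the eligible-set size is the
#' Bonferroni denominator.
#'
#' @param carriers a `carrier_matrix` (needs its `counts`).
#' @param min_case_carriers minimum case carriers (default 5).
#' @param count_in `"cases"` (default) counts case carriers only; `"pooled"`
#'   counts carriers in the whole cohort.
#' @return Character vector of eligible gene ids.
#' @export
gene_test_eligibility <- function(carriers, min_case_carriers = 5,
                                  count_in = c("cases", "pooled")) {
  count_in <- match.arg(count_in)
  stopifnot(inherits(carriers, "carrier_matrix"))
  cnt <- carriers$counts
  n <- if (count_in == "cases") cnt$case_carriers
       else cnt$case_carriers + cnt$control_carriers
  cnt$gene[n >= min_case_carriers]
}
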