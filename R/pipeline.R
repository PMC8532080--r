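# End-to-end orchestration: read inputs -> QC -> qualifying-variant selection
# and carrier collapsing -> ancestry PCA -> per-gene Firth burden LRT ->
# Bonferroni correction -> summaries. Every stage reads and writes plain
# files, so partial reruns are possible, and the whole run is a pure function
# of the inputs plus the config.

#' Pipeline configuration
#'
#' @param vcf,annotation,sample_sheet input file paths.
#' @param decoy_bed optional BED of low-complexity/decoy regions.
#' @param pc_scores optional TSV of externally computed PC scores (skips the
#'   in-cohort PCA).
#' @param out_dir output directory.
#' @param thresholds a [qc_thresholds()].
#' @param max_pop_maf qualifying-variant MAF bound (strict).
#' @param control_mode if TRUE run the synonymous negative-control analysis.
#' @param pca_min_maf,pca_min_call_rate,n_pcs PCA variant selection and number
#'   of components; `n_pcs = 0` fits the burden model without PC covariates.
#' @param use_age include age (in years, untransformed) as a covariate.
#' @param min_case_carriers eligibility bound for the Bonferroni family.
#' @param alpha family-wise error rate.
#' @param firth_tol,firth_max_iter Firth fitting controls.
#' @param mrr_scope forwarded to [apply_qc()].
#' @param seed recorded in the report (the pipeline itself is deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, annotation, sample_sheet, decoy_bed = NULL,
                            pc_scores = NULL, out_dir = "xlburden_out",
                            thresholds = qc_thresholds(),
                            max_pop_maf = 1e-4, control_mode = FALSE,
                            pca_min_maf = 0.01, pca_min_call_rate = 0.99,
                            n_pcs = 5, use_age = TRUE,
                            min_case_carriers = 5, alpha = 0.05,
                            firth_tol = 1e-8, firth_max_iter = 100,
                            mrr_scope = "variant_calls", seed = 1L) {
  check_prob(max_pop_maf, "max_pop_maf", open_left = TRUE, open_right = TRUE)
  check_prob(alpha, "alpha", open_left = TRUE)
  check_count(n_pcs, "n_pcs")
  check_count(min_case_carriers, "min_case_carriers")
  structure(list(vcf = vcf, annotation = annotation,
                 sample_sheet = sample_sheet, decoy_bed = decoy_bed,
                 pc_scores = pc_scores, out_dir = out_dir,
                 thresholds = thresholds, max_pop_maf = max_pop_maf,
                 control_mode = control_mode, pca_min_maf = pca_min_maf,
                 pca_min_call_rate = pca_min_call_rate, n_pcs = n_pcs,
                 use_age = use_age, min_case_carriers = min_case_carriers,
                 alpha = alpha, firth_tol = firth_tol,
                 firth_max_iter = firth_max_iter, mrr_scope = mrr_scope,
                 seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat key-value document mirroring [pipeline_config()]; QC thresholds are
#' given as `qc.<name>` nested keys or omitted for defaults.
#'
#' @param path YAML file.
#' @param ... overrides applied after reading.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  thr <- do.call(qc_thresholds, y$qc %||% list())
  y$qc <- NULL
  args <- utils::modifyList(y, list(...))
  args$thresholds <- thr
  do.call(pipeline_config, args)
}

#' Validate pipeline inputs
#'
#' Collects all problems (missing files, schema violations, range errors,
#' sample-sheet/VCF discordance) before failing; returns them rather than
#' throwing.
#'
#' @param config a [pipeline_config()].
#' @return Character vector of error messages; length 0 means inputs are ok.
#' @export
validate_inputs <- function(config) {
  errs <- character(0)
  note <- function(...) errs <<- c(errs, sprintf(...))
  for (f in c("vcf", "annotation", "sample_sheet")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      note("%s: file not found (%s)", f, config[[f]] %||% "NULL")
    }
  }
  if (!is.null(config$decoy_bed) && !file.exists(config$decoy_bed)) {
    note("decoy_bed: file not found (%s)", config$decoy_bed)
  }
  if (length(errs)) return(errs)

  samples <- tryCatch(read_sample_sheet(config$sample_sheet),
                      error = function(e) {note("%s", conditionMessage(e)); NULL})
  sites <- tryCatch(read_annotation(config$annotation,
                                    decoy_bed = config$decoy_bed),
                    error = function(e) {note("%s", conditionMessage(e)); NULL})
  genotypes <- tryCatch(read_genotypes_vcf(config$vcf),
                        error = function(e) {note("%s", conditionMessage(e)); NULL})
  if (!is.null(samples)) {
    if (anyDuplicated(samples$sample_id)) {
      note("sample sheet: duplicated sample_id")
    }
    if (!all(samples$phenotype %in% c("case", "control"))) {
      note("sample sheet: phenotype must be 'case' or 'control'")
    }
    if (any(!is.na(samples$age) & samples$age <= 0)) {
      note("sample sheet: ages must be positive")
    }
  }
  if (!is.null(sites)) {
    for (col in c("pop_maf", "male_maf", "pop_call_rate")) {
      bad <- which(sites[[col]] < 0 | sites[[col]] > 1)
      if (length(bad)) {
        note("annotation: %s out of [0,1] at row(s) %s", col,
             paste(utils::head(bad, 3), collapse = ", "))
      }
    }
    if (any(sites$pos < 1)) note("annotation: positions must be >= 1")
    if (any(sites$span_nt < 1)) note("annotation: span_nt must be >= 1")
  }
  if (!is.null(samples) && !is.null(genotypes) && nrow(genotypes) > 0) {
    orphan <- setdiff(unique(genotypes$sample_id), samples$sample_id)
    if (length(orphan)) {
      note("VCF sample(s) absent from sample sheet: %s",
           paste(utils::head(orphan, 5), collapse = ", "))
    }
  }
  if (!is.null(sites) && !is.null(genotypes) && nrow(genotypes) > 0) {
    vid <- variant_id(sites$chrom, sites$pos, sites$ref, sites$alt)
    orphan <- setdiff(unique(genotypes$variant_id), vid)
    if (length(orphan)) {
      note("VCF variant(s) absent from annotation: %s",
           paste(utils::head(orphan, 5), collapse = ", "))
    }
  }
  errs
}

#' Run the full burden pipeline
#'
#' Stages run in fixed order (QC, qualifying selection, collapsing, PCA,
#' Firth LRT per gene, Bonferroni, summaries); any stage failure aborts with a
#' stage-tagged error. Identical config and inputs give byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a `run_report` list: per-stage counts, QC report,
#'   eligible-gene count, Bonferroni threshold, the results table, and the
#'   config echo. Output files (results.tsv, carrier_counts.tsv,
#'   qc_report.tsv, pc_scores.tsv, summary.tsv, report.json) are written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  errs <- validate_inputs(config)
  if (length(errs)) {
    stop("[stage validate] invalid inputs:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  samples <- read_sample_sheet(config$sample_sheet)
  sites <- read_annotation(config$annotation, decoy_bed = config$decoy_bed)
  genotypes <- read_genotypes_vcf(config$vcf)

  qc <- stage("qc", apply_qc(samples, sites, genotypes,
                             thresholds = config$thresholds,
                             mrr_scope = config$mrr_scope))

  rule <- selection_rule(max_pop_maf = config$max_pop_maf,
                         control_mode = config$control_mode)
  qual <- stage("select", select_qualifying(qc$sites, rule))
  carriers <- stage("collapse",
                    collapse_carriers(qc$genotypes, qual, samples))

  covars <- NULL
  pcs <- NULL
  if (!is.null(config$pc_scores)) {
    pcs <- stage("pca", read_pc_scores(config$pc_scores, samples,
                                       k = config$n_pcs))
  } else if (config$n_pcs > 0) {
    pcs <- stage("pca", {
      G <- select_pca_variants(qc$sites, qc$genotypes, samples,
                               min_maf = config$pca_min_maf,
                               min_call_rate = config$pca_min_call_rate,
                               k = config$n_pcs)
      compute_pcs(G, k = config$n_pcs)
    })
  }
  if (!is.null(pcs)) covars <- pcs$scores
  if (config$use_age) covars <- cbind(covars, age = samples$age)

  y <- as.integer(samples$phenotype == "case")
  results <- stage("burden",
                   test_all_genes(carriers, covars, y,
                                  min_case_carriers = config$min_case_carriers,
                                  alpha = config$alpha,
                                  tol = config$firth_tol,
                                  max_iter = config$firth_max_iter))
  threshold <- attr(results, "threshold")

  any_carrier <- colSums(carriers$matrix) >= 1
  summaries <- stage("summarize", cohort_summaries(samples, any_carrier))

  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  write_tsv <- function(d, name) {
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(x) sprintf("%.10g", x))
    utils::write.table(d, file.path(out, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv(results, "results.tsv")
  write_tsv(carriers$counts, "carrier_counts.tsv")
  write_tsv(qc_report_df(qc$report), "qc_report.tsv")
  if (!is.null(pcs)) {
    write_tsv(data.frame(sample_id = samples$sample_id, pcs$scores,
                         check.names = FALSE), "pc_scores.tsv")
  }
  write_tsv(summaries, "summary.tsv")

  report <- list(
    package_version = as.character(utils::packageVersion("xlburden")),
    seed = config$seed,
    control_mode = config$control_mode,
    n_samples = nrow(samples),
    n_cases = sum(y), n_controls = sum(1 - y),
    n_sites_input = nrow(sites),
    n_sites_qc_passed = nrow(qc$sites),
    n_sites_qualifying = nrow(qual),
    n_genes_tested = nrow(results),
    n_eligible = sum(results$eligible),
    bonferroni_threshold = threshold,
    top_genes = utils::head(results, 10),
    qc = unclass(qc$report),
    config = config_echo(config)
  )
  class(report) <- "run_report"
  jsonlite::write_json(report_for_json(report), file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

config_echo <- function(config) {
  e <- unclass(config)
  e$thresholds <- unclass(e$thresholds)
  e
}

report_for_json <- function(report) {
  r <- unclass(report)
  r$top_genes <- as.data.frame(r$top_genes)
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("xlburden run: %d cases / %d controls, %d genes tested, %d eligible\n",
              x$n_cases, x$n_controls, x$n_genes_tested, x$n_eligible))
  if (is.finite(x$bonferroni_threshold %||% NA)) {
    cat(sprintf("Bonferroni threshold: %.3g\n", x$bonferroni_threshold))
  }
  print(utils::head(x$top_genes, 5))
  invisible(x)
}

#' Simulate a cohort and write it to disk
#'
#' Convenience wrapper composing [simulate_dataset()] and [write_cohort()];
#' the `simulate` CLI subcommand is a thin shim over it.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory.
#' @return Invisibly, the list of file paths.
#' @export
simulate_to_dir <- function(spec, out_dir) {
  d <- simulate_dataset(spec)
  write_cohort(d$samples, d$sites, d$genotypes, out_dir)
}
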