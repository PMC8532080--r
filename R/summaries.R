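# Reporter-activity allele classification and cohort-level summaries.
#
# Alleles are classified from NF-kB reporter activity expressed as a
# percentage of the stimulated wild type: loss-of-function (LOF) when mean
# stimulated activity is at or below lof_max, hypomorphic when strictly below
# hypomorphic_max (the published cutoff, activity < 25% of WT), neutral
# otherwise. Only the percentage of WT matters, so classification is
# invariant to the batch's raw luminescence scale.

#' Activity classification rule
#'
#' @param hypomorphic_max upper bound (strict) of the hypomorphic band, as a
#'   fraction of wild-type activity (default 0.25).
#' @param lof_max upper bound (inclusive) of the LOF band (default 0.05,
#'   activity indistinguishable from the empty-vector control; a modelling
#'   choice, exposed here).
#' @param stimulated_conditions condition labels counted as stimulated.
#' @param wt_allele label of the wild-type allele in activity tables.
#' @return Validated list of class `classification_rule`.
#' @export
classification_rule <- function(hypomorphic_max = 0.25, lof_max = 0.05,
                                stimulated_conditions = c("R848", "imiquimod",
                                                          "CL264"),
                                wt_allele = "WT") {
  if (!(lof_max >= 0 && lof_max <= hypomorphic_max && hypomorphic_max < 1)) {
    stop_config("lof_max/hypomorphic_max",
                "must satisfy 0 <= lof_max <= hypomorphic_max < 1")
  }
  structure(list(hypomorphic_max = hypomorphic_max, lof_max = lof_max,
                 stimulated_conditions = stimulated_conditions,
                 wt_allele = wt_allele),
            class = "classification_rule")
}

#' Classify one allele from its reporter-activity records
#'
#' @param records data frame rows for one allele: columns `condition` and
#'   `activity_pct_wt` (replicates aggregated by mean).
#' @param rule a [classification_rule()].
#' @return `"LOF"`, `"hypomorphic"` or `"neutral"`.
#' @examples
#' r <- data.frame(condition = "R848", activity_pct_wt = c(24, 25.8))
#' classify_allele(r)  # mean 24.9% of WT -> hypomorphic
#' @export
classify_allele <- function(records, rule = classification_rule()) {
  stim <- records[records$condition %in% rule$stimulated_conditions, ,
                  drop = FALSE]
  if (nrow(stim) == 0) {
    stop("no stimulated-condition activity records for this allele",
         call. = FALSE)
  }
  if (any(stim$activity_pct_wt < 0)) {
    stop("negative reporter activity", call. = FALSE)
  }
  act <- mean(stim$activity_pct_wt) / 100
  if (act <= rule$lof_max) "LOF"
  else if (act < rule$hypomorphic_max) "hypomorphic"
  else "neutral"
}

#' Classify every allele in an activity table
#'
#' @param activity data frame: `allele`, `condition`, `replicate`,
#'   `activity_pct_wt`. The wild-type allele must be present (it anchors the
#'   100% scale); it is reported as neutral.
#' @param rule a [classification_rule()].
#' @return Data frame: allele, mean_stimulated_activity_pct, class.
#' @export
classify_alleles <- function(activity, rule = classification_rule()) {
  req <- c("allele", "condition", "activity_pct_wt")
  if (!all(req %in% names(activity))) {
    stop("activity table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!rule$wt_allele %in% activity$allele) {
    stop("wild-type reference allele '", rule$wt_allele,
         "' absent from the activity table", call. = FALSE)
  }
  alleles <- unique(activity$allele)
  res <- lapply(alleles, function(a) {
    rec <- activity[activity$allele == a, , drop = FALSE]
    stim <- rec[rec$condition %in% rule$stimulated_conditions, , drop = FALSE]
    data.frame(allele = a,
               mean_stimulated_activity_pct = mean(stim$activity_pct_wt),
               class = classify_allele(rec, rule),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cumulative hemizygous minor allele frequency
#'
#' Sums the male MAF of a set of alleles — for an X-linked gene in males this
#' approximates the frequency of the affected genotype. With a classification
#' supplied, the set can be restricted to deleterious classes (LOF plus
#' hypomorphic) or to strictly-LOF alleles.
#'
#' @param freq data frame with `allele` and either `male_maf` or both
#'   `male_allele_count` and `male_allele_number`.
#' @param alleles allele ids to sum (default: all in `freq`).
#' @param classes optional data frame from [classify_alleles()]; with
#'   `classes_allowed`, restricts `alleles` to those classes.
#' @param classes_allowed classes summed when `classes` is given (default
#'   deleterious = LOF + hypomorphic).
#' @return The cumulative MAF (a single number; 0 for an empty set).
#' @export
cumulative_maf <- function(freq, alleles = freq$allele, classes = NULL,
                           classes_allowed = c("LOF", "hypomorphic")) {
  if (!"male_maf" %in% names(freq)) {
    if (!all(c("male_allele_count", "male_allele_number") %in% names(freq))) {
      stop("frequency table needs male_maf or male_allele_count/number",
           call. = FALSE)
    }
    if (any(freq$male_allele_count < 0 |
              freq$male_allele_count > freq$male_allele_number)) {
      stop("allele counts must satisfy 0 <= count <= number", call. = FALSE)
    }
    freq$male_maf <- freq$male_allele_count / freq$male_allele_number
  }
  if (!is.null(classes)) {
    allowed <- classes$allele[classes$class %in% classes_allowed]
    alleles <- intersect(alleles, allowed)
  }
  if (length(alleles) == 0) return(0)
  idx <- match(alleles, freq$allele)
  if (anyNA(idx)) {
    stop("allele(s) missing from the frequency table: ",
         paste(alleles[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sum(freq$male_maf[idx])
}

#' Cohort-level carrier and age summaries
#'
#' Per-group carrier counts and proportions (rounded to one decimal place of
#' percent, matching report formatting; underlying values are kept at full
#' precision in `carrier_fraction`) plus age mean, SD and range.
#'
#' @param samples sample sheet with `age`.
#' @param carrier logical/0-1 vector, one per sample.
#' @param group grouping vector (default phenotype).
#' @return Data frame with one row per group.
#' @examples
#' s <- data.frame(sample_id = as.character(1:3), phenotype = "case",
#'                 age = c(5, 5, 38))
#' cohort_summaries(s, carrier = c(TRUE, TRUE, TRUE))$age_mean  # 16
#' @export
cohort_summaries <- function(samples, carrier, group = samples$phenotype) {
  stopifnot(length(carrier) == nrow(samples))
  carrier <- as.logical(carrier)
  levels <- unique(group)
  res <- lapply(levels, function(gp) {
    sel <- group == gp
    n <- sum(sel)
    data.frame(group = gp, n = n,
               carriers = sum(carrier[sel]),
               carrier_pct = if (n > 0) percent_of(sum(carrier[sel]), n) else NA_real_,
               carrier_fraction = if (n > 0) sum(carrier[sel]) / n else NA_real_,
               age_mean = mean(samples$age[sel]),
               age_sd = stats::sd(samples$age[sel]),
               age_min = if (n > 0) min(samples$age[sel]) else NA_real_,
               age_max = if (n > 0) max(samples$age[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
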