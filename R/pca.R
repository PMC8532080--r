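# In-cohort genotype PCA used for ancestry covariates. Common, well-called
# variants are standardized (centered at the estimated allele frequency and
# scaled by the square root of its binomial variance) and the top-k left
# singular vectors, scaled by the singular values, are the PC scores entering
# the burden regression. A hook accepts externally computed scores instead.

#' Build the common-variant matrix for PCA
#'
#' Retains variants with in-cohort minor allele frequency strictly above
#' `min_maf` and call rate strictly above `min_call_rate` (computed after QC
#' masking), then mean-imputes residual missing entries.
#'
#' @param sites site annotation (QC-passed).
#' @param genotypes QC-masked long genotype data frame.
#' @param samples sample sheet (row order of the returned matrix).
#' @param min_maf strict MAF bound (default 0.01).
#' @param min_call_rate strict call-rate bound (default 0.99).
#' @param k number of components eventually requested; used to fail early when
#'   too few variants survive.
#' @return Numeric matrix samples x variants (dimnames set), mean-imputed.
#' @export
select_pca_variants <- function(sites, genotypes, samples,
                                min_maf = 0.01, min_call_rate = 0.99, k = 5) {
  vid <- variant_id(sites$chrom, sites$pos, sites$ref, sites$alt)
  n_s <- nrow(samples)
  G <- matrix(NA_real_, nrow = n_s, ncol = length(vid),
              dimnames = list(samples$sample_id, vid))
  gi <- match(genotypes$variant_id, vid)
  si <- match(genotypes$sample_id, samples$sample_id)
  ok <- !is.na(gi) & !is.na(si)
  G[cbind(si[ok], gi[ok])] <- genotypes$allele_count[ok]

  call_rate <- colMeans(!is.na(G))
  f <- colMeans(G, na.rm = TRUE)
  f[is.nan(f)] <- 0
  maf <- pmin(f, 1 - f)
  keep <- maf > min_maf & call_rate > min_call_rate
  if (!any(keep)) {
    stop("no informative variants for PCA: none exceed MAF ", min_maf,
         " and call rate ", min_call_rate, call. = FALSE)
  }
  if (sum(keep) < k) {
    stop("fewer PCA variants retained (", sum(keep), ") than components ",
         "requested (", k, ")", call. = FALSE)
  }
  G <- G[, keep, drop = FALSE]
  # mean-impute residual missing entries
  cm <- colMeans(G, na.rm = TRUE)
  na_idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(na_idx)) G[na_idx] <- cm[na_idx[, 2]]
  G
}

#' Compute genotype principal components
#'
#' Columns are centered at their mean and scaled by the square root of the
#' binomial variance at the estimated allele frequency (`scale = "binomial"`,
#' the standard genotype standardization) or left unscaled. Scores are the
#' top-k left singular vectors scaled by the singular values; the sign of each
#' component is fixed so that its largest-magnitude variant loading is
#' positive, making the output deterministic.
#'
#' @param G samples x variants matrix from [select_pca_variants()].
#' @param k number of components (default 5).
#' @param scale `"binomial"` or `"none"`.
#' @return Object of class `pc_scores`: `scores` (samples x k, columns
#'   PC1..PCk), `explained_variance` (fractions, all components), `k`.
#' @export
compute_pcs <- function(G, k = 5, scale = c("binomial", "none")) {
  scale <- match.arg(scale)
  check_count(k, "k", positive = TRUE)
  G <- as.matrix(G)
  ctr <- colMeans(G)
  Z <- sweep(G, 2, ctr, "-")
  if (scale == "binomial") {
    p <- ctr  # hemizygous allele frequency estimate
    v <- p * (1 - p)
    if (any(v <= 0)) {
      stop("monomorphic variant column(s) in PCA input; filter first",
           call. = FALSE)
    }
    Z <- sweep(Z, 2, sqrt(v), "/")
  }
  s <- svd(Z)
  if (max(s$d) == 0) {
    # degenerate input (identical rows): every sample gets the same (zero)
    # score and no component explains any variance
    scores <- matrix(0, nrow(G), k,
                     dimnames = list(rownames(G), paste0("PC", seq_len(k))))
    return(structure(list(scores = scores,
                          explained_variance = rep(0, length(s$d)), k = k),
                     class = "pc_scores"))
  }
  rank <- sum(s$d > max(dim(Z)) * .Machine$double.eps * max(s$d, 1))
  if (k > rank) {
    stop("k = ", k, " exceeds the rank of the genotype matrix (", rank, ")",
         call. = FALSE)
  }
  # deterministic sign: largest-magnitude loading positive per component
  for (j in seq_len(k)) {
    jmax <- which.max(abs(s$v[, j]))
    if (s$v[jmax, j] < 0) {
      s$v[, j] <- -s$v[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k, k)
  dimnames(scores) <- list(rownames(G), paste0("PC", seq_len(k)))
  ev <- if (sum(s$d^2) > 0) s$d^2 / sum(s$d^2) else rep(0, length(s$d))
  structure(list(scores = scores, explained_variance = ev, k = k),
            class = "pc_scores")
}

#' @export
print.pc_scores <- function(x, ...) {
  cat(sprintf("pc_scores: %d samples x %d components\n", nrow(x$scores), x$k))
  cat("explained variance: ",
      paste(sprintf("%.3f", utils::head(x$explained_variance, x$k)),
            collapse = " "), "\n")
  invisible(x)
}

#' Read externally computed PC scores
#'
#' Input hook reproducing an external reference-panel PCA: a TSV with
#' `sample_id` and `PC1..PCk` columns.
#'
#' @param path TSV file.
#' @param samples sample sheet; scores are aligned to its order.
#' @param k number of components to use (default: all present).
#' @return A `pc_scores` object (explained variance unknown, `NA`).
#' @export
read_pc_scores <- function(path, samples, k = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(d)) {
    stop("PC score file lacks a sample_id column", call. = FALSE)
  }
  pc_cols <- grep("^PC[0-9]+$", names(d), value = TRUE)
  if (is.null(k)) k <- length(pc_cols)
  pc_cols <- paste0("PC", seq_len(k))
  if (!all(pc_cols %in% names(d))) {
    stop("PC score file lacks columns: ",
         paste(setdiff(pc_cols, names(d)), collapse = ", "), call. = FALSE)
  }
  idx <- match(samples$sample_id, d$sample_id)
  if (anyNA(idx)) {
    stop("PC scores missing for sample(s): ",
         paste(utils::head(samples$sample_id[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  }
  scores <- as.matrix(d[idx, pc_cols, drop = FALSE])
  rownames(scores) <- samples$sample_id
  structure(list(scores = scores, explained_variance = NA_real_, k = k),
            class = "pc_scores")
}
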