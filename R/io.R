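# Readers and writers for the pipeline's file formats: VCF v4.2 with haploid
# GT:DP:GQ:AD, annotation TSV, sample sheet TSV, and a 0-based half-open BED
# of low-complexity/decoy regions. The VCF is read with vcfR; the BED is
# read/written through rtracklayer so interval conventions are handled by the
# standard machinery.

ANNOTATION_COLS <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                     "pop_maf", "male_maf", "pop_call_rate", "pass_flag",
                     "n_alleles", "span_nt")
SAMPLE_COLS <- c("sample_id", "phenotype", "age", "stratum")

fmt_num <- function(x) sprintf("%.15g", x)

#' Write a synthetic cohort to disk
#'
#' Emits `cohort.vcf` (VCF v4.2, haploid GT plus DP/GQ/AD), `annotation.tsv`,
#' `samples.tsv` and `decoy.bed` into `out_dir`. The files round-trip
#' losslessly through [read_cohort()].
#'
#' @param samples,sites,genotypes as produced by [simulate_dataset()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a named list of the four file paths.
#' @export
write_cohort <- function(samples, sites, genotypes, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  vid <- variant_id(sites$chrom, sites$pos, sites$ref, sites$alt)
  if (nrow(genotypes) > 0) {
    if (!all(genotypes$sample_id %in% samples$sample_id) ||
        !all(genotypes$variant_id %in% vid)) {
      stop("genotypes reference unknown samples or sites", call. = FALSE)
    }
  }

  paths <- list(vcf = file.path(out_dir, "cohort.vcf"),
                annotation = file.path(out_dir, "annotation.tsv"),
                samples = file.path(out_dir, "samples.tsv"),
                decoy = file.path(out_dir, "decoy.bed"))

  # sample sheet
  s <- samples
  s$age <- fmt_num(s$age)
  utils::write.table(s[, SAMPLE_COLS[SAMPLE_COLS %in% names(s)], drop = FALSE],
                     paths$samples, sep = "\t", quote = FALSE, row.names = FALSE)

  # annotation (in_decoy travels as the BED, not as a column)
  a <- sites[, ANNOTATION_COLS, drop = FALSE]
  a$pop_maf <- fmt_num(a$pop_maf)
  a$male_maf <- fmt_num(a$male_maf)
  a$pop_call_rate <- fmt_num(a$pop_call_rate)
  utils::write.table(a, paths$annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # decoy BED (0-based half-open) covering each flagged site's span
  dec <- sites[sites$in_decoy, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(dec)) dec$chrom else character(),
    ranges = IRanges::IRanges(start = if (nrow(dec)) dec$pos else integer(),
                              width = if (nrow(dec)) dec$span_nt else integer())
  )
  rtracklayer::export(gr, paths$decoy, format = "BED")

  # VCF
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=xlburden",
    "##contig=<ID=X>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Hemizygous genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples$sample_id), collapse = "\t")
  )
  body <- character(0)
  if (nrow(sites) > 0 && nrow(samples) > 0) {
    n_s <- nrow(samples)
    ord <- order(match(genotypes$variant_id, vid),
                 match(genotypes$sample_id, samples$sample_id))
    g <- genotypes[ord, , drop = FALSE]
    gt <- ifelse(is.na(g$allele_count), ".", as.character(g$allele_count))
    cell <- paste0(gt, ":", g$depth, ":", g$gq, ":", g$ref_reads, ",", g$alt_reads)
    cells <- matrix(cell, nrow = n_s)  # column v = site v
    gt_fields <- apply(cells, 2, paste, collapse = "\t")
    body <- paste(sites$chrom, sites$pos, vid, sites$ref, sites$alt,
                  ".", ".", ".", "GT:DP:GQ:AD", gt_fields, sep = "\t")
  } else if (nrow(sites) > 0) {
    body <- paste(sites$chrom, sites$pos, vid, sites$ref, sites$alt,
                  ".", ".", ".", "GT:DP:GQ:AD", sep = "\t")
  }
  writeLines(c(header, body), paths$vcf)
  invisible(paths)
}

#' Read a sample sheet TSV
#' @param path file with columns sample_id, phenotype, age, stratum.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(SAMPLE_COLS, names(s))
  if (length(missing)) {
    stop("sample sheet ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  s$sample_id <- as.character(s$sample_id)
  s$phenotype <- as.character(s$phenotype)
  s$age <- as.numeric(s$age)
  s$stratum <- as.character(s$stratum)
  s
}

#' Read a variant annotation TSV
#' @param path annotation file; see [write_cohort()] for the column set.
#' @param decoy_bed optional BED path (or GRanges) used to set `in_decoy`.
#' @return Data frame of sites incl. logical `in_decoy`.
#' @export
read_annotation <- function(path, decoy_bed = NULL) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(ANNOTATION_COLS, names(a))
  if (length(missing)) {
    stop("annotation ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("chrom", "ref", "alt", "gene", "consequence")) {
    a[[col]] <- as.character(a[[col]])
  }
  a$pass_flag <- as.logical(a$pass_flag)
  a$n_alleles <- as.integer(a$n_alleles)
  a$span_nt <- as.integer(a$span_nt)
  a$pos <- as.integer(a$pos)
  a$in_decoy <- if (is.null(decoy_bed)) FALSE else flag_decoy(a, decoy_bed)
  a
}

#' Flag sites overlapping decoy/low-complexity regions
#' @param sites data frame with chrom, pos, span_nt.
#' @param decoy_bed BED file path or a GRanges of regions.
#' @return Logical vector, one per site.
#' @export
flag_decoy <- function(sites, decoy_bed) {
  gr_regions <- if (inherits(decoy_bed, "GRanges")) decoy_bed else {
    if (!file.exists(decoy_bed)) {
      stop("decoy BED not found: ", decoy_bed, call. = FALSE)
    }
    rtracklayer::import(decoy_bed, format = "BED")
  }
  if (nrow(sites) == 0) return(logical(0))
  gr_sites <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos, width = sites$span_nt)
  )
  GenomicRanges::countOverlaps(gr_sites, gr_regions) > 0
}

#' Read hemizygous genotype calls from a VCF
#'
#' Parses haploid GT plus DP/GQ/AD FORMAT fields via vcfR into the package's
#' long genotype format.
#'
#' @param path VCF file.
#' @return Data frame: sample_id, variant_id, allele_count, depth, gq,
#'   ref_reads, alt_reads (site-major order).
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  empty <- data.frame(sample_id = character(), variant_id = character(),
                      allele_count = integer(), depth = integer(),
                      gq = integer(), ref_reads = integer(),
                      alt_reads = integer(), stringsAsFactors = FALSE)
  if (is.null(fix) || NROW(fix) == 0 || ncol(v@gt) <= 1) return(empty)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  vid <- variant_id(fix$CHROM, fix$POS, fix$REF, fix$ALT)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  samples_in <- colnames(gt)
  n_v <- nrow(gt); n_s <- ncol(gt)
  # site-major long format, samples varying fastest (transpose the matrices)
  tv <- function(m) as.vector(t(m))
  gt_v <- tv(gt)
  ad_v <- tv(ad)
  ad_split <- matrix(as.integer(unlist(strsplit(ifelse(is.na(ad_v), "0,0", ad_v),
                                                ",", fixed = TRUE))),
                     ncol = 2, byrow = TRUE)
  data.frame(
    sample_id = rep(samples_in, times = n_v),
    variant_id = rep(vid, each = n_s),
    allele_count = suppressWarnings(as.integer(gt_v)),
    depth = as.integer(tv(dp)),
    gq = as.integer(tv(gq)),
    ref_reads = ad_split[, 1],
    alt_reads = ad_split[, 2],
    stringsAsFactors = FALSE
  )
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir directory holding cohort.vcf, annotation.tsv, samples.tsv,
#'   decoy.bed.
#' @return List with `samples`, `sites`, `genotypes`.
#' @export
read_cohort <- function(dir) {
  samples <- read_sample_sheet(file.path(dir, "samples.tsv"))
  bed <- file.path(dir, "decoy.bed")
  sites <- read_annotation(file.path(dir, "annotation.tsv"),
                           decoy_bed = if (file.exists(bed)) bed else NULL)
  genotypes <- read_genotypes_vcf(file.path(dir, "cohort.vcf"))
  list(samples = samples, sites = sites, genotypes = genotypes)
}
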