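#' Read a VCF into a genotype dosage matrix
#'
#' Parses GT fields of a (optionally bgzipped) VCF into ALT-allele dosage
#' counts.  Multi-allelic sites are dropped (a message reports how many);
#' missing calls (`./.`) are kept as `NA` so that [filter_missing()] can
#' remove the affected variants.  Only diploid autosomal-style calls are
#' supported: haploid GT entries raise an error.
#'
#' @param path path to a VCF (`.vcf` or `.vcf.gz`).
#' @param region optional `"chrom:start-end"` string restricting the variants
#'   (1-based, inclusive).
#' @return a [genotype_matrix()] with ALT-allele counts (pre-recode: columns
#'   are not yet oriented to the minor allele).
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    warn("VCF contains no variants")
    return(genotype_matrix(matrix(integer(), 0, 0), empty_variants()))
  }
  bi <- !grepl(",", fix$ALT %||% "") & !is.na(fix$ALT) & fix$ALT != "."
  n_dropped <- sum(!bi)
  if (n_dropped > 0L) {
    message(sprintf("read_vcf: dropped %d multi-allelic site(s)", n_dropped))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[bi, , drop = FALSE]
  fix <- fix[bi, , drop = FALSE]

  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) abort("region must be of the form 'chrom:start-end'")
    keep <- fix$CHROM == m[2] &
      as.integer(fix$POS) >= as.integer(m[3]) &
      as.integer(fix$POS) <= as.integer(m[4])
    gt <- gt[keep, , drop = FALSE]
    fix <- fix[keep, , drop = FALSE]
    if (nrow(fix) == 0L) warn(sprintf("no variants in region %s", region))
  }

  dos <- gt_to_dosage(gt)  # variants x samples
  variants <- tibble::tibble(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM,
    pos_bp = as.integer(fix$POS),
    ref_allele = fix$REF,
    alt_allele = fix$ALT
  )
  genotype_matrix(t(dos), variants, sample_ids = colnames(gt))
}

gt_to_dosage <- function(gt) {
  out <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  alleles <- gsub("\\|", "/", as.character(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  idx <- match(alleles, names(known))
  out[] <- known[idx]
  is_missing <- is.na(alleles) | alleles %in% c("./.", ".", "./0", "0/.",
                                               "./1", "1/.")
  bad <- !is_missing & is.na(idx)
  if (any(bad)) {
    first <- which(bad)[1]
    abort(sprintf("unsupported GT value '%s' (haploid or multi-allelic?)",
                  alleles[first]))
  }
  out
}

#' Orient dosage columns to count the minor allele
#'
#' Additive recoding: each genotype becomes the number of copies of the
#' *minor* allele carried at the locus.  Columns whose counted (ALT) allele
#' has frequency above 0.5 are flipped (`d -> 2 - d`) and their
#' `minor_allele` set to `"ref"`.  A frequency of exactly 0.5 is left as the
#' ALT allele.  Missing entries are ignored when computing frequencies and
#' preserved in the output.  Populates the `maf` and `minor_allele` columns
#' of the variant table.
#'
#' @param g a [genotype_matrix()] with ALT-count dosages.
#' @return a [genotype_matrix()] with minor-allele dosages and `maf` set.
#' @export
additive_recode <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (n_snps(g) == 0L) {
    g$variants$minor_allele <- character(0)
    g$variants$maf <- double(0)
    return(g)
  }
  freq <- unname(colMeans(g$dosages / 2, na.rm = TRUE))
  freq[is.nan(freq)] <- 0
  flip <- freq > 0.5
  d <- g$dosages
  d[, flip] <- 2L - d[, flip, drop = FALSE]
  g$dosages <- d
  g$variants$minor_allele <- ifelse(flip, "ref", "alt")
  # recompute on the oriented columns so recoding is exactly idempotent
  maf <- unname(colMeans(d / 2, na.rm = TRUE))
  maf[is.nan(maf)] <- 0
  g$variants$maf <- maf
  g
}

#' Filter variants on minor allele frequency
#'
#' Keeps variants whose MAF is strictly greater than `threshold` (the
#' common-variant filter: the default keeps MAF > 0.01).
#'
#' @param g a [genotype_matrix()] whose variant table has `maf` populated
#'   (run [additive_recode()] first).
#' @param threshold MAF cutoff in `[0, 0.5)`; strict inequality.
#' @return the filtered [genotype_matrix()], with attributes `n_kept` and
#'   `n_removed`.
#' @export
filter_maf <- function(g, threshold = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 0.5) {
    abort("threshold must be a single number in [0, 0.5)")
  }
  if (!"maf" %in% names(g$variants)) {
    abort("variant table has no 'maf' column; run additive_recode() first")
  }
  keep <- g$variants$maf > threshold
  out <- g[, keep]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Drop variants with any missing genotype calls
#'
#' Removes every variant with a non-zero missing genotype rate; the result
#' contains no `NA` entries.
#'
#' @param g a [genotype_matrix()].
#' @return the filtered [genotype_matrix()], with attributes `n_kept` and
#'   `n_removed`.
#' @export
filter_missing <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  keep <- colSums(is.na(g$dosages)) == 0L
  if (!any(keep) && n_snps(g) > 0L) {
    warn("all variants have missing calls; result is empty")
  }
  out <- g[, keep]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Write / read a filtered dosage matrix as TSV + JSON manifest
#'
#' The on-disk exchange format is a tab-delimited dosage matrix (one header
#' row of SNP ids, one row per sample with the sample id in the first
#' column) plus a JSON sidecar manifest recording variant metadata
#' (id, chrom, pos, alleles, minor allele, MAF) and sample/phenotype
#' information.  `read_dosage_matrix(write_dosage_matrix(g))` is the
#' identity.
#'
#' @param g a fully filtered [genotype_matrix()] (no missing entries).
#' @param path output path of the TSV; the manifest is written next to it
#'   as `<path>.manifest.json`.
#' @return `write_dosage_matrix` returns `path` invisibly;
#'   `read_dosage_matrix` returns a [genotype_matrix()].
#' @export
write_dosage_matrix <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$dosages)) abort("matrix contains missing entries; filter first")
  df <- as.data.frame(g$dosages)
  df <- cbind(sample_id = g$sample_ids, df)
  readr::write_tsv(df, path, progress = FALSE)
  manifest <- list(
    n_samples = n_samples(g),
    n_snps = n_snps(g),
    variants = as.data.frame(g$variants),
    sample_ids = g$sample_ids,
    phenotype = g$phenotype
  )
  jsonlite::write_json(manifest, manifest_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

manifest_path <- function(path) paste0(path, ".manifest.json")

#' @rdname write_dosage_matrix
#' @export
read_dosage_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("dosage matrix not found: %s", path))
  mp <- manifest_path(path)
  if (!file.exists(mp)) abort(sprintf("manifest not found: %s", mp))
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  dos <- as.matrix(df[, -1, drop = FALSE])
  variants <- tibble::as_tibble(manifest$variants)
  if (length(manifest$variants) == 0L) variants <- empty_variants()
  if (nrow(variants) != ncol(dos) ||
      manifest$n_snps != ncol(dos) || manifest$n_samples != nrow(dos)) {
    abort("manifest/matrix shape mismatch: integrity check failed")
  }
  if (ncol(dos) && !identical(colnames(dos), as.character(variants$id))) {
    abort("manifest/matrix SNP id mismatch: integrity check failed")
  }
  genotype_matrix(dos, variants, sample_ids = df[[1]],
                  phenotype = manifest$phenotype)
}
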