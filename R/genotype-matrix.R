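#' Genotype dosage matrix with variant metadata
#'
#' The central container of the package: an `n_samples x n_snps` integer
#' matrix of allele dosages (0, 1, 2, or `NA` for missing calls) together
#' with a variant table and sample identifiers.  After the standard filter
#' chain ([filter_missing()], [additive_recode()], [filter_maf()]) every
#' column counts copies of the minor allele and contains no missing values.
#'
#' @param dosages integer matrix, samples in rows, variants in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param variants a data frame with one row per variant and columns
#'   `id`, `chrom`, `pos_bp` (1-based), `ref_allele`, `alt_allele`; columns
#'   `minor_allele` (`"ref"` or `"alt"`) and `maf` are added by
#'   [additive_recode()] if absent.
#' @param sample_ids character vector of row identifiers (defaults to
#'   rownames of `dosages` or `S1..Sn`).
#' @param phenotype optional per-sample label (e.g. case/control), recycled
#'   checks apply: must have one entry per sample.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants` (a tibble), `sample_ids`, `phenotype`.
#' @export
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0L, 1L, 2L, 0L, 0L, 1L), nrow = 3),
#'   variants = data.frame(
#'     id = c("rs1", "rs2"), chrom = "22", pos_bp = c(100L, 200L),
#'     ref_allele = "A", alt_allele = "G"
#'   )
#' )
#' n_snps(g)
genotype_matrix <- function(dosages, variants, sample_ids = NULL,
                            phenotype = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  variants <- tibble::as_tibble(variants)
  required <- c("id", "chrom", "pos_bp", "ref_allele", "alt_allele")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    abort(paste0("variants is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(variants) != ncol(dosages)) {
    abort(sprintf(
      "variant table has %d rows but dosage matrix has %d columns",
      nrow(variants), ncol(dosages)
    ))
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    abort("dosages must be 0, 1, 2 or NA")
  }
  if (nrow(variants) > 1L) {
    o <- order(variants$chrom, variants$pos_bp)
    if (!identical(o, seq_len(nrow(variants)))) {
      dosages <- dosages[, o, drop = FALSE]
      variants <- variants[o, ]
    }
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages) %||% sprintf("S%d", seq_len(nrow(dosages)))
  }
  if (length(sample_ids) != nrow(dosages)) {
    abort("sample_ids length must equal the number of dosage rows")
  }
  if (!is.null(phenotype) && length(phenotype) != nrow(dosages)) {
    abort("phenotype must have one entry per sample")
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  structure(
    list(dosages = dosages, variants = variants,
         sample_ids = as.character(sample_ids), phenotype = phenotype),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d SNPs (%s)\n",
    n_samples(x), n_snps(x),
    if (n_snps(x)) paste(unique(x$variants$chrom), collapse = ", ") else "empty"
  ))
  n_na <- sum(is.na(x$dosages))
  if (n_na) cat(sprintf("  %d missing genotype calls\n", n_na))
  if ("maf" %in% names(x$variants) && n_snps(x)) {
    cat(sprintf("  MAF range: %.4f-%.4f\n",
                min(x$variants$maf), max(x$variants$maf)))
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Number of samples / variants in a genotype matrix
#' @param g a [genotype_matrix()]
#' @return an integer count
#' @export
n_samples <- function(g) nrow(g$dosages)

#' @rdname n_samples
#' @export
n_snps <- function(g) ncol(g$dosages)

#' @export
as.matrix.genotype_matrix <- function(x, ...) x$dosages

#' Subset a genotype matrix by samples and/or variants
#'
#' @param x a [genotype_matrix()]
#' @param i sample index (rows)
#' @param j variant index (columns)
#' @param ... ignored
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_snps(x))
  genotype_matrix(
    x$dosages[i, j, drop = FALSE],
    x$variants[j, ],
    sample_ids = x$sample_ids[i],
    phenotype = if (!is.null(x$phenotype)) x$phenotype[i]
  )
}

empty_variants <- function() {
  tibble::tibble(
    id = character(), chrom = character(), pos_bp = integer(),
    ref_allele = character(), alt_allele = character(),
    minor_allele = character(), maf = double()
  )
}
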