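#' Genotype dosage matrix
#'
#' Light container for an n samples by k variants dosage matrix (allele
#' counts 0/1/2) with per-variant metadata: variant identifiers, empirical
#' minor-allele frequencies and, for simulated data, the causal mask.
#'
#' @param dosages numeric matrix, entries in \{0, 1, 2\}, one row per sample.
#' @param variant_ids optional character vector of column labels.
#' @param causal_mask optional logical vector marking simulated causal
#'   variants.
#' @param orient_minor if `TRUE`, columns whose coded-allele frequency
#'   exceeds 0.5 are flipped (`x -> 2 - x`) so that dosages count the minor
#'   allele. File readers re-orient; the simulator keeps its own coding.
#' @return An object of class `genotype_matrix`: the dosage matrix with
#'   attributes `maf` (empirical minor-allele frequency per variant) and
#'   optionally `causal_mask`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 0), 2, 2))
#' attr(g, "maf")
#' @export
genotype_matrix <- function(dosages, variant_ids = NULL, causal_mask = NULL,
                            orient_minor = FALSE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (nrow(dosages) < 2L) stop("need at least 2 samples")
  if (ncol(dosages) < 1L) stop("need at least 1 variant")
  if (anyNA(dosages) || !all(dosages %in% c(0, 1, 2)))
    stop("dosages must be 0, 1 or 2")
  if (!is.null(variant_ids)) {
    stopifnot(length(variant_ids) == ncol(dosages))
    colnames(dosages) <- variant_ids
  } else if (is.null(colnames(dosages))) {
    colnames(dosages) <- paste0("v", seq_len(ncol(dosages)))
  }
  f <- colMeans(dosages) / 2
  if (orient_minor && any(f > 0.5)) {
    flip <- f > 0.5
    dosages[, flip] <- 2 - dosages[, flip]
    f <- colMeans(dosages) / 2
  }
  structure(dosages,
            maf = pmin(f, 1 - f),
            causal_mask = causal_mask,
            class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x), "samples x", ncol(x), "variants\n")
  maf <- attr(x, "maf")
  cat("MAF range:", format(min(maf), digits = 3), "-",
      format(max(maf), digits = 3), "\n")
  if (!is.null(attr(x, "causal_mask")))
    cat("causal variants:", sum(attr(x, "causal_mask")), "\n")
  invisible(x)
}

# plain numeric matrix view (drops class/attributes)
geno_dosages <- function(geno) {
  m <- unclass(as.matrix(geno))
  attr(m, "maf") <- NULL
  attr(m, "causal_mask") <- NULL
  m
}

#' Read a genotype matrix from delimited text or VCF
#'
#' Tab-delimited input must have a header of variant ids and one row of
#' 0/1/2 dosages per sample. VCF input is parsed with \pkg{vcfR}; the dosage
#' is the count of ALT alleles in GT, re-oriented to the minor allele.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("package 'vcfR' is required to read VCF input")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
    ids <- v@fix[, "ID"]
    ids[is.na(ids) | ids == "."] <-
      paste0(v@fix[, "CHROM"], ":", v@fix[, "POS"])[is.na(ids) | ids == "."]
    genotype_matrix(t(dos), variant_ids = ids, orient_minor = TRUE)
  } else {
    m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                     check.names = FALSE))
    genotype_matrix(m, orient_minor = TRUE)
  }
}

#' Read a trait vector (one numeric value per line)
#' @param path file path.
#' @return numeric vector.
#' @export
read_trait <- function(path) {
  y <- scan(path, what = double(), quiet = TRUE)
  if (!all(is.finite(y))) stop("trait values must be finite")
  y
}

#' Write a genotype matrix as tab-delimited text
#' @param geno a [genotype_matrix()] or plain dosage matrix.
#' @param path output path.
#' @export
write_genotypes <- function(geno, path) {
  m <- geno_dosages(geno)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
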