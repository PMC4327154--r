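#' Read a haploid VCF into a haplotype matrix
#'
#' Reads a VCF 4.x file of haploid (or homozygous-diploid) genotypes at
#' biallelic SNP sites. Accepted GT strings are `0`, `1`, `0/0`, `1/1` (and
#' the `|`-phased forms); `.` and `./.` are missing. Heterozygous calls are
#' non-haploid and raise an error naming the sample and position.
#'
#' @param path VCF file path (plain text or bgzipped)
#' @param require_complete if `TRUE` (default), any missing call is an error;
#'   if `FALSE`, sites with one or more missing calls are dropped and their
#'   count reported in a message.
#' @param skip_invalid if `TRUE`, multiallelic and indel records are silently
#'   skipped instead of raising an error.
#' @return a `haplotype_matrix` (unpolarized: `ancestral_known` all `FALSE`)
#' @export
read_haploid_vcf <- function(path, require_complete = TRUE, skip_invalid = FALSE) {
  vcf <- VariantAnnotation::readVcf(path, genome = "MSY")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  alt <- rep(NA_character_, length(n_alt))
  alt[n_alt == 1] <- as.character(unlist(alt_list[n_alt == 1]))

  valid <- n_alt == 1 & !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 & alt != "*"
  if (!all(valid)) {
    if (!skip_invalid)
      ychron_stop(sprintf("non-biallelic-SNP record at %s:%d (multiallelic or indel); set skip_invalid=TRUE to drop",
                          chrom[!valid][1], pos[!valid][1]))
    vcf <- vcf[valid]
    chrom <- chrom[valid]; pos <- pos[valid]; ref <- ref[valid]; alt <- alt[valid]
  }
  key <- paste(chrom, pos)
  if (anyDuplicated(key))
    ychron_stop(sprintf("duplicate position %s", key[duplicated(key)][1]))

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) ychron_stop("VCF has no GT field")
  samples <- colnames(gt)
  gt_clean <- gsub("\\|", "/", gt)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  code[gt_clean %in% c("0", "0/0")] <- 0L
  code[gt_clean %in% c("1", "1/1")] <- 1L
  miss <- gt_clean %in% c(".", "./.")
  het <- !(gt_clean %in% c("0", "0/0", "1", "1/1")) & !miss
  if (any(het)) {
    w <- which(matrix(het, nrow(gt)), arr.ind = TRUE)[1, ]
    ychron_stop(sprintf("non-haploid call '%s' for sample %s at %s:%d",
                        gt[w[1], w[2]], samples[w[2]], chrom[w[1]], pos[w[1]]))
  }

  # sort by chrom, then position
  o <- order(chrom, pos)
  code <- code[o, , drop = FALSE]
  sites <- data.frame(chrom = chrom[o], pos = pos[o], ref = ref[o], alt = alt[o],
                      stringsAsFactors = FALSE)
  calls <- t(code)
  rownames(calls) <- samples
  if (anyNA(calls)) {
    if (require_complete) {
      w <- which(is.na(calls), arr.ind = TRUE)[1, ]
      ychron_stop(sprintf("missing call for sample %s at %s:%d (require_complete=TRUE)",
                          samples[w[1]], sites$chrom[w[2]], sites$pos[w[2]]))
    }
    drop <- colSums(is.na(calls)) > 0
    message(sprintf("read_haploid_vcf: dropped %d site(s) with missing calls", sum(drop)))
    calls <- calls[, !drop, drop = FALSE]
    sites <- sites[!drop, , drop = FALSE]
  }
  haplotype_matrix(calls, sites)
}

#' Write a haplotype matrix as a haploid VCF
#'
#' Emits VCF 4.2 with haploid GT values (`0`, `1`, `.`). Calls coded 1 are
#' written as the ALT allele regardless of polarization; polarization state
#' is not representable in VCF and is carried separately.
#'
#' @param x a `haplotype_matrix`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_haploid_vcf <- function(x, path) {
  stopifnot(inherits(x, "haplotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ychron",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'), con)
  samples <- rownames(x$calls)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  if (ncol(x$calls) > 0) {
    gt <- t(x$calls)                       # sites x samples
    gt_chr <- matrix(as.character(gt), nrow(gt))
    gt_chr[is.na(gt)] <- "."
    body <- paste(x$sites$chrom, x$sites$pos, ".", x$sites$ref, x$sites$alt,
                  ".", ".", ".", "GT",
                  apply(gt_chr, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}
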