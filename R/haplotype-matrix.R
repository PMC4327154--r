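#' Haplotype matrix of haploid biallelic SNP calls
#'
#' The central SNP container: a samples x sites matrix of haploid calls coded
#' 0 (reference, or ancestral once polarized), 1 (alternate/derived) or `NA`
#' (missing), together with a site table (chromosome, 1-based position, ref,
#' alt) and a per-site flag saying whether the ancestral state is known.
#'
#' @param calls integer matrix, samples in rows (rownames = sample ids),
#'   sites in columns; values in `{0, 1, NA}`.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`; one row
#'   per column of `calls`. Positions must be strictly increasing within each
#'   chromosome. Single-base ref and alt, ref != alt.
#' @param ancestral_known logical per site; `TRUE` means code 0 is the
#'   ancestral state (site is polarized). Defaults to all `FALSE`.
#' @return an object of class `haplotype_matrix`
#' @examples
#' hm <- haplotype_matrix(
#'   matrix(c(0L, 1L, 1L, 0L), 2, 2, dimnames = list(c("S1", "S2"), NULL)),
#'   data.frame(chrom = "chrY", pos = c(100L, 200L), ref = c("A", "C"),
#'              alt = c("G", "T")))
#' hm
#' @export
haplotype_matrix <- function(calls, sites, ancestral_known = NULL) {
  if (!is.matrix(calls)) ychron_stop("`calls` must be a matrix")
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) ychron_stop("`calls` must have sample ids as rownames")
  if (anyDuplicated(rownames(calls)))
    ychron_stop("duplicate sample ids in haplotype matrix")
  bad <- !(calls %in% c(0L, 1L, NA_integer_))
  if (any(bad)) ychron_stop("calls must be coded 0, 1 or NA")
  sites <- as.data.frame(sites)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites)))
    ychron_stop("`sites` needs columns chrom, pos, ref, alt")
  if (nrow(sites) != ncol(calls))
    ychron_stop("site table and call matrix disagree on the number of sites")
  if (nrow(sites) > 0) {
    one_base <- nchar(sites$ref) == 1L & nchar(sites$alt) == 1L
    if (!all(one_base)) ychron_stop("non-SNP site: ref and alt must be single bases")
    if (any(sites$ref == sites$alt)) ychron_stop("site with ref == alt")
    for (ch in unique(sites$chrom)) {
      p <- sites$pos[sites$chrom == ch]
      if (any(diff(p) <= 0))
        ychron_stop(sprintf("positions not strictly increasing on %s (duplicate or unsorted)", ch))
    }
  }
  ids <- site_ids(sites)
  colnames(calls) <- ids
  rownames(sites) <- ids
  if (is.null(ancestral_known)) ancestral_known <- rep(FALSE, nrow(sites))
  stopifnot(length(ancestral_known) == nrow(sites))
  structure(list(calls = calls, sites = sites,
                 ancestral_known = as.logical(ancestral_known)),
            class = "haplotype_matrix")
}

site_ids <- function(sites) {
  if (nrow(sites) == 0) return(character())
  paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("<haplotype_matrix> %d samples x %d sites; %d missing calls; %d/%d sites polarized\n",
              nrow(x$calls), ncol(x$calls), sum(is.na(x$calls)),
              sum(x$ancestral_known), ncol(x$calls)))
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$calls)

#' Sample ids of a container
#'
#' @param x a `haplotype_matrix`, `str_profile_table` or `mutation_tree`
#' @return character vector of sample ids
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.haplotype_matrix <- function(x) rownames(x$calls)

#' Subset a haplotype matrix by samples and/or sites
#'
#' @param x a `haplotype_matrix`
#' @param samples character or index vector of samples to keep
#' @param sites character or index vector of site ids to keep
#' @return a `haplotype_matrix`
#' @export
hm_subset <- function(x, samples = NULL, sites = NULL) {
  calls <- x$calls
  keep_sites <- if (is.null(sites)) seq_len(ncol(calls)) else sites
  keep_samp <- if (is.null(samples)) seq_len(nrow(calls)) else samples
  calls <- calls[keep_samp, keep_sites, drop = FALSE]
  st <- x$sites[keep_sites, , drop = FALSE]
  haplotype_matrix(calls, st, x$ancestral_known[if (is.character(keep_sites))
    match(keep_sites, rownames(x$sites)) else keep_sites])
}
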