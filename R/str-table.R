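#' Built-in Y-STR marker subset registry
#'
#' The three dating subsets used throughout the package, derived from the
#' 23-locus PowerPlex Y23 panel:
#' \describe{
#'   \item{set21}{all loci minus the bilocal DYS385a/b pair (21 loci);}
#'   \item{set17}{set21 minus the rapidly mutating loci DYS570 and DYS576 and
#'     the complex/interrupted-array loci DYS389II and DYS448 (17 loci);}
#'   \item{set13}{set17 minus the non-Yfiler loci DYS481, DYS533, DYS549 and
#'     DYS643 (13 loci).}
#' }
#' Bilocal loci (DYS385a/b) are never part of any dating subset.
#'
#' @return named list of character vectors of locus names
#' @export
str_subsets <- function() {
  base <- c("DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
            "DYS393", "DYS437", "DYS438", "DYS439", "DYS448", "DYS456",
            "DYS458", "DYS635", "GATAH4", "DYS481", "DYS533", "DYS549",
            "DYS570", "DYS576", "DYS643")
  set21 <- base
  set17 <- setdiff(set21, c("DYS570", "DYS576", "DYS389II", "DYS448"))
  set13 <- setdiff(set17, c("DYS481", "DYS533", "DYS549", "DYS643"))
  list(set21 = set21, set17 = set17, set13 = set13)
}

#' Loci flagged as bilocal (two co-amplified copies)
#' @return character vector of locus-name prefixes treated as bilocal
#' @keywords internal
bilocal_loci <- function() c("DYS385", "DYS385a", "DYS385b", "DYS385ab")

#' STR profile table
#'
#' Samples x loci integer repeat counts with the dating-subset registry
#' attached. Bilocal loci (any DYS385 column) are kept in the table but
#' flagged and excluded from every dating subset.
#'
#' @param counts integer matrix, samples in rows (rownames = sample ids),
#'   loci in columns (colnames = locus names); nonnegative integers, `NA`
#'   allowed for missing.
#' @return an object of class `str_profile_table`
#' @export
str_profile_table <- function(counts) {
  if (!is.matrix(counts)) ychron_stop("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    ychron_stop("STR table needs sample rownames and locus colnames")
  if (anyDuplicated(rownames(counts))) ychron_stop("duplicate sample ids in STR table")
  if (anyDuplicated(colnames(counts))) ychron_stop("duplicate locus names in STR table")
  if (!is.numeric(counts) || any(counts[!is.na(counts)] != floor(counts[!is.na(counts)])))
    ychron_stop("non-integer STR allele")
  if (any(counts[!is.na(counts)] < 0)) ychron_stop("negative repeat count")
  storage.mode(counts) <- "integer"
  bilocal <- grepl("^DYS385", colnames(counts))
  structure(list(counts = counts, bilocal = bilocal, subsets = str_subsets()),
            class = "str_profile_table")
}

#' @export
print.str_profile_table <- function(x, ...) {
  cat(sprintf("<str_profile_table> %d samples x %d loci (%d bilocal, excluded from dating)\n",
              nrow(x$counts), ncol(x$counts), sum(x$bilocal)))
  invisible(x)
}

#' @export
sample_ids.str_profile_table <- function(x) rownames(x$counts)

#' Resolve a marker subset against an STR table
#'
#' Returns the loci of a registered subset that the table contains. A locus
#' listed in the subset but absent from the table is an error -- unless it is
#' one of the loci the subset definition itself excludes relative to the full
#' panel (so e.g. `set17` resolves on a table that never typed DYS570).
#'
#' @param x an `str_profile_table`
#' @param subset subset name (`"set21"`, `"set17"`, `"set13"`) or an explicit
#'   character vector of locus names
#' @return character vector of locus names, all present in the table
#' @export
str_subset_loci <- function(x, subset) {
  stopifnot(inherits(x, "str_profile_table"))
  loci <- if (is.character(subset) && length(subset) == 1 && subset %in% names(x$subsets))
    x$subsets[[subset]] else as.character(subset)
  if (any(grepl("^DYS385", loci)))
    ychron_stop("bilocal DYS385 loci cannot be used in a dating subset")
  missing <- setdiff(loci, colnames(x$counts))
  if (length(missing))
    ychron_stop(sprintf("subset locus not in table: %s", paste(missing, collapse = ", ")))
  loci
}

#' Read an STR profile table from a tab-delimited file
#'
#' Expects a header of locus names, a first column of sample ids, and integer
#' repeat counts (empty or `NA` for missing).
#'
#' @param path file path
#' @return an `str_profile_table`
#' @export
read_str_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) ychron_stop("STR table needs a sample column plus loci")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- apply(m, 2, as.numeric))
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(m), dimnames = dimnames(m))
  bad <- !is.na(m) & m != "" & (is.na(num) | num != floor(num))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    ychron_stop(sprintf("non-integer allele '%s' for sample %s at locus %s",
                        m[bad][1], ids[w[1]], colnames(m)[w[2]]))
  }
  rownames(num) <- ids
  str_profile_table(num)
}

#' Write an STR profile table
#' @param x an `str_profile_table`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_str_table <- function(x, path) {
  df <- data.frame(sample = rownames(x$counts), x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
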