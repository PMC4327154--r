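TISSUE_SOURCES <- c("LCL", "blood", "saliva", "unknown")

#' Sample metadata table
#'
#' @param df data.frame with columns `sample_id`, `population`, `region`,
#'   `tissue_source` (one of LCL, blood, saliva, unknown) and optionally
#'   `haplogroup` (free string).
#' @return a `sample_meta` data.frame
#' @export
sample_meta <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "region", "tissue_source")
  if (!all(need %in% names(df)))
    ychron_stop("metadata needs columns sample_id, population, region, tissue_source")
  if (anyDuplicated(df$sample_id)) ychron_stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(df$tissue_source), TISSUE_SOURCES)
  if (length(bad))
    ychron_stop(sprintf("tissue_source not in {%s}: %s",
                        paste(TISSUE_SOURCES, collapse = ", "), paste(bad, collapse = ", ")))
  if (is.null(df$haplogroup)) df$haplogroup <- NA_character_
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Read / write sample metadata (tab-delimited)
#'
#' @param path file path
#' @param matrix optional `haplotype_matrix`; if given, every metadata sample
#'   must be present in it.
#' @return a `sample_meta` data.frame
#' @export
read_sample_meta <- function(path, matrix = NULL) {
  df <- sample_meta(utils::read.delim(path, stringsAsFactors = FALSE))
  if (!is.null(matrix)) {
    orphan <- setdiff(df$sample_id, sample_ids(matrix))
    if (length(orphan))
      ychron_stop(sprintf("metadata sample absent from matrix: %s",
                          paste(orphan, collapse = ", ")))
  }
  df
}

#' @rdname read_sample_meta
#' @param x a `sample_meta` data.frame
#' @export
write_sample_meta <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
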