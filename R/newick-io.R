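#' Serialize a mutation tree to Newick
#'
#' Branch lengths encode integer mutation counts; internal node labels are
#' preserved so the event sidecar table (see [write_events()]) can reference
#' branches. Stem events are written as a root edge. Newick cannot carry
#' per-mutation detail, so `write_newick()` alone loses the site-to-branch
#' map; use [write_tree_files()] to keep it.
#'
#' @param tree a `mutation_tree`
#' @param path optional file path; if `NULL` the Newick string is returned
#' @return the Newick string (invisibly when `path` is given)
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "mutation_tree"))
  phy <- tree$phy
  if (nrow(tree$events) > 0) {
    bs <- branch_stats(tree)
    phy$edge.length <- bs$l_b[match(node_id(phy, phy$edge[, 2]), bs$branch)]
    stem <- sum(is.na(tree$events$branch))
    if (stem > 0) phy$root.edge <- stem
  } else if (is.null(phy$edge.length)) {
    phy$edge.length <- rep(0, nrow(phy$edge))
  }
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a Newick tree into a mutation tree
#'
#' The inverse of [write_newick()]: topology, labels and integer branch
#' lengths round-trip exactly. The event table is empty unless an event
#' sidecar is supplied via [read_tree_files()]. Malformed Newick raises a
#' parse error reporting the character offset of the first unbalanced
#' parenthesis.
#'
#' @param text Newick string, or `NULL` when `path` is given
#' @param path file to read instead of `text`
#' @return a `mutation_tree`
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      ychron_stop(sprintf("Newick parse error: unbalanced ')' at character %d", i))
  }
  if (depth != 0L)
    ychron_stop(sprintf("Newick parse error: %d unclosed '(' at character %d",
                        depth, length(chars)))
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) ychron_stop(paste("Newick parse error:", conditionMessage(e))))
  if (is.null(phy)) ychron_stop("Newick parse error: no tree found")
  mutation_tree(phy)
}

#' Write / read the per-mutation event sidecar
#'
#' Tab-delimited table with columns `site_id`, `branch` (node id below the
#' branch; empty = stem above the root), `direction` (`gain`/`loss`) and
#' `compatible`.
#'
#' @param tree a `mutation_tree`
#' @param path file path
#' @return `path` invisibly (write); data.frame (read)
#' @export
write_events <- function(tree, path) {
  ev <- tree$events
  ev$branch[is.na(ev$branch)] <- ""
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(site_id = "character", branch = "character"))
  ev$branch[ev$branch == ""] <- NA_character_
  ev$compatible <- as.logical(ev$compatible)
  ev
}

#' Write / read a mutation tree as Newick plus event sidecar
#'
#' @param tree a `mutation_tree`
#' @param newick_path,events_path file paths
#' @return (read) a `mutation_tree` with events attached
#' @export
write_tree_files <- function(tree, newick_path, events_path) {
  write_newick(tree, newick_path)
  write_events(tree, events_path)
  invisible(newick_path)
}

#' @rdname write_tree_files
#' @export
read_tree_files <- function(newick_path, events_path) {
  tr <- read_newick(path = newick_path)
  ev <- read_events(events_path)
  mutation_tree(tr$phy, ev)
}
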