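#' Rooted mutation-annotated tree
#'
#' Wraps an [ape::read.tree()]-style `phylo` object (rooted, polytomies
#' allowed, branch lengths = integer mutation counts) together with the
#' per-branch event table. Branches are identified by the name of the node
#' below them: a tip label for terminal branches, a node label (`N1`, `N2`,
#' ...; the root is `ROOT`) for internal ones. Events with `branch = NA` sit
#' on the stem above the root (mutations shared by every sample, or inferred
#' above-root gains for back-mutated sites) and are excluded from all
#' within-tree statistics.
#'
#' @param phy a rooted `phylo` with unique tip labels and node labels
#' @param events data.frame with columns `site_id`, `branch`, `direction`
#'   (`"gain"` or `"loss"`), `compatible` (logical); may have zero rows
#' @param node_times optional named numeric vector of node ages in years
#'   before present (tips usually 0), names = tip and node labels
#' @return an object of class `mutation_tree`
#' @export
mutation_tree <- function(phy, events = NULL,
                          node_times = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label)) ychron_stop("duplicate tip labels")
  if (is.null(phy$node.label))
    phy$node.label <- c("ROOT", paste0("N", seq_len(phy$Nnode - 1)))[seq_len(phy$Nnode)]
  if (is.null(events))
    events <- data.frame(site_id = character(), branch = character(),
                         direction = character(), compatible = logical(),
                         stringsAsFactors = FALSE)
  known <- c(phy$tip.label, phy$node.label)
  bad <- !is.na(events$branch) & !(events$branch %in% known)
  if (any(bad))
    ychron_stop(sprintf("event references unknown branch: %s", events$branch[bad][1]))
  structure(list(phy = phy, events = events, node_times = node_times),
            class = "mutation_tree")
}

#' @export
print.mutation_tree <- function(x, ...) {
  cat(sprintf("<mutation_tree> %d tips, %d internal nodes, %d mutation events (%d on stem)\n",
              length(x$phy$tip.label), x$phy$Nnode, nrow(x$events),
              sum(is.na(x$events$branch))))
  invisible(x)
}

#' @export
sample_ids.mutation_tree <- function(x) x$phy$tip.label

# node number (phylo indexing) for a branch/clade id; tips 1..Ntip, internal
# Ntip+1..Ntip+Nnode
node_number <- function(phy, id) {
  nt <- length(phy$tip.label)
  i <- match(id, phy$tip.label)
  if (!is.na(i)) return(i)
  j <- match(id, phy$node.label)
  if (is.na(j)) ychron_stop(sprintf("unknown node '%s'", id))
  nt + j
}

node_id <- function(phy, num) {
  nt <- length(phy$tip.label)
  out <- character(length(num))
  tip <- num <= nt
  out[tip] <- phy$tip.label[num[tip]]
  out[!tip] <- phy$node.label[num[!tip] - nt]
  out
}

# number of descendant tips below each node (index = node number)
tip_counts <- function(phy) {
  nt <- length(phy$tip.label)
  n <- nt + phy$Nnode
  cnt <- c(rep(1L, nt), rep(0L, phy$Nnode))
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge)))
    cnt[po$edge[k, 1]] <- cnt[po$edge[k, 1]] + cnt[po$edge[k, 2]]
  cnt
}

# tips (numbers) below a node number
tips_below <- function(phy, num) {
  nt <- length(phy$tip.label)
  if (num <= nt) return(num)
  po <- ape::reorder.phylo(phy, "postorder")
  below <- logical(nt + phy$Nnode)
  below[num] <- TRUE
  for (k in rev(seq_len(nrow(po$edge))))   # preorder sweep
    if (below[po$edge[k, 1]]) below[po$edge[k, 2]] <- TRUE
  which(below[seq_len(nt)])
}

#' Per-branch mutation and descendant-tip counts
#'
#' For every branch: its id (name of the node below it), the number of
#' mutation events it carries (`l_b`, from the event table, or from the
#' Newick branch length for trees read without an event sidecar) and the
#' number of tips below it (`n_b`). These are the branch sums that the rho
#' statistic and its standard deviation are built from.
#'
#' @param tree a `mutation_tree`
#' @return data.frame with columns `branch`, `l_b`, `n_b`, `parent`
#' @export
branch_stats <- function(tree) {
  phy <- tree$phy
  cnt <- tip_counts(phy)
  child <- phy$edge[, 2]
  ids <- node_id(phy, child)
  ev <- tree$events
  if (nrow(ev) > 0) {
    l <- as.integer(table(factor(ev$branch[!is.na(ev$branch)], levels = ids)))
  } else if (!is.null(phy$edge.length)) {
    l <- as.integer(round(phy$edge.length))
  } else {
    l <- rep(0L, length(ids))
  }
  data.frame(branch = ids, l_b = l, n_b = cnt[child],
             parent = node_id(phy, phy$edge[, 1]),
             stringsAsFactors = FALSE)
}
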