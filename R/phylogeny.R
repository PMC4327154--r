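#' Polarize a haplotype matrix to derived-allele coding
#'
#' Recodes calls so that 1 always means the derived state. The ancestral
#' state at each site is taken from one of three sources: an outgroup sample
#' contained in the matrix, an ancestral-allele table, or the convention that
#' the reference allele is ancestral. Sites whose ancestral state cannot be
#' resolved (missing outgroup call, allele matching neither ref nor alt) are
#' flagged `ancestral_known = FALSE` and reported; they are excluded from
#' tree building by default, never guessed.
#'
#' @param x a `haplotype_matrix`
#' @param ancestral one of: a single sample id present in `x` (outgroup); a
#'   data.frame with columns `site_id` and `allele`; or the string `"ref"`.
#' @param drop_outgroup drop the outgroup row from the returned matrix
#'   (default `TRUE`)
#' @return a `haplotype_matrix` with derived coding, `ancestral_known` set,
#'   and a per-site `ancestral` allele column added to the site table
#' @export
polarize <- function(x, ancestral, drop_outgroup = TRUE) {
  stopifnot(inherits(x, "haplotype_matrix"))
  sites <- x$sites
  m <- nrow(sites)
  anc_allele <- rep(NA_character_, m)
  if (is.character(ancestral) && length(ancestral) == 1 && ancestral == "ref") {
    anc_allele <- sites$ref
  } else if (is.character(ancestral) && length(ancestral) == 1) {
    if (!(ancestral %in% rownames(x$calls)))
      ychron_stop(sprintf("outgroup sample '%s' not in matrix", ancestral))
    og <- x$calls[ancestral, ]
    anc_allele <- ifelse(is.na(og), NA_character_,
                         ifelse(og == 0L, sites$ref, sites$alt))
  } else if (is.data.frame(ancestral)) {
    i <- match(rownames(sites), ancestral$site_id)
    anc_allele <- as.character(ancestral$allele[i])
  } else {
    ychron_stop("`ancestral` must be \"ref\", an outgroup sample id, or a site table")
  }
  known <- !is.na(anc_allele) & (anc_allele == sites$ref | anc_allele == sites$alt)
  flip <- known & anc_allele == sites$alt
  calls <- x$calls
  if (is.character(ancestral) && length(ancestral) == 1 && ancestral != "ref" &&
      drop_outgroup)
    calls <- calls[setdiff(rownames(calls), ancestral), , drop = FALSE]
  if (any(flip)) calls[, flip] <- 1L - calls[, flip]
  out <- haplotype_matrix(calls, sites, ancestral_known = known)
  out$sites$ancestral <- anc_allele
  if (any(!known))
    message(sprintf("polarize: %d site(s) unresolvable, flagged ancestral_known=FALSE",
                    sum(!known)))
  out
}

# -- Sankoff / Fitch small parsimony for a two-state character ---------------

# Minimal-change placement of a derived-carrier set on a fixed rooted tree
# (unit costs, polytomies handled exactly). Root state is free: an optimal
# derived root implies a single gain on the stem above the root, counted as
# an event with branch NA and flagged as a possible back-mutation pattern.
# Tie rules (deterministic): root tie -> ancestral; keep-vs-switch tie at an
# internal edge -> keep the parent state, pushing events toward the tips.
sankoff_place <- function(phy, carrier_tips) {
  nt <- length(phy$tip.label)
  nn <- nt + phy$Nnode
  state <- rep(NA_integer_, nn)
  cost <- matrix(0, nn, 2)                       # cost[, s+1] given node state s
  obs <- integer(nt)
  obs[carrier_tips] <- 1L
  cost[seq_len(nt), ] <- Inf
  cost[cbind(seq_len(nt), obs + 1L)] <- 0
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    cost[p, 1] <- cost[p, 1] + min(cost[ch, 1], cost[ch, 2] + 1)
    cost[p, 2] <- cost[p, 2] + min(cost[ch, 2], cost[ch, 1] + 1)
  }
  root <- nt + 1L
  root_state <- if (cost[root, 1] <= cost[root, 2]) 0L else 1L
  state[root] <- root_state
  ev_branch <- character(); ev_dir <- character()
  for (k in rev(seq_len(nrow(po$edge)))) {       # preorder
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    s <- state[p]
    keep <- cost[ch, s + 1L]
    switch_ <- cost[ch, 2L - s] + 1
    if (keep <= switch_) {
      state[ch] <- s
    } else {
      state[ch] <- 1L - s
      ev_branch <- c(ev_branch, node_id(phy, ch))
      ev_dir <- c(ev_dir, if (s == 0L) "gain" else "loss")
    }
  }
  n_in_tree <- length(ev_dir)
  if (root_state == 1L) {
    # implied gain on the stem above the root; reported but not counted as a
    # within-tree state change (n_events matches exhaustive two-state
    # parsimony with a free root)
    ev_branch <- c(NA_character_, ev_branch)
    ev_dir <- c("gain", ev_dir)
  }
  list(n_events = n_in_tree,
       events = data.frame(branch = ev_branch, direction = ev_dir,
                           stringsAsFactors = FALSE),
       back_mutation = root_state == 1L,
       min_changes = min(cost[root, ]))
}

#' Parsimony placement of a (possibly recurrent) site on a fixed tree
#'
#' Computes the minimum number of state changes needed to explain a
#' derived-carrier set on the tree (two-state small parsimony, exact on
#' polytomies) and one deterministic optimal assignment of events to
#' branches. A carrier set equal to an existing clade needs one event; sets
#' incompatible with the tree need at least two. When the optimal root state
#' is derived the pattern is consistent with a back-mutation (gain above the
#' root, loss inside) and is flagged.
#'
#' @param tree a `mutation_tree`
#' @param carriers character vector of tip ids carrying the derived state
#' @return list with `n_events`, `events` (branch/direction data.frame),
#'   `back_mutation`
#' @export
place_recurrent <- function(tree, carriers) {
  stopifnot(inherits(tree, "mutation_tree"))
  if (length(carriers) == 0) ychron_stop("empty carrier set")
  idx <- match(carriers, tree$phy$tip.label)
  if (anyNA(idx))
    ychron_stop(sprintf("unknown tip in carrier set: %s", carriers[is.na(idx)][1]))
  sankoff_place(tree$phy, idx)
}

# -- rooted perfect phylogeny + parsimony placement --------------------------

#' Build the rooted mutation-annotated tree from derived-coded haplotypes
#'
#' Sites whose derived-carrier sets form a laminar family (pairwise nested or
#' disjoint) admit a perfect phylogeny: each such site maps to exactly one
#' branch. Carrier sets are processed in decreasing size order and accepted
#' greedily while they stay laminar with everything accepted so far; the
#' accepted family defines the rooted tree (polytomies retained, identical
#' haplotypes attached by zero-length branches). Each rejected (recurrent)
#' site is then placed on the fixed tree by exact two-state parsimony
#' ([place_recurrent()]), contributing >= 2 events. Sites derived in every
#' sample are stem events above the root.
#'
#' @param x a `haplotype_matrix` in derived coding. Sites flagged
#'   `ancestral_known = FALSE` are excluded (if no site is flagged, the whole
#'   matrix is assumed derived-coded already). Missing calls among used sites
#'   are an error.
#' @return a `mutation_tree`; its `site_report` element is a data.frame with
#'   one row per used site: `site_id`, `compatible`, `n_events`
#' @export
build_tree <- function(x) {
  stopifnot(inherits(x, "haplotype_matrix"))
  use <- if (any(x$ancestral_known)) x$ancestral_known else rep(TRUE, ncol(x$calls))
  calls <- x$calls[, use, drop = FALSE]
  if (ncol(calls) == 0) ychron_stop("no usable (polarized) sites")
  if (nrow(calls) == 0) ychron_stop("empty matrix")
  if (anyNA(calls)) ychron_stop("missing calls among tree-building sites")
  samples <- rownames(calls)
  n <- length(samples)
  site_id <- colnames(calls)
  sizes <- colSums(calls)

  report <- data.frame(site_id = site_id, compatible = NA, n_events = NA_integer_,
                       stringsAsFactors = FALSE)
  ev_list <- list()
  mono <- sizes == 0L
  report$n_events[mono] <- 0L
  stem <- sizes == n
  report$compatible[stem] <- TRUE
  report$n_events[stem] <- 1L
  if (any(stem))
    ev_list[["stem"]] <- data.frame(site_id = site_id[stem], branch = NA_character_,
                                    direction = "gain", compatible = TRUE,
                                    stringsAsFactors = FALSE)

  seg <- which(!mono & !stem)
  pat_key <- apply(calls[, seg, drop = FALSE], 2, paste, collapse = "")
  first <- !duplicated(pat_key)
  upat <- calls[, seg[first], drop = FALSE]           # n x k unique carrier sets
  ukey <- pat_key[first]
  k <- ncol(upat)
  ord <- order(-colSums(upat), seq_len(k))            # decreasing size, stable
  acc <- logical(k)
  A <- matrix(FALSE, nrow = n, ncol = 0)
  asz <- integer(0)
  for (j in ord) {
    cvec <- upat[, j] == 1L
    csz <- sum(cvec)
    if (ncol(A) > 0) {
      iv <- as.integer(crossprod(A, cvec))
      if (!all(iv == 0L | iv == csz | iv == asz)) next
    }
    acc[j] <- TRUE
    A <- cbind(A, cvec)
    asz <- c(asz, csz)
  }

  # tree from the accepted laminar family
  acc_idx <- which(acc)
  int_idx <- acc_idx[colSums(upat[, acc_idx, drop = FALSE]) >= 2]
  int_ord <- int_idx[order(-colSums(upat[, int_idx, drop = FALSE]))]
  n_int <- length(int_ord)
  root_num <- n + 1L
  int_sets <- lapply(int_ord, function(j) which(upat[, j] == 1L))
  int_size <- vapply(int_sets, length, 1L)
  parent_of <- function(members) {
    # smallest accepted internal set strictly containing `members`
    best <- 0L; best_size <- n + 1L
    for (ii in seq_len(n_int)) {
      if (int_size[ii] <= length(members)) next
      if (all(members %in% int_sets[[ii]]) && int_size[ii] < best_size) {
        best <- ii; best_size <- int_size[ii]
      }
    }
    if (best == 0L) root_num else root_num + best
  }
  edges <- matrix(0L, nrow = 0, ncol = 2)
  for (ii in seq_len(n_int))
    edges <- rbind(edges, c(parent_of(int_sets[[ii]]), root_num + ii))
  for (tip in seq_len(n)) {
    small <- 0L; small_size <- n + 1L
    for (ii in seq_len(n_int))
      if (tip %in% int_sets[[ii]] && int_size[ii] < small_size) {
        small <- ii; small_size <- int_size[ii]
      }
    edges <- rbind(edges, c(if (small == 0L) root_num else root_num + small, tip))
  }
  phy <- structure(list(edge = edges, Nnode = n_int + 1L, tip.label = samples,
                        edge.length = rep(0, nrow(edges)),
                        node.label = c("ROOT", if (n_int > 0) paste0("N", seq_len(n_int)))),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")

  # map compatible sites to branches: singleton sets sit on the tip edge,
  # larger accepted sets on the edge above their clade node
  branch_of_pat <- rep(NA_character_, k)
  for (j in acc_idx) {
    members <- which(upat[, j] == 1L)
    if (length(members) == 1L) branch_of_pat[j] <- samples[members]
  }
  for (ii in seq_len(n_int)) branch_of_pat[int_ord[ii]] <- paste0("N", ii)

  pat_of_site <- match(pat_key, ukey)                 # per segregating site
  comp_sites <- seg[acc[pat_of_site]]
  if (length(comp_sites)) {
    br <- branch_of_pat[pat_of_site[acc[pat_of_site]]]
    ev_list[["compat"]] <- data.frame(site_id = site_id[comp_sites], branch = br,
                                      direction = "gain", compatible = TRUE,
                                      stringsAsFactors = FALSE)
    report$compatible[comp_sites] <- TRUE
    report$n_events[comp_sites] <- 1L
  }

  # parsimony placement of rejected (recurrent) sites
  rej_sites <- seg[!acc[pat_of_site]]
  for (s in rej_sites) {
    pl <- sankoff_place(phy, which(calls[, s] == 1L))
    ev_list[[paste0("rej", s)]] <-
      data.frame(site_id = site_id[s], branch = pl$events$branch,
                 direction = pl$events$direction, compatible = FALSE,
                 stringsAsFactors = FALSE)
    report$compatible[s] <- FALSE
    report$n_events[s] <- pl$n_events
  }

  events <- do.call(rbind, ev_list)
  if (is.null(events))
    events <- data.frame(site_id = character(), branch = character(),
                         direction = character(), compatible = logical())
  rownames(events) <- NULL
  tree <- mutation_tree(phy, events)
  bs <- branch_stats(tree)
  tree$phy$edge.length <- bs$l_b[match(node_id(phy, tree$phy$edge[, 2]), bs$branch)]
  tree$site_report <- report
  tree
}

#' Mutation count from each tip to the root
#'
#' The number of mutation events on the path from a tip to the root of the
#' tree (stem events excluded). The mean over all tips equals the rho
#' statistic of the whole tree.
#'
#' @param tree a `mutation_tree`
#' @return named integer vector, one entry per tip
#' @export
mutations_to_root <- function(tree) {
  stopifnot(inherits(tree, "mutation_tree"))
  phy <- tree$phy
  bs <- branch_stats(tree)
  l_of <- setNames(bs$l_b, bs$branch)
  nt <- length(phy$tip.label)
  depth <- numeric(nt + phy$Nnode)
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in rev(seq_len(nrow(po$edge)))) {      # preorder
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    depth[ch] <- depth[p] + l_of[[node_id(phy, ch)]]
  }
  setNames(as.integer(depth[seq_len(nt)]), phy$tip.label)
}

#' Groups of samples indistinguishable under a marker set
#'
#' Partitions samples into identity classes: for a haplotype matrix, samples
#' with identical calls at every site; for an STR table, identical repeat
#' counts at the loci of the chosen subset. When an STR table is grouped and
#' a SNP matrix is also supplied, the pairwise SNP-difference counts inside
#' each STR-identical group are reported (how many SNPs separate samples the
#' STRs cannot tell apart).
#'
#' @param x a `haplotype_matrix` or `str_profile_table`
#' @param subset marker subset name or locus vector (STR tables only;
#'   default: all non-bilocal loci)
#' @param snp optional `haplotype_matrix` for SNP-difference counts
#' @return list with `groups` (identity classes with >= 2 members),
#'   `n_classes`, `class_sizes` (table), and `snp_differences` (per group,
#'   when `snp` is given)
#' @export
identical_groups <- function(x, subset = NULL, snp = NULL) {
  if (inherits(x, "haplotype_matrix")) {
    m <- x$calls
  } else if (inherits(x, "str_profile_table")) {
    loci <- if (is.null(subset)) colnames(x$counts)[!x$bilocal]
            else str_subset_loci(x, subset)
    m <- x$counts[, loci, drop = FALSE]
  } else ychron_stop("x must be a haplotype_matrix or str_profile_table")
  key <- apply(m, 1, paste, collapse = ",")
  cls <- split(rownames(m), key)
  groups <- unname(cls[lengths(cls) >= 2])
  groups <- groups[order(vapply(groups, `[`, "", 1))]
  out <- list(groups = groups, n_classes = length(cls),
              class_sizes = table(lengths(cls)))
  if (!is.null(snp) && length(groups)) {
    stopifnot(inherits(snp, "haplotype_matrix"))
    out$snp_differences <- lapply(groups, function(g) {
      g <- intersect(g, rownames(snp$calls))
      if (length(g) < 2) return(integer(0))
      prs <- utils::combn(g, 2)
      d <- apply(prs, 2, function(p)
        sum(snp$calls[p[1], ] != snp$calls[p[2], ], na.rm = TRUE))
      setNames(d, apply(prs, 2, paste, collapse = "|"))
    })
  }
  out
}
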