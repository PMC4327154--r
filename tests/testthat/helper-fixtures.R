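# shared fixtures and independent oracles, all built in code

# the worked 4-tip dataset: derived-carrier sets
#   site1 = {S1,S2}, site2 = {S3,S4}, site3 = {S1}, site4 = {S3,S4}
# expected tree: ({S1,S2}: l=1) with (S1: l=1), ({S3,S4}: l=2)
worked_matrix <- function(with_incompatible = FALSE) {
  calls <- matrix(0L, 4, 4, dimnames = list(c("S1", "S2", "S3", "S4"), NULL))
  calls[c(1, 2), 1] <- 1L
  calls[c(3, 4), 2] <- 1L
  calls[1, 3] <- 1L
  calls[c(3, 4), 4] <- 1L
  pos <- c(100L, 200L, 300L, 400L)
  if (with_incompatible) {           # site5 = {S2,S3}, crosses both clades
    calls <- cbind(calls, c(0L, 1L, 1L, 0L))
    pos <- c(pos, 500L)
  }
  haplotype_matrix(calls, data.frame(chrom = "chrY", pos = pos,
                                     ref = "A", alt = "G"))
}

write_toy_vcf <- function(path, gt = c("0\t1\t0", "1\t1\t0")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    paste0("chrY\t100\t.\tA\tG\t.\t.\t.\tGT\t", gt[1]),
    paste0("chrY\t200\t.\tC\tT\t.\t.\t.\tGT\t", gt[2])), path)
  path
}

toy_str_table <- function() {
  m <- matrix(c(14L, 15L, 30L, 12L,
                14L, 16L, 30L, 12L), nrow = 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"),
                              c("DYS19", "DYS390", "DYS389II", "DYS391")))
  str_profile_table(m)
}

# exhaustive two-state small-parsimony oracle: enumerate every assignment of
# 0/1 to the internal nodes (root free) and count edges whose endpoint
# states differ; independent of the Sankoff implementation
brute_parsimony <- function(phy, carrier_tips) {
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  tip_state <- integer(nt)
  tip_state[carrier_tips] <- 1L
  best <- Inf
  for (mask in 0:(2^nn - 1)) {
    int_state <- as.integer(intToBits(mask)[seq_len(nn)])
    st <- c(tip_state, int_state)
    changes <- sum(st[phy$edge[, 1]] != st[phy$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# structural equality of two mutation trees: same tips, same clades with the
# same branch mutation counts (label-invariant)
expect_tree_equal <- function(t1, t2) {
  sig <- function(tr) {
    bs <- branch_stats(tr)
    cl <- vapply(bs$branch, function(b)
      paste(sort(tr$phy$tip.label[tips_below_pub(tr$phy, b)]), collapse = ","), "")
    paste(sort(paste(cl, bs$l_b)), collapse = ";")
  }
  expect_setequal(t1$phy$tip.label, t2$phy$tip.label)
  expect_identical(sig(t1), sig(t2))
}

# tips below a branch id (test-side helper on the public structures)
tips_below_pub <- function(phy, id) {
  nt <- length(phy$tip.label)
  i <- match(id, phy$tip.label)
  if (!is.na(i)) return(i)
  num <- nt + match(id, phy$node.label)
  po <- ape::reorder.phylo(phy, "postorder")
  below <- logical(nt + phy$Nnode)
  below[num] <- TRUE
  for (k in rev(seq_len(nrow(po$edge))))
    if (below[po$edge[k, 1]]) below[po$edge[k, 2]] <- TRUE
  which(below[seq_len(nt)])
}

# rebuild the haplotype matrix implied by a tree's compatible gain events;
# used for the perfect-phylogeny round-trip property
rebuild_matrix_from_tree <- function(tree, site_order) {
  tips <- sort(tree$phy$tip.label)
  ev <- tree$events
  calls <- matrix(0L, length(tips), length(site_order),
                  dimnames = list(tips, site_order))
  for (i in seq_len(nrow(ev))) {
    if (is.na(ev$branch[i])) { calls[, ev$site_id[i]] <- 1L; next }
    carr <- tree$phy$tip.label[tips_below_pub(tree$phy, ev$branch[i])]
    calls[carr, ev$site_id[i]] <- 1L
  }
  calls
}
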