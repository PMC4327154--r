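#' Simulation configuration for a nonrecombining male genealogy
#'
#' The generator emulates the data-generating process the analyses assume:
#' a haploid genealogy (constant-size coalescent, star of fixed depth, or a
#' user tree), Poisson SNP mutations at `snp_rate` per nucleotide per year
#' over a `target_length` bp target (defaults 1.0e-9 and 3,724,156, i.e. one
#' mutation per 268.5 years), strictly single-step STR mutations at
#' per-locus per-generation rates, optional finite-sites recurrence with a
#' CpG-elevated rate class (default 10x on 2% of sites), tissue-source
#' labels, and optional extra somatic singletons on cell-line (LCL) tips.
#'
#' @param n_tips number of sampled males (>= 2)
#' @param genealogy `"coalescent"`, `"star"` or `"newick"`
#' @param Ne effective number of males (coalescent model), default 5000
#' @param star_depth root-to-tip depth in years (star model)
#' @param newick user tree (Newick string, branch lengths in years)
#' @param snp_rate SNP mutations/nucleotide/year
#' @param target_length callable target, nucleotides
#' @param sites_model `"infinite"` (every mutation hits a fresh site) or
#'   `"finite"` (mutations recur among `n_sites` sites)
#' @param n_sites number of mutable sites in finite-sites mode
#' @param cpg_fraction fraction of sites in the CpG-elevated class
#' @param cpg_multiplier rate multiplier for the CpG class
#' @param str_rates named per-locus STR rates, mutations/STR/generation
#' @param str_root_allele root repeat count (scalar, or named per locus)
#' @param generation_time years per generation
#' @param tissue_probs named probabilities for tissue sources; default is
#'   the 152:208:88 LCL:blood:saliva composition of the reference dataset
#' @param lcl_extra_rate Poisson mean of extra private somatic singletons
#'   per LCL sample (terminal-branch artefacts), default 0
#' @param seed integer seed; mandatory, every stochastic stage derives its
#'   own stream from it
#' @return a validated `sim_config` list
#' @export
sim_config <- function(n_tips = 50,
                       genealogy = c("coalescent", "star", "newick"),
                       Ne = 5000,
                       star_depth = 125826,
                       newick = NULL,
                       snp_rate = 1.0e-9,
                       target_length = 3724156,
                       sites_model = c("infinite", "finite"),
                       n_sites = 1000,
                       cpg_fraction = 0.02,
                       cpg_multiplier = 10,
                       str_rates = setNames(rep(6.9e-4, 21), str_subsets()$set21),
                       str_root_allele = 14,
                       generation_time = 30,
                       tissue_probs = c(LCL = 152, blood = 208, saliva = 88) / 448,
                       lcl_extra_rate = 0,
                       seed = NULL) {
  genealogy <- match.arg(genealogy)
  sites_model <- match.arg(sites_model)
  if (is.null(seed)) ychron_stop("a seed is mandatory for every stochastic run")
  if (n_tips < 2) ychron_stop("need n_tips >= 2")
  if (abs(sum(tissue_probs) - 1) > 1e-8) ychron_stop("tissue probabilities must sum to 1")
  if (any(c(snp_rate, str_rates, lcl_extra_rate, cpg_multiplier) < 0))
    ychron_stop("rates must be nonnegative")
  if (genealogy == "newick" && is.null(newick)) ychron_stop("newick genealogy needs `newick`")
  structure(list(n_tips = as.integer(n_tips), genealogy = genealogy, Ne = Ne,
                 star_depth = star_depth, newick = newick, snp_rate = snp_rate,
                 target_length = target_length, sites_model = sites_model,
                 n_sites = as.integer(n_sites), cpg_fraction = cpg_fraction,
                 cpg_multiplier = cpg_multiplier, str_rates = str_rates,
                 str_root_allele = str_root_allele,
                 generation_time = generation_time, tissue_probs = tissue_probs,
                 lcl_extra_rate = lcl_extra_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# descendant tip numbers for every node, one postorder pass
descendants_list <- function(phy) {
  nt <- length(phy$tip.label)
  out <- vector("list", nt + phy$Nnode)
  for (i in seq_len(nt)) out[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge)))
    out[[po$edge[k, 1]]] <- c(out[[po$edge[k, 1]]], out[[po$edge[k, 2]]])
  out
}

#' Simulate a genealogy skeleton
#'
#' Returns a rooted, time-annotated `mutation_tree` skeleton (no mutations
#' yet; branch lengths in years). Coalescent waiting times while `k`
#' lineages remain are exponential with rate `k(k-1)/(2 Ne)` generations.
#'
#' @param config a `sim_config`
#' @param seed seed for this stage (default: derived from `config$seed`)
#' @return a `mutation_tree` with `node_times` (years before present)
#' @export
sim_genealogy <- function(config, seed = derive_seed(config$seed, 0)) {
  n <- config$n_tips
  tips <- sprintf("S%03d", seq_len(n))
  if (config$genealogy == "star") {
    phy <- structure(list(edge = cbind(rep(n + 1L, n), seq_len(n)),
                          Nnode = 1L, tip.label = tips,
                          edge.length = rep(config$star_depth, n),
                          node.label = "ROOT"),
                     class = "phylo")
    times <- setNames(c(rep(0, n), config$star_depth), c(tips, "ROOT"))
    return(mutation_tree(phy, node_times = times))
  }
  if (config$genealogy == "newick") {
    tr <- read_newick(text = config$newick)
    phy <- tr$phy
    nt <- length(phy$tip.label)
    depth <- numeric(nt + phy$Nnode)
    po <- ape::reorder.phylo(phy, "postorder")
    for (k in rev(seq_len(nrow(po$edge))))
      depth[po$edge[k, 2]] <- depth[po$edge[k, 1]] + po$edge.length[k]
    times <- max(depth) - depth
    names(times) <- c(phy$tip.label, phy$node.label)
    return(mutation_tree(phy, node_times = times))
  }
  set.seed(seed)
  g <- config$generation_time
  active <- seq_len(n)                  # node numbers of active lineages
  t_node <- numeric(2 * n - 1)          # years
  merge_num <- integer(0)
  t <- 0
  next_internal <- 2L * n - 1L          # first merge gets the largest number
  while (length(active) > 1) {
    k <- length(active)
    t <- t + stats::rexp(1, rate = k * (k - 1) / 2 / config$Ne) * g
    pair <- sample(active, 2)
    node <- next_internal
    next_internal <- next_internal - 1L
    t_node[node] <- t
    merge_num <- c(merge_num, node)
    active <- c(setdiff(active, pair), node)
    attr(t_node, paste0("ch", node)) <- pair
  }
  # the final merge must be node n+1 (ape root convention); by construction
  # next_internal ended at n, so the last assigned number is n+1 only when
  # merges were numbered downward from 2n-1 -- which they were
  edges <- matrix(0L, nrow = 0, ncol = 2)
  lens <- numeric(0)
  for (node in merge_num) {
    for (ch in attr(t_node, paste0("ch", node))) {
      edges <- rbind(edges, c(node, ch))
      lens <- c(lens, t_node[node] - t_node[ch])
    }
  }
  nlab <- character(n - 1)
  nlab[1] <- "ROOT"
  if (n > 2) nlab[2:(n - 1)] <- paste0("N", seq_len(n - 2))
  phy <- structure(list(edge = edges, Nnode = n - 1L, tip.label = tips,
                        edge.length = lens, node.label = nlab),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  times <- setNames(t_node[c(seq_len(n), (n + 1):(2 * n - 1))], c(tips, nlab))
  mutation_tree(phy, node_times = times)
}

random_snp_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ri <- sample.int(4, n, replace = TRUE)
  # alt: one of the three other bases, drawn as a cyclic offset
  ai <- (ri + sample.int(3, n, replace = TRUE) - 1L) %% 4L + 1L
  list(ref = bases[ri], alt = bases[ai])
}

#' Simulate SNP haplotypes on a genealogy
#'
#' Per-branch mutation counts are Poisson with mean
#' `snp_rate * target_length * branch_years`. In infinite-sites mode every
#' mutation hits a fresh site; in finite-sites mode mutations land on a
#' fixed panel of `n_sites` sites with the CpG class upweighted by
#' `cpg_multiplier`, so sites can be hit repeatedly (recurrence,
#' back-mutation). The truth log records every event's site, branch and
#' direction.
#'
#' @param tree a time-annotated `mutation_tree` skeleton ([sim_genealogy()])
#' @param config a `sim_config`
#' @param seed stage seed
#' @param return_matrix build the haplotype matrix (set `FALSE` to get only
#'   the event log, e.g. for large star simulations)
#' @return list with `matrix` (a derived-coded `haplotype_matrix`, or `NULL`),
#'   `events` (truth log: `site_id`, `branch`, `direction`), `site_table`
#'   (with `pos` and `cpg` flag), `tip_counts` (true mutations to root per tip)
#' @export
sim_snps <- function(tree, config, seed = derive_seed(config$seed, 1),
                     return_matrix = TRUE) {
  force(tree); force(seed)   # evaluate before seeding: args may use the RNG
  set.seed(seed)
  phy <- tree$phy
  nt <- length(phy$tip.label)
  lens <- phy$edge.length
  branch_ids <- node_id(phy, phy$edge[, 2])
  mu_tot <- config$snp_rate * config$target_length
  n_ev_branch <- stats::rpois(length(lens), mu_tot * lens)
  desc <- descendants_list(phy)

  if (config$sites_model == "infinite") {
    total <- sum(n_ev_branch)
    pos <- sort(sample.int(config$target_length, total))
    al <- random_snp_alleles(total)
    cpg <- stats::runif(total) < config$cpg_fraction
    site_tab <- data.frame(chrom = rep("chrY", total), pos = pos,
                           ref = al$ref, alt = al$alt,
                           cpg = cpg, stringsAsFactors = FALSE)
    ids <- site_ids(site_tab)
    # assign sites to branches in a random order so position is independent
    # of branch
    ev_branch <- rep(branch_ids, n_ev_branch)
    site_of_event <- sample.int(total)
    events <- data.frame(site_id = ids[site_of_event], branch = ev_branch,
                         direction = rep("gain", total), stringsAsFactors = FALSE)
    mat <- NULL
    if (return_matrix) {
      calls <- matrix(0L, nrow = nt, ncol = total,
                      dimnames = list(phy$tip.label, ids))
      child <- phy$edge[, 2]
      ends <- cumsum(n_ev_branch)
      starts <- ends - n_ev_branch + 1L
      for (k in seq_along(n_ev_branch)) {
        if (n_ev_branch[k] == 0) next
        cols <- site_of_event[starts[k]:ends[k]]
        calls[desc[[child[k]]], cols] <- 1L
      }
      mat <- haplotype_matrix(calls, site_tab[, c("chrom", "pos", "ref", "alt")],
                              ancestral_known = rep(TRUE, total))
    }
    tipc <- tip_path_event_counts(phy, branch_ids, n_ev_branch)
    return(list(matrix = mat, events = events, site_table = site_tab,
                tip_counts = tipc))
  }

  # finite sites
  ns <- config$n_sites
  pos <- sort(sample.int(config$target_length, ns))
  al <- random_snp_alleles(ns)
  cpg <- stats::runif(ns) < config$cpg_fraction
  w <- ifelse(cpg, config$cpg_multiplier, 1)
  site_tab <- data.frame(chrom = "chrY", pos = pos, ref = al$ref, alt = al$alt,
                         cpg = cpg, stringsAsFactors = FALSE)
  ids <- site_ids(site_tab)
  nn <- nt + phy$Nnode
  state <- matrix(0L, nrow = nn, ncol = ns)     # state at each node
  po <- ape::reorder.phylo(phy, "postorder")
  ev_site <- integer(0); ev_branch <- character(0); ev_dir <- character(0)
  ord <- rev(seq_len(nrow(po$edge)))            # preorder
  for (k in ord) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    s <- state[p, ]
    kk <- stats::rpois(1, mu_tot * po$edge.length[k])
    if (kk > 0) {
      hit <- sample.int(ns, kk, replace = TRUE, prob = w)
      for (h in hit) {
        ev_site <- c(ev_site, h)
        ev_branch <- c(ev_branch, node_id(phy, ch))
        ev_dir <- c(ev_dir, if (s[h] == 0L) "gain" else "loss")
        s[h] <- 1L - s[h]
      }
    }
    state[ch, ] <- s
  }
  events <- data.frame(site_id = ids[ev_site], branch = ev_branch,
                       direction = ev_dir, stringsAsFactors = FALSE)
  seg <- colSums(state[seq_len(nt), , drop = FALSE]) > 0
  mat <- NULL
  if (return_matrix) {
    calls <- state[seq_len(nt), seg, drop = FALSE]
    dimnames(calls) <- list(phy$tip.label, ids[seg])
    mat <- haplotype_matrix(calls, site_tab[seg, c("chrom", "pos", "ref", "alt")],
                            ancestral_known = rep(TRUE, sum(seg)))
  }
  tb <- table(events$branch)
  tipc_all <- tip_path_event_counts(phy, names(tb), as.integer(tb))
  list(matrix = mat, events = events, site_table = site_tab,
       tip_counts = tipc_all)
}

# per-tip number of events on the root path, from per-branch event counts
tip_path_event_counts <- function(phy, branches, counts) {
  nt <- length(phy$tip.label)
  l_of <- setNames(numeric(nt + phy$Nnode), node_id(phy, seq_len(nt + phy$Nnode)))
  l_of[branches] <- counts
  depth <- numeric(nt + phy$Nnode)
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in rev(seq_len(nrow(po$edge)))) {
    ch <- po$edge[k, 2]
    depth[ch] <- depth[po$edge[k, 1]] + l_of[[node_id(phy, ch)]]
  }
  setNames(as.integer(depth[seq_len(nt)]), phy$tip.label)
}

#' Simulate STR profiles on a genealogy
#'
#' Strict symmetric single-step mutation: per branch and locus the number of
#' steps is Poisson with mean `rate * branch_years / generation_time`, each
#' step +1 or -1 with equal probability.
#'
#' @param tree a time-annotated `mutation_tree` skeleton
#' @param config a `sim_config`
#' @param seed stage seed
#' @return list with `profiles` (an `str_profile_table`) and `root` (the
#'   true ancestral `root_haplotype`)
#' @export
sim_strs <- function(tree, config, seed = derive_seed(config$seed, 2)) {
  force(tree); force(seed)
  set.seed(seed)
  phy <- tree$phy
  nt <- length(phy$tip.label)
  loci <- names(config$str_rates)
  nl <- length(loci)
  root_al <- if (length(config$str_root_allele) == 1)
    setNames(rep(as.integer(config$str_root_allele), nl), loci)
  else {
    stopifnot(all(loci %in% names(config$str_root_allele)))
    config$str_root_allele[loci]
  }
  nn <- nt + phy$Nnode
  alle <- matrix(rep(root_al, each = nn), nrow = nn, dimnames = list(NULL, loci))
  po <- ape::reorder.phylo(phy, "postorder")
  gy <- config$generation_time
  for (k in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    gens <- po$edge.length[k] / gy
    steps <- stats::rpois(nl, config$str_rates * gens)
    net <- 2L * stats::rbinom(nl, steps, 0.5) - steps
    alle[ch, ] <- alle[p, ] + net
  }
  prof <- alle[seq_len(nt), , drop = FALSE]
  if (any(prof < 0)) {
    warning("clamping negative simulated repeat counts at 0")
    prof[prof < 0] <- 0L
  }
  rownames(prof) <- phy$tip.label
  list(profiles = str_profile_table(prof),
       root = root_haplotype(root_al, "ancestral"))
}

#' Simulate sample metadata, with optional LCL somatic singletons
#'
#' Tissue-source labels are drawn from the configured probabilities. When
#' `lcl_extra_rate > 0` and a haplotype matrix is supplied, each LCL sample
#' receives a Poisson number of extra private singleton variants (somatic,
#' cell-line-culture artefacts); these are appended to the matrix and to the
#' returned extra-event log, always on terminal branches.
#'
#' @param tree a `mutation_tree` skeleton (tip set)
#' @param config a `sim_config`
#' @param matrix optional `haplotype_matrix` to augment
#' @param seed stage seed
#' @return list with `meta` (a `sample_meta`), `matrix` (augmented or the
#'   input), `extra_events` (site_id, branch, direction)
#' @export
sim_metadata <- function(tree, config, matrix = NULL,
                         seed = derive_seed(config$seed, 3)) {
  force(tree); force(matrix); force(seed)
  set.seed(seed)
  tips <- tree$phy$tip.label
  tissue <- sample(names(config$tissue_probs), length(tips), replace = TRUE,
                   prob = config$tissue_probs)
  meta <- sample_meta(data.frame(sample_id = tips, population = "SIM",
                                 region = "SIM", tissue_source = tissue,
                                 haplogroup = NA_character_,
                                 stringsAsFactors = FALSE))
  extra <- data.frame(site_id = character(), branch = character(),
                      direction = character(), stringsAsFactors = FALSE)
  if (config$lcl_extra_rate > 0) {
    lcl <- tips[tissue == "LCL"]
    n_extra <- stats::rpois(length(lcl), config$lcl_extra_rate)
    total <- sum(n_extra)
    if (total > 0) {
      taken <- if (is.null(matrix)) integer(0) else matrix$sites$pos
      pool <- setdiff(sample.int(config$target_length, total + length(taken)), taken)
      pos <- sort(pool[seq_len(total)])
      al <- random_snp_alleles(total)
      new_sites <- data.frame(chrom = "chrY", pos = pos, ref = al$ref,
                              alt = al$alt, stringsAsFactors = FALSE)
      ids <- site_ids(new_sites)
      owner <- sample(rep(lcl, n_extra))        # random position-to-sample map
      if (!is.null(matrix)) {
        calls <- matrix(0L, nrow = nrow(matrix$calls), ncol = total,
                        dimnames = list(rownames(matrix$calls), ids))
        calls[cbind(match(owner, rownames(calls)), seq_len(total))] <- 1L
        all_calls <- cbind(matrix$calls, calls)
        all_sites <- rbind(matrix$sites[, c("chrom", "pos", "ref", "alt")], new_sites)
        o <- order(all_sites$pos)
        matrix <- haplotype_matrix(all_calls[, o, drop = FALSE],
                                   all_sites[o, , drop = FALSE],
                                   ancestral_known = rep(TRUE, nrow(all_sites)))
      }
      extra <- data.frame(site_id = ids, branch = owner, direction = "gain",
                          stringsAsFactors = FALSE)
    }
  }
  list(meta = meta, matrix = matrix, extra_events = extra)
}

#' Simulate a complete dataset
#'
#' Runs genealogy, SNP, STR and metadata stages with per-stage seeds derived
#' from `config$seed`; the whole result is a pure function of the config.
#'
#' @param config a `sim_config`
#' @return list with `tree` (truth `mutation_tree`: skeleton plus the true
#'   event log), `matrix`, `site_table`, `str` (profiles + ancestral root),
#'   `meta`, `events` (SNP truth log incl. LCL extras), `tip_counts`
#' @export
simulate_dataset <- function(config) {
  skel <- sim_genealogy(config)
  snps <- sim_snps(skel, config)
  strs <- sim_strs(skel, config)
  md <- sim_metadata(skel, config, matrix = snps$matrix)
  events <- rbind(cbind(snps$events, compatible = NA),
                  if (nrow(md$extra_events)) cbind(md$extra_events, compatible = NA))
  tipc <- snps$tip_counts
  if (nrow(md$extra_events)) {
    add <- table(md$extra_events$branch)
    tipc[names(add)] <- tipc[names(add)] + as.integer(add)
  }
  truth_tree <- mutation_tree(skel$phy, events, node_times = skel$node_times)
  list(tree = truth_tree, matrix = md$matrix %||% snps$matrix,
       site_table = snps$site_table, str = strs, meta = md$meta,
       events = events, tip_counts = tipc, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits `<prefix>.vcf` (haploid calls), `<prefix>_strs.tsv`,
#' `<prefix>_meta.tsv`, `<prefix>_truth.nwk` (time tree, years) and
#' `<prefix>_events.tsv` (truth event log).
#'
#' @param sim result of [simulate_dataset()]
#' @param prefix output path prefix
#' @return named character vector of the files written
#' @export
write_simulation <- function(sim, prefix) {
  paths <- c(vcf = paste0(prefix, ".vcf"), str = paste0(prefix, "_strs.tsv"),
             meta = paste0(prefix, "_meta.tsv"),
             newick = paste0(prefix, "_truth.nwk"),
             events = paste0(prefix, "_events.tsv"))
  write_haploid_vcf(sim$matrix, paths["vcf"])
  write_str_table(sim$str$profiles, paths["str"])
  write_sample_meta(sim$meta, paths["meta"])
  skel <- mutation_tree(sim$tree$phy, node_times = sim$tree$node_times)
  write_newick(skel, paths["newick"])
  ev <- sim$events
  ev$branch[is.na(ev$branch)] <- ""
  utils::write.table(ev, paths["events"], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
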