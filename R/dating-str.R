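#' Root haplotype for STR dating
#'
#' @param alleles named integer vector, locus -> repeat count
#' @param provenance `"ancestral"` (true/assumed founder state) or
#'   `"modal"` (per-locus mode of the clade members)
#' @return an object of class `root_haplotype`
#' @export
root_haplotype <- function(alleles, provenance = c("ancestral", "modal")) {
  provenance <- match.arg(provenance)
  if (is.null(names(alleles))) ychron_stop("root haplotype needs locus names")
  if (any(is.na(alleles)) || any(alleles != floor(alleles)))
    ychron_stop("root haplotype alleles must be integers")
  structure(list(alleles = alleles, provenance = provenance),
            class = "root_haplotype")
}

#' Modal haplotype of a sample set
#'
#' Per-locus most frequent repeat count among the members; ties are broken
#' deterministically toward the smallest allele.
#'
#' @param profiles an `str_profile_table`
#' @param members character vector of sample ids
#' @param subset marker subset name or locus vector
#' @return a `root_haplotype` with provenance `"modal"`
#' @export
modal_haplotype <- function(profiles, members, subset = "set21") {
  stopifnot(inherits(profiles, "str_profile_table"))
  if (length(members) == 0) ychron_stop("empty member set")
  loci <- str_subset_loci(profiles, subset)
  miss <- setdiff(members, rownames(profiles$counts))
  if (length(miss)) ychron_stop(sprintf("unknown sample: %s", miss[1]))
  m <- profiles$counts[members, loci, drop = FALSE]
  alleles <- vapply(loci, function(lc) {
    v <- m[, lc]
    v <- v[!is.na(v)]
    if (length(v) == 0) ychron_stop(sprintf("all members missing at locus %s", lc))
    tab <- table(v)
    as.integer(names(tab)[tab == max(tab)][1])   # names sorted ascending -> smallest
  }, 1L)
  root_haplotype(alleles, "modal")
}

check_str_args <- function(profiles, members, root, loci) {
  miss <- setdiff(members, rownames(profiles$counts))
  if (length(miss)) ychron_stop(sprintf("unknown sample: %s", miss[1]))
  if (!all(loci %in% names(root$alleles)))
    ychron_stop("root haplotype does not cover every subset locus")
}

#' Average squared distance (ASD) to a root haplotype
#'
#' `ASD = (1/(n m)) * sum_samples sum_loci (allele - root_allele)^2` over `n`
#' members and `m` subset loci. Under an unbounded symmetric stepwise
#' mutation model its expectation is (rate x time) per locus for any depth,
#' which is what makes it the preferred STR dating statistic at saturation.
#'
#' @param profiles an `str_profile_table`
#' @param members character vector of sample ids
#' @param root a `root_haplotype`
#' @param subset marker subset name or locus vector
#' @return scalar ASD (per-locus mean)
#' @export
asd <- function(profiles, members, root, subset = "set21") {
  stopifnot(inherits(profiles, "str_profile_table"), inherits(root, "root_haplotype"))
  loci <- str_subset_loci(profiles, subset)
  check_str_args(profiles, members, root, loci)
  m <- profiles$counts[members, loci, drop = FALSE]
  d <- sweep(m, 2, root$alleles[loci])
  mean(d^2, na.rm = TRUE)
}

#' STR rho: mean absolute step distance to a root haplotype
#'
#' `rho_str = (1/(n m)) * sum_samples sum_loci |allele - root_allele|`. This
#' is the star-genealogy reduction of network-based rho counting: the net
#' repeat displacement lower-bounds the number of mutation events, so at
#' depths where back-mutation matters rho_str undercounts relative to ASD.
#'
#' @inheritParams asd
#' @return scalar per-locus mean absolute distance
#' @export
rho_str <- function(profiles, members, root, subset = "set21") {
  stopifnot(inherits(profiles, "str_profile_table"), inherits(root, "root_haplotype"))
  loci <- str_subset_loci(profiles, subset)
  check_str_args(profiles, members, root, loci)
  m <- profiles$counts[members, loci, drop = FALSE]
  d <- sweep(m, 2, root$alleles[loci])
  mean(abs(d), na.rm = TRUE)
}

#' Mean per-locus STR mutation rate for a subset under a rate regime
#' @param rates a `rate_model`
#' @param subset subset name or locus vector
#' @param regime `"evolutionary"` or `"pedigree"`
#' @return scalar mean rate, mutations/STR/generation
#' @export
str_mean_rate <- function(rates, subset, regime = c("evolutionary", "pedigree")) {
  regime <- match.arg(regime)
  tab <- rates$str_rates[[regime]]
  if (is.null(tab)) ychron_stop(sprintf("no %s STR rates in rate model", regime))
  loci <- if (is.character(subset) && length(subset) == 1 && subset %in% names(str_subsets()))
    str_subsets()[[subset]] else as.character(subset)
  if (length(tab) == 1 && is.null(names(tab))) return(unname(tab))
  miss <- setdiff(loci, names(tab))
  if (length(miss))
    ychron_stop(sprintf("missing %s rate for locus %s", regime, miss[1]))
  mean(tab[loci])
}

#' STR-based TMRCA from a dating statistic
#'
#' `TMRCA_generations = statistic / mean_rate(subset, regime)`; years are
#' generations times the model generation time.
#'
#' @param statistic ASD or rho_str value (per-locus mean)
#' @param method `"asd"` or `"rho"`
#' @param subset marker subset the statistic was computed on
#' @param regime `"evolutionary"` or `"pedigree"`
#' @param rates a `rate_model`
#' @param clade,root_provenance annotation columns for the output row
#' @return one-row data.frame of class `str_estimate`
#' @export
tmrca_str <- function(statistic, method = c("asd", "rho"), subset = "set21",
                      regime = c("evolutionary", "pedigree"),
                      rates = rate_model(), clade = NA_character_,
                      root_provenance = NA_character_) {
  method <- match.arg(method); regime <- match.arg(regime)
  if (statistic < 0) ychron_stop("statistic must be nonnegative")
  rate <- str_mean_rate(rates, subset, regime)
  gen <- statistic / rate
  out <- data.frame(clade = clade, method = method,
                    root = root_provenance,
                    subset = if (is.character(subset) && length(subset) == 1) subset else "custom",
                    regime = regime, statistic = statistic,
                    tmrca_generations = gen,
                    tmrca_years = gen * rates$generation_time,
                    stringsAsFactors = FALSE)
  class(out) <- c("str_estimate", "data.frame")
  out
}

#' Date clades from STR profiles across methods, subsets and regimes
#'
#' For each clade (a named list of member vectors) computes the dating
#' statistic and TMRCA for every requested combination of method
#' (asd / rho), subset and rate regime, under a modal root (computed per
#' clade) or supplied ancestral roots.
#'
#' @param profiles an `str_profile_table`
#' @param clades named list: clade id -> character vector of member ids
#' @param rates a `rate_model`
#' @param methods,subsets,regimes combinations to evaluate
#' @param roots `"modal"`, or a named list of `root_haplotype`s (one per
#'   clade) used as ancestral roots
#' @return `str_estimate` data.frame
#' @export
date_str_clades <- function(profiles, clades, rates = rate_model(),
                            methods = c("asd", "rho"),
                            subsets = c("set21", "set17", "set13"),
                            regimes = c("evolutionary", "pedigree"),
                            roots = "modal") {
  rows <- list()
  for (cl in names(clades)) {
    members <- clades[[cl]]
    for (ss in subsets) {
      root <- if (identical(roots, "modal")) modal_haplotype(profiles, members, ss)
              else roots[[cl]]
      for (me in methods) {
        stat <- if (me == "asd") asd(profiles, members, root, ss)
                else rho_str(profiles, members, root, ss)
        for (rg in regimes)
          rows[[length(rows) + 1L]] <-
            tmrca_str(stat, me, ss, rg, rates, clade = cl,
                      root_provenance = root$provenance)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare STR-based against SNP-based TMRCA estimates
#'
#' Joins the two estimate tables on clade id and, for every
#' (method, root, subset, regime) cell, reports the Pearson correlation of
#' STR vs SNP point estimates, the mean signed relative error
#' `mean((str - snp)/snp)` and an over/under flag. Cells with fewer than 3
#' shared clades have undefined correlation (`NA`).
#'
#' @param snp a `clade_estimate` data.frame ([date_clades()])
#' @param str an `str_estimate` data.frame ([date_str_clades()])
#' @return data.frame, one row per cell, plus the merged per-clade table as
#'   attribute `"pairs"`
#' @export
compare_estimates <- function(snp, str) {
  merged <- merge(str, snp[, c("clade", "tmrca_years")], by = "clade",
                  suffixes = c("_str", "_snp"))
  cells <- unique(merged[, c("method", "root", "subset", "regime")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- merged$method == cells$method[i] & merged$root == cells$root[i] &
           merged$subset == cells$subset[i] & merged$regime == cells$regime[i]
    a <- merged$tmrca_years_str[sel]; b <- merged$tmrca_years_snp[sel]
    ok <- is.finite(a) & is.finite(b)
    r <- if (sum(ok) >= 3 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0)
      stats::cor(a[ok], b[ok]) else NA_real_
    rel <- mean((a[ok] - b[ok]) / b[ok])
    data.frame(cells[i, , drop = FALSE], n_clades = sum(ok), pearson_r = r,
               mean_rel_error = rel,
               bias = if (is.nan(rel)) NA_character_ else
                      if (rel > 0) "over" else if (rel < 0) "under" else "none",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "pairs") <- merged
  out
}
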