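#' Mutation-rate model for SNP and STR dating
#'
#' Carries the constants every TMRCA estimate depends on. The defaults are
#' the values used throughout this package's reference analysis: a
#' pedigree-derived SNP rate of 1.0e-9 mutations/nucleotide/year with 95% CI
#' 3.0e-10 to 2.5e-9, a 3,724,156 bp callable target (giving one mutation
#' per 268.5 years), a 30-year generation time, an "evolutionary" STR rate
#' of 6.9e-4 mutations/STR/generation, and per-locus "pedigree" STR rates
#' whose subset means fall in the 2.797e-3 to 4.238e-3 bracket. The shipped
#' pedigree per-locus values are placeholders with realistic relative
#' magnitudes, not measured rates; supply your own for real data.
#'
#' @param snp_rate point SNP mutation rate, mutations/nucleotide/year
#' @param snp_rate_ci length-2 numeric, lower and upper CI bound of the rate
#' @param target_length callable target length in nucleotides
#' @param generation_time years per generation (STR dating only)
#' @param str_rates named list with elements `evolutionary` (single
#'   per-locus-mean rate per generation) and `pedigree` (named per-locus
#'   rates per generation)
#' @return an object of class `rate_model`
#' @export
rate_model <- function(snp_rate = 1.0e-9,
                       snp_rate_ci = c(3.0e-10, 2.5e-9),
                       target_length = 3724156,
                       generation_time = 30,
                       str_rates = default_str_rates()) {
  if (!(snp_rate > 0) || target_length <= 0 || generation_time <= 0)
    ychron_stop("rates, target length and generation time must be positive")
  if (length(snp_rate_ci) != 2 || !(snp_rate_ci[1] > 0) ||
      snp_rate_ci[1] > snp_rate || snp_rate > snp_rate_ci[2])
    ychron_stop("need 0 < ci_lo <= rate <= ci_hi")
  structure(list(snp_rate = snp_rate, snp_rate_ci = snp_rate_ci,
                 target_length = target_length,
                 generation_time = generation_time,
                 str_rates = str_rates),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> SNP %.3g/nt/y (CI %.3g-%.3g), L=%d nt -> %.1f y/mutation; g=%g y\n",
              x$snp_rate, x$snp_rate_ci[1], x$snp_rate_ci[2], x$target_length,
              years_per_mutation(x), x$generation_time))
  invisible(x)
}

#' Years represented by one SNP mutation under a rate model
#' @param rates a `rate_model`
#' @return scalar, `1 / (snp_rate * target_length)`
#' @export
years_per_mutation <- function(rates) 1 / (rates$snp_rate * rates$target_length)

#' Default STR mutation-rate tables
#'
#' `evolutionary`: the population-calibrated mean rate 6.9e-4
#' mutations/STR/generation applied to every locus. `pedigree`: per-locus
#' placeholder rates (father-son regime); their subset means are
#' set21 = 3.910e-3, set17 = 2.965e-3, set13 = 2.808e-3 per generation.
#'
#' @return named list with elements `evolutionary` and `pedigree`
#' @export
default_str_rates <- function() {
  pedigree <- c(DYS19 = 2.2e-3, DYS389I = 2.5e-3, DYS389II = 3.6e-3,
                DYS390 = 2.1e-3, DYS391 = 2.6e-3, DYS392 = 0.5e-3,
                DYS393 = 1.1e-3, DYS437 = 1.3e-3, DYS438 = 0.4e-3,
                DYS439 = 5.5e-3, DYS448 = 1.4e-3, DYS456 = 4.7e-3,
                DYS458 = 6.9e-3, DYS635 = 3.8e-3, GATAH4 = 2.9e-3,
                DYS481 = 5.0e-3, DYS533 = 3.9e-3, DYS549 = 4.0e-3,
                DYS570 = 12.4e-3, DYS576 = 14.3e-3, DYS643 = 1.0e-3)
  list(evolutionary = 6.9e-4, pedigree = pedigree)
}

#' rho statistic and its standard deviation for a clade
#'
#' For the clade below a node, over all branches `b` inside the clade with
#' mutation count `l_b` and descendant-tip count `n_b`, and `n` tips in the
#' clade:
#' \deqn{\rho = \sum_b l_b n_b / n, \qquad
#'       \sigma = \sqrt{\sum_b l_b (n_b/n)^2}}
#' rho equals the mean number of mutations from the clade's tips to its root
#' node (the branch-sum and tip-path-mean forms are algebraically identical).
#'
#' @param tree a `mutation_tree`
#' @param clade node id (`"ROOT"` for the whole tree, a node label, or a tip
#'   id for the degenerate single-tip clade)
#' @return list with `rho`, `sigma`, `n` (tips in the clade)
#' @export
rho_sigma <- function(tree, clade = "ROOT") {
  stopifnot(inherits(tree, "mutation_tree"))
  phy <- tree$phy
  num <- node_number(phy, clade)
  tips <- tips_below(phy, num)
  n <- length(tips)
  if (num <= length(phy$tip.label))
    return(list(rho = 0, sigma = 0, n = 1L))
  bs <- branch_stats(tree)
  # branches inside the clade = edges whose child's tip set is within the clade
  below <- logical(length(phy$tip.label) + phy$Nnode)
  below[num] <- TRUE
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in rev(seq_len(nrow(po$edge))))
    if (below[po$edge[k, 1]]) below[po$edge[k, 2]] <- TRUE
  inside <- below[vapply(bs$branch, function(b) node_number(phy, b), 1L)] &
            bs$branch != clade
  l <- bs$l_b[inside]; nb <- bs$n_b[inside]
  list(rho = sum(l * nb) / n,
       sigma = sqrt(sum(l * (nb / n)^2)),
       n = n)
}

#' SNP-based TMRCA for a clade from rho
#'
#' Point estimate `rho / (mu * L)` years; the mutation-rate CI is propagated
#' by pure inverse-rate scaling, giving the range
#' `rho / (mu_hi * L)` ... `rho / (mu_lo * L)`. The `ka` columns are rounded
#' half-up to 0.1 ka, the convention used for printed dating tables.
#'
#' @param rho rho statistic (>= 0)
#' @param sigma Saillard standard deviation of rho (optional, `NA` to omit)
#' @param rates a `rate_model`
#' @param clade clade id string for the output row
#' @param n number of tips (for the output row)
#' @return one-row data.frame of class `clade_estimate`: `clade`, `n`,
#'   `rho`, `sigma`, `tmrca_years`, `tmrca_ka`, `range_lo_ka`, `range_hi_ka`,
#'   `method`
#' @export
tmrca_snp <- function(rho, sigma = NA_real_, rates = rate_model(),
                      clade = NA_character_, n = NA_integer_) {
  if (rho < 0) ychron_stop("rho must be nonnegative")
  ypm <- years_per_mutation(rates)
  yrs <- rho * ypm
  lo <- rho / (rates$snp_rate_ci[2] * rates$target_length)
  hi <- rho / (rates$snp_rate_ci[1] * rates$target_length)
  out <- data.frame(clade = clade, n = n, rho = rho, sigma = sigma,
                    tmrca_years = yrs,
                    tmrca_ka = round_half_up(yrs / 1000, 1),
                    range_lo_ka = round_half_up(lo / 1000, 1),
                    range_hi_ka = round_half_up(hi / 1000, 1),
                    method = "rho_snp", stringsAsFactors = FALSE)
  class(out) <- c("clade_estimate", "data.frame")
  out
}

#' Rescale a TMRCA point estimate to a different mutation rate
#'
#' TMRCA is inverse-linear in the rate, so an estimate made at `from_rate`
#' becomes `point_ka * from_rate / to_rate` at `to_rate`. This is how a
#' printed point estimate maps onto its mutation-rate-CI range bounds.
#'
#' @param point_ka point estimate in ka (any unit works; scaling is linear)
#' @param from_rate rate the estimate was made at
#' @param to_rate target rate
#' @return rescaled estimate, same units as `point_ka`
#' @export
rescale_estimate <- function(point_ka, from_rate, to_rate) {
  if (!(from_rate > 0) || !(to_rate > 0)) ychron_stop("rates must be positive")
  point_ka * from_rate / to_rate
}

#' Date a set of clades of a tree (SNP rho dating)
#'
#' @param tree a `mutation_tree`
#' @param clades character vector of node ids (default: root plus every
#'   internal node with at least `min_n` tips)
#' @param rates a `rate_model`
#' @param min_n minimum clade size for the default clade list
#' @return `clade_estimate` data.frame, one row per clade
#' @export
date_clades <- function(tree, clades = NULL, rates = rate_model(), min_n = 5) {
  if (is.null(clades)) {
    cnt <- tip_counts(tree$phy)
    nt <- length(tree$phy$tip.label)
    ok <- which(cnt[(nt + 1):(nt + tree$phy$Nnode)] >= min_n)
    clades <- tree$phy$node.label[ok]
  }
  rows <- lapply(clades, function(cl) {
    rs <- rho_sigma(tree, cl)
    tmrca_snp(rs$rho, rs$sigma, rates, clade = cl, n = rs$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
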