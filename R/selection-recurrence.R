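#' Chi-square test with Yates continuity correction on a 2x2 table
#'
#' `chi2 = sum (max(|O - E| - 0.5, 0))^2 / E`, compared against the 1-df
#' chi-square upper tail. All marginals must be positive.
#'
#' @param table 2x2 matrix of nonnegative integer counts
#' @return list with `chi2`, `p_value`, `df = 1`
#' @export
yates_chi2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) ychron_stop("need a 2x2 table")
  if (any(table < 0) || any(table != floor(table)))
    ychron_stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    ychron_stop("zero marginal in 2x2 table")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  chi2 <- sum(pmax(abs(table - E) - 0.5, 0)^2 / E)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE), df = 1)
}

#' Validate an annotated-variant table
#'
#' Schema: `site_id`, optional `gene`, `consequence` (synonymous /
#' nonsynonymous / noncoding), one logical `damaging_*` column per external
#' predictor, `derived_count` (in-dataset derived-allele count). The
#' `singleton` flag is derived (`derived_count == 1`). Damaging flags on
#' non-nonsynonymous variants are an error: damaging-ness is consumed as
#' input for nonsynonymous sites only, never computed here.
#'
#' @param df data.frame in the schema above
#' @return the validated data.frame with a `singleton` column
#' @export
annotated_variants <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("site_id", "consequence", "derived_count")
  if (!all(need %in% names(df)))
    ychron_stop("annotation needs columns site_id, consequence, derived_count")
  ok <- df$consequence %in% c("synonymous", "nonsynonymous", "noncoding")
  if (!all(ok)) ychron_stop(sprintf("bad consequence '%s'", df$consequence[!ok][1]))
  if (any(df$derived_count < 1)) ychron_stop("derived_count must be >= 1")
  df$singleton <- df$derived_count == 1L
  for (cl in grep("^damaging_", names(df), value = TRUE)) {
    df[[cl]] <- as.logical(df[[cl]])
    if (any(df[[cl]] & df$consequence != "nonsynonymous", na.rm = TRUE))
      ychron_stop(sprintf("%s flag set on a non-nonsynonymous variant", cl))
  }
  df
}

#' Singleton enrichment among damaging variants
#'
#' Tests whether the proportion of singletons among variants flagged
#' damaging by a predictor exceeds the singleton proportion in the dataset
#' as a whole. The 2x2 table is (damaging vs remainder of the background) x
#' (singleton vs not): the damaging counts are subtracted from the
#' background marginals so the rows partition the dataset. An excess of
#' damaging singletons is the frequency-spectrum signature of ongoing
#' purifying selection.
#'
#' @param variants an [annotated_variants()] data.frame
#' @param predictor name of the damaging flag column (e.g.
#'   `"damaging_sift"`)
#' @param background length-2 integer: total singletons and total variants
#'   in the dataset the annotated variants are drawn from
#' @param method `"yates"` (default) or `"fisher"`
#' @return list with the 2x2 `table`, `chi2` (NA for fisher), `p_value`,
#'   `direction` (`"enriched"`/`"depleted"`), `n_damaging`,
#'   `n_damaging_singletons`
#' @export
singleton_enrichment <- function(variants, predictor, background,
                                 method = c("yates", "fisher")) {
  method <- match.arg(method)
  if (!(predictor %in% names(variants)))
    ychron_stop(sprintf("no column '%s' in annotation", predictor))
  if (length(background) != 2 || background[1] > background[2])
    ychron_stop("background must be (singletons, total) with singletons <= total")
  dmg <- variants[[predictor]] %in% TRUE
  nd <- sum(dmg)
  if (nd == 0) ychron_stop("no damaging variant for this predictor")
  ns <- sum(variants$singleton[dmg])
  tab <- matrix(c(ns, nd - ns,
                  background[1] - ns, (background[2] - background[1]) - (nd - ns)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("damaging", "rest"), c("singleton", "non_singleton")))
  if (any(tab < 0)) ychron_stop("background inconsistent with damaging counts")
  res <- if (method == "yates") yates_chi2(tab)
         else list(chi2 = NA_real_, p_value = stats::fisher.test(tab)$p.value)
  prop_d <- ns / nd
  prop_bg <- background[1] / background[2]
  list(table = tab, chi2 = res$chi2, p_value = res$p_value,
       direction = if (prop_d >= prop_bg) "enriched" else "depleted",
       n_damaging = nd, n_damaging_singletons = ns)
}

#' Is a site in CpG context?
#'
#' A site is a CpG dinucleotide if, in its reference trinucleotide context
#' (base before, site base, base after), the site base forms a CG pair on
#' either strand: context `.CG` (C at the site followed by G) or `CG.`
#' (G at the site preceded by C).
#'
#' @param context character vector of trinucleotide contexts (site base in
#'   the middle), reference strand
#' @return logical vector
#' @export
is_cpg_context <- function(context) {
  context <- toupper(context)
  bad <- !grepl("^[ACGTN]{3}$", context)
  if (any(bad)) ychron_stop(sprintf("bad trinucleotide context '%s'", context[bad][1]))
  substr(context, 2, 3) == "CG" | substr(context, 1, 2) == "CG"
}

#' Recurrence summary of a tree's site-compatibility report
#'
#' Counts recurrent sites (needing more than one mutational event), total
#' events at those sites, and the fraction of those events at CpG
#' dinucleotides when context is supplied.
#'
#' @param report a site report (`tree$site_report` from [build_tree()]):
#'   columns `site_id`, `compatible`, `n_events`
#' @param cpg optional: logical vector named by site id, or a character
#'   vector of reference trinucleotide contexts named by site id
#' @return list with `n_sites`, `n_recurrent`, `recurrent_fraction`,
#'   `total_recurrent_events`, and (with context) `cpg_events`,
#'   `cpg_fraction`
#' @export
recurrence_summary <- function(report, cpg = NULL) {
  used <- report[!is.na(report$compatible), , drop = FALSE]
  rec <- used[!used$compatible, , drop = FALSE]
  out <- list(n_sites = nrow(used), n_recurrent = nrow(rec),
              recurrent_fraction = if (nrow(used)) nrow(rec) / nrow(used) else 0,
              total_recurrent_events = sum(rec$n_events))
  if (!is.null(cpg)) {
    if (is.character(cpg)) cpg <- setNames(is_cpg_context(cpg), names(cpg))
    flag <- cpg[rec$site_id]
    if (anyNA(flag)) ychron_stop("CpG context missing for a recurrent site")
    out$cpg_events <- sum(rec$n_events[flag])
    out$cpg_fraction <- if (out$total_recurrent_events > 0)
      out$cpg_events / out$total_recurrent_events else 0
  }
  out
}

#' Compare recurrence rates between two variant sets
#'
#' 2x2 (recurrent vs non-recurrent) x (study) chi-square. The Yates
#' continuity correction is applied by default; `correct = FALSE` gives the
#' plain Pearson chi-square.
#'
#' @param a,b length-2 integer vectors `(recurrent, total)`
#' @param correct apply the Yates continuity correction
#' @return list with the `table`, `chi2`, `p_value`
#' @export
compare_recurrence_rates <- function(a, b, correct = TRUE) {
  if (length(a) != 2 || length(b) != 2 || a[1] > a[2] || b[1] > b[2] ||
      a[2] <= 0 || b[2] <= 0)
    ychron_stop("a and b must be (recurrent, total) with recurrent <= total")
  tab <- matrix(c(a[1], a[2] - a[1], b[1], b[2] - b[1]), nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("recurrent", "non_recurrent")))
  if (correct) {
    res <- yates_chi2(tab)
  } else {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi2 <- sum((tab - E)^2 / E)
    res <- list(chi2 = chi2, p_value = stats::pchisq(chi2, 1, lower.tail = FALSE))
  }
  c(list(table = tab), res[c("chi2", "p_value")])
}
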