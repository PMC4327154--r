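#' Run the full analysis pipeline from a config
#'
#' Orchestrates: input (load files, or simulate), tree building, SNP dating,
#' STR dating and comparison, branch-length heterogeneity testing, and
#' selection/recurrence summaries. Optional stages degrade gracefully: a
#' missing STR table skips the STR stages with a logged skip, a missing
#' haplogroup column skips the heterogeneity protocol. Missing mandatory
#' input fails before any stage runs. The report is deterministic
#' (bit-identical) given identical inputs and seeds.
#'
#' Config (YAML, JSON or an R list) blocks:
#' \preformatted{
#' inputs:            # either this block...
#'   vcf: path        # mandatory
#'   ancestral: ref | outgroup sample id
#'   str: path        # optional
#'   meta: path       # optional
#' simulate:          # ...or this one: arguments for sim_config()
#'   n_tips: 60
#'   seed: 7
#' rates:             # optional overrides for rate_model()
#' dating:
#'   min_clade_n: 5
#' heterogeneity:
#'   group: haplogroup | tissue_source
#'   k: 10
#'   reps: 100
#'   seed: 1
#' selection:
#'   annotations: path   # annotated_variants() TSV, optional
#' output:
#'   report: path        # JSON report, optional
#' }
#'
#' @param config path to a YAML/JSON config file, or an equivalent list
#' @return a `run_report` list: per-stage `status` (`ok`/`skipped`),
#'   `params` (including all seeds), `summary` statistics, and the main
#'   result objects in `$results`
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  status <- list()
  summary <- list()
  results <- list()

  rates <- do.call(rate_model, config$rates %||% list())

  # --- input stage ----------------------------------------------------------
  meta <- NULL; str_tab <- NULL; str_root <- NULL; truth <- NULL
  if (!is.null(config$simulate)) {
    sc <- do.call(sim_config, config$simulate)
    sim <- simulate_dataset(sc)
    hm <- sim$matrix
    meta <- sim$meta
    str_tab <- sim$str$profiles
    str_root <- sim$str$root
    truth <- sim
    status$input <- "ok"
  } else if (!is.null(config$inputs$vcf)) {
    if (!file.exists(config$inputs$vcf))
      ychron_stop(sprintf("mandatory input missing: %s", config$inputs$vcf))
    hm <- read_haploid_vcf(config$inputs$vcf,
                           require_complete = config$inputs$require_complete %||% TRUE)
    anc <- config$inputs$ancestral %||% "ref"
    hm <- polarize(hm, anc)
    if (!is.null(config$inputs$str)) str_tab <- read_str_table(config$inputs$str)
    if (!is.null(config$inputs$meta)) meta <- read_sample_meta(config$inputs$meta, hm)
    status$input <- "ok"
  } else {
    ychron_stop("config needs an `inputs` block with a vcf, or a `simulate` block")
  }

  # --- tree stage -----------------------------------------------------------
  tree <- build_tree(hm)
  results$tree <- tree
  idg <- identical_groups(hm)
  rec <- recurrence_summary(tree$site_report,
                            cpg = if (!is.null(truth))
                              setNames(truth$site_table$cpg,
                                       site_ids(truth$site_table)) else NULL)
  status$tree <- "ok"
  summary$n_samples <- nrow(hm$calls)
  summary$n_sites <- ncol(hm$calls)
  summary$identical_groups <- length(idg$groups)
  summary$recurrence <- rec

  # --- SNP dating -----------------------------------------------------------
  dating_cfg <- config$dating %||% list()
  snp_dates <- date_clades(tree, rates = rates,
                           min_n = dating_cfg$min_clade_n %||% 5)
  results$snp_dates <- snp_dates
  status$dating_snp <- "ok"
  summary$clade_dates <- snp_dates[, c("clade", "n", "rho", "tmrca_ka",
                                       "range_lo_ka", "range_hi_ka")]

  # --- STR dating and comparison -------------------------------------------
  if (!is.null(str_tab)) {
    nt <- length(tree$phy$tip.label)
    cl_nodes <- snp_dates$clade
    clades <- setNames(lapply(cl_nodes, function(cl)
      tree$phy$tip.label[tips_below(tree$phy, node_number(tree$phy, cl))]), cl_nodes)
    loci_avail <- colnames(str_tab$counts)
    subsets <- names(Filter(function(s) all(s %in% loci_avail), str_subsets()))
    str_dates <- date_str_clades(str_tab, clades, rates, subsets = subsets)
    if (!is.null(str_root)) {
      anc_dates <- date_str_clades(str_tab, clades, rates, subsets = subsets,
                                   roots = setNames(rep(list(str_root),
                                                        length(clades)),
                                                    names(clades)))
      str_dates <- rbind(str_dates, anc_dates)
    }
    results$str_dates <- str_dates
    results$snp_str_comparison <- compare_estimates(snp_dates, str_dates)
    status$dating_str <- "ok"
    summary$snp_str_comparison <- results$snp_str_comparison
  } else {
    status$dating_str <- "skipped: no STR table"
  }

  # --- branch-length heterogeneity -----------------------------------------
  het_cfg <- config$heterogeneity %||% list()
  grp_col <- het_cfg$group %||% "haplogroup"
  if (!is.null(meta) && grp_col %in% names(meta) &&
      sum(table(meta[[grp_col]]) >= 2) >= 2) {
    counts <- mutations_to_root(tree)
    labels <- meta[[grp_col]][match(names(counts), meta$sample_id)]
    keep <- !is.na(labels)
    het <- subsampled_pairwise_test(counts[keep], labels[keep],
                                    k = het_cfg$k %||% 10,
                                    R = het_cfg$reps %||% 100,
                                    seed = het_cfg$seed %||% 1)
    results$heterogeneity <- het
    status$heterogeneity <- "ok"
    summary$flagged_pairs <- het[het$flagged, c("group_a", "group_b",
                                                "prop_significant")]
  } else {
    status$heterogeneity <- sprintf("skipped: no usable '%s' groups", grp_col)
  }
  if (!is.null(meta) && sum(table(meta$tissue_source) >= 2) >= 2) {
    counts <- mutations_to_root(tree)
    gr <- split(as.numeric(counts),
                meta$tissue_source[match(names(counts), meta$sample_id)])
    gr <- gr[lengths(gr) >= 2]
    av <- tryCatch(anova_one_way(gr), ychron_error = function(e) NULL)
    if (!is.null(av)) {
      results$tissue_anova <- av
      summary$tissue_anova_p <- av$p_value
      status$tissue_anova <- "ok"
    } else status$tissue_anova <- "skipped: degenerate groups"
  } else {
    status$tissue_anova <- "skipped: no tissue groups"
  }

  # --- selection ------------------------------------------------------------
  if (!is.null(config$selection$annotations)) {
    ann <- annotated_variants(utils::read.delim(config$selection$annotations,
                                                stringsAsFactors = FALSE))
    bg <- config$selection$background %||%
      c(sum(colSums(hm$calls, na.rm = TRUE) == 1), ncol(hm$calls))
    preds <- grep("^damaging_", names(ann), value = TRUE)
    results$selection <- lapply(setNames(preds, preds), function(p)
      singleton_enrichment(ann, p, bg))
    summary$selection_p <- vapply(results$selection, `[[`, 1.0, "p_value")
    status$selection <- "ok"
  } else {
    status$selection <- "skipped: no annotations"
  }

  report <- list(stages = status,
                 params = list(rates = unclass(rates)[c("snp_rate", "snp_rate_ci",
                                                        "target_length",
                                                        "generation_time")],
                               seeds = list(simulate = config$simulate$seed,
                                            heterogeneity = het_cfg$seed %||% 1)),
                 summary = summary)
  out <- c(report, list(results = results))
  class(out) <- "run_report"
  if (!is.null(config$output$report)) {
    jsonlite::write_json(report, config$output$report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (s in names(x$stages)) cat(sprintf("  %-15s %s\n", s, x$stages[[s]]))
  invisible(x)
}
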