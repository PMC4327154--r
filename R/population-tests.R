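#' Mann-Whitney U test (exact enumeration or tie-corrected normal)
#'
#' Two-sided test of the Mann-Whitney U statistic. `method = "exact"` fully
#' enumerates the permutation distribution of U over all
#' `choose(n1+n2, n1)` group assignments (correct in the presence of ties,
#' unlike the classical exact distribution), and returns
#' `P(|U - n1 n2/2| >= |U_obs - n1 n2/2|)`. `method = "normal"` uses the
#' tie-corrected normal approximation with continuity correction (this is
#' [stats::wilcox.test()]). `method = "auto"` (default) enumerates when the
#' number of assignments is at most `2e5`, otherwise approximates.
#'
#' @param x,y numeric samples (nonempty)
#' @param method `"auto"`, `"exact"` or `"normal"`
#' @return list with `U` (for `x` relative to `y`, ties counted half) and
#'   `p_value`
#' @export
mw_u_test <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) ychron_stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ncomb <- choose(n1 + n2, n1)
  if (method == "auto") method <- if (ncomb <= 2e5) "exact" else "normal"
  if (method == "exact") {
    if (ncomb > 2e6) ychron_stop("exact enumeration infeasible for these sample sizes")
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    mid <- n1 * n2 / 2
    p <- sum(abs(u_all - mid) >= abs(U - mid) - 1e-9) / ncomb
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    p <- wt$p.value
    if (is.nan(p)) p <- 1       # zero variance (all values tied)
  }
  list(U = U, p_value = min(p, 1))
}

#' Subsampled pairwise branch-length heterogeneity protocol
#'
#' For every pair of groups: in each of `R` replicates, groups larger than
#' `k` are subsampled without replacement to `k` members (groups with
#' `n <= k` are used whole), a two-sided Mann-Whitney U test is applied to
#' the per-sample mutation counts, and the p-value is recorded. P-values are
#' Bonferroni-corrected by the number of pairs tested (overridable via
#' `m_correction`). A pair is flagged "of interest" when more than half of
#' its replicates are significant after correction.
#'
#' @param counts numeric vector of per-sample mutations-to-root
#' @param labels group label per sample (haplogroup, tissue source, ...)
#' @param k subsample size (>= 2)
#' @param R replicates per pair
#' @param alpha significance level applied to corrected p-values
#' @param m_correction Bonferroni divisor; default = number of pairs tested
#' @param min_n groups smaller than this are excluded (default 2)
#' @param seed integer seed; the protocol is deterministic given the seed
#' @param method Mann-Whitney flavour passed to [mw_u_test()]; default
#'   `"normal"` (the approximation is the default at the protocol's k = 10)
#' @return data.frame of class `heterogeneity_result`: one row per pair with
#'   `group_a`, `group_b`, `n_a`, `n_b`, `prop_significant`, `flagged`;
#'   per-replicate p-values in attribute `"p_values"` (named list)
#' @export
subsampled_pairwise_test <- function(counts, labels, k = 10, R = 100,
                                     alpha = 0.05, m_correction = NULL,
                                     min_n = 2, seed = 1, method = "normal") {
  if (k < 2) ychron_stop("k must be >= 2")
  stopifnot(length(counts) == length(labels))
  groups <- split(as.numeric(counts), as.character(labels))
  groups <- groups[lengths(groups) >= min_n]
  if (length(groups) < 2) ychron_stop("need >= 2 groups with enough samples")
  gn <- names(groups)
  prs <- utils::combn(gn, 2)
  n_pairs <- ncol(prs)
  m <- m_correction %||% n_pairs
  set.seed(as.integer(seed))
  pvals <- vector("list", n_pairs)
  rows <- vector("list", n_pairs)
  for (j in seq_len(n_pairs)) {
    a <- groups[[prs[1, j]]]; b <- groups[[prs[2, j]]]
    p <- vapply(seq_len(R), function(rep) {
      xa <- if (length(a) > k) sample(a, k) else a
      xb <- if (length(b) > k) sample(b, k) else b
      mw_u_test(xa, xb, method = method)$p_value
    }, 1.0)
    prop <- mean(pmin(p * m, 1) < alpha)
    pvals[[j]] <- p
    rows[[j]] <- data.frame(group_a = prs[1, j], group_b = prs[2, j],
                            n_a = length(a), n_b = length(b),
                            prop_significant = prop, flagged = prop > 0.5,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("heterogeneity_result", "data.frame")
  names(pvals) <- paste(prs[1, ], prs[2, ], sep = "|")
  attr(out, "p_values") <- pvals
  attr(out, "params") <- list(k = k, R = R, alpha = alpha, m = m, seed = seed)
  out
}

#' Classical one-way analysis of variance
#'
#' @param groups list of >= 2 numeric samples
#' @return list with `F`, `p_value`, `df` (between, within)
#' @export
anova_one_way <- function(groups) {
  if (length(groups) < 2) ychron_stop("need >= 2 groups")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(y) <= length(groups)) ychron_stop("total n must exceed the number of groups")
  if (all(vapply(groups, function(v) stats::var(v) == 0 || length(v) < 2, NA)))
    ychron_stop("zero within-group variance in all groups")
  fit <- stats::anova(stats::lm(y ~ g))
  list(F = fit$`F value`[1], p_value = fit$`Pr(>F)`[1],
       df = c(between = fit$Df[1], within = fit$Df[2]))
}

#' Monte-Carlo power of the Mann-Whitney test for a branch-length shift
#'
#' Optional helper: simulates Poisson mutation counts in two groups whose
#' means differ by `shift` and reports the fraction of replicates with a
#' two-sided Mann-Whitney p below `alpha`.
#'
#' @param n1,n2 group sizes
#' @param mean1 Poisson mean of the first group
#' @param shift mean difference (group 2 mean = `mean1 + shift`)
#' @param alpha significance level
#' @param reps Monte-Carlo replicates
#' @param seed integer seed
#' @return estimated power (scalar in `[0, 1]`)
#' @export
mw_power <- function(n1, n2, mean1, shift, alpha = 0.05, reps = 1000, seed = 1) {
  set.seed(as.integer(seed))
  mean(vapply(seq_len(reps), function(i) {
    x <- stats::rpois(n1, mean1)
    y <- stats::rpois(n2, mean1 + shift)
    mw_u_test(x, y, method = "normal")$p_value < alpha
  }, NA))
}
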