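#' Lilliefors test of composite normality
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with
#' estimated mean and SD; the p-value comes from a seeded Monte-Carlo null
#' distribution (10,000 resamples by default), computed once per sample
#' size and cached.
#'
#' @param differences numeric sample (n >= 4).
#' @param n_sim Monte-Carlo resamples for the null (default 10000).
#' @return list: `statistic` (sup-difference D), `p_value`, `n`.
#' @export
lilliefors_normality <- function(differences, n_sim = 10000) {
  x <- differences[is.finite(differences)]
  n <- length(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (sd(x) == 0) # constant sample: non-normal by convention
    return(list(statistic = 1, p_value = 0, n = n))
  D <- lilliefors_statistic(x)
  null <- lilliefors_null(n, n_sim)
  p <- (1 + sum(null >= D)) / (length(null) + 1)
  list(statistic = D, p_value = p, n = n)
}

#' Lilliefors KS statistic (sup-difference to the fitted normal CDF)
#' @param x numeric sample.
#' @return scalar D.
#' @export
lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  F0 <- stats::pnorm(z)
  max(pmax(seq_len(n) / n - F0, F0 - (seq_len(n) - 1) / n))
}

lilliefors_null <- function(n, n_sim) {
  key <- paste0("lillie_", n, "_", n_sim)
  if (!is.null(.lp_cache[[key]])) return(.lp_cache[[key]])
  null <- with_seed(10007L + n, vapply(seq_len(n_sim), function(i)
    lilliefors_statistic(rnorm(n)), numeric(1)))
  .lp_cache[[key]] <- null
  null
}

#' Normality-gated paired two-group comparison
#'
#' Tests the paired differences for normality with the Lilliefors test at
#' the gate level; normal differences go to a two-tailed paired t-test,
#' non-normal ones to a two-sided Wilcoxon signed-rank test (exact for
#' n <= 25 after dropping zero differences, normal approximation with
#' continuity correction otherwise).  Degenerate cases: all-zero
#' differences give p = 1; equal nonzero differences (zero variance) are
#' routed to an exact sign test.
#'
#' @param group_a,group_b paired numeric vectors of equal length.
#' @param alpha significance level (default 0.05, also the gate level).
#' @param paired set `FALSE` for the unpaired Mann-Whitney variant.
#' @param comparison label carried into the result.
#' @return one-row data frame: `comparison`, `n`, `normality_p`, `test`,
#'   `statistic`, `p_value`, `significant`.
#' @export
paired_compare <- function(group_a, group_b, alpha = 0.05, paired = TRUE,
                           comparison = "") {
  stopifnot(length(group_a) == length(group_b) || !paired)
  if (!paired) {
    wt <- suppressWarnings(wilcox.test(group_a, group_b, exact = FALSE,
                                       correct = TRUE))
    return(data.frame(comparison = comparison, n = length(group_a),
                      normality_p = NA_real_, test = "mann_whitney",
                      statistic = unname(wt$statistic),
                      p_value = wt$p.value,
                      significant = wt$p.value < alpha,
                      stringsAsFactors = FALSE))
  }
  d <- group_a - group_b
  n <- length(d)
  if (all(d == 0)) {
    return(data.frame(comparison = comparison, n = n, normality_p = NA_real_,
                      test = "degenerate", statistic = 0, p_value = 1,
                      significant = FALSE, stringsAsFactors = FALSE))
  }
  if (sd(d) == 0) { # equal nonzero differences: exact sign test
    p <- min(1, 2 * 0.5^n)
    return(data.frame(comparison = comparison, n = n, normality_p = 0,
                      test = "sign", statistic = n, p_value = p,
                      significant = p < alpha, stringsAsFactors = FALSE))
  }
  gate <- lilliefors_normality(d)
  if (gate$p_value >= alpha) {
    tt <- t.test(group_a, group_b, paired = TRUE)
    res <- data.frame(comparison = comparison, n = n,
                      normality_p = gate$p_value, test = "paired_t",
                      statistic = unname(tt$statistic),
                      p_value = tt$p.value,
                      significant = tt$p.value < alpha,
                      stringsAsFactors = FALSE)
  } else {
    nz <- d[d != 0]
    wt <- suppressWarnings(
      wilcox.test(nz, exact = length(nz) <= 25, correct = TRUE))
    res <- data.frame(comparison = comparison, n = n,
                      normality_p = gate$p_value, test = "wilcoxon",
                      statistic = unname(wt$statistic),
                      p_value = wt$p.value,
                      significant = wt$p.value < alpha,
                      stringsAsFactors = FALSE)
    res$n_zero_dropped <- n - length(nz)
  }
  res
}

#' One-way analysis of variance
#'
#' Classic equal-variance one-way ANOVA across three or more groups.
#'
#' @param groups list of numeric vectors (each n >= 2).
#' @param alpha significance level (default 0.05).
#' @param comparison label carried into the result.
#' @return one-row data frame with `test = "anova"`, the F statistic and
#'   p-value.
#' @export
one_way_anova <- function(groups, alpha = 0.05, comparison = "") {
  if (length(groups) < 3) stop("need at least 3 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 observations", call. = FALSE)
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
  Fst <- unname(ow$statistic)
  if (!is.finite(Fst)) Fst <- 0 # identical constant groups
  p <- if (is.finite(ow$p.value)) ow$p.value else 1
  data.frame(comparison = comparison, n = length(values),
             normality_p = NA_real_, test = "anova", statistic = Fst,
             p_value = p, significant = p < alpha, stringsAsFactors = FALSE)
}
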