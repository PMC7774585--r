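#' Summarise a raw sample for two-group comparison
#'
#' @param x Numeric vector, length >= 2.
#' @return A `pps_group_summary`: list with `n`, `mean`, `sd`.
#' @export
group_summary <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  structure(list(n = length(x), mean = mean(x), sd = stats::sd(x)),
            class = "pps_group_summary")
}

as_group_summary <- function(s) {
  if (inherits(s, "pps_group_summary")) return(s)
  s <- as.list(s)
  stopifnot(all(c("n", "mean", "sd") %in% names(s)))
  if (s$n < 2 || s$sd < 0) stop("invalid group summary", call. = FALSE)
  structure(s[c("n", "mean", "sd")], class = "pps_group_summary")
}

comparison_result <- function(statistic, df, p, pairwise = NULL, note = NULL) {
  structure(list(statistic = statistic, df = df, p = p,
                 pairwise = pairwise, note = note),
            class = "pps_comparison")
}

#' @export
print.pps_comparison <- function(x, ...) {
  cat(sprintf("statistic = %.4g, df = %s, p = %s\n", x$statistic,
              paste(signif(x$df, 6), collapse = ", "),
              format.pval(x$p, digits = 3, eps = 1e-4)))
  if (!is.null(x$pairwise)) {
    for (nm in names(x$pairwise)) {
      cat(sprintf("  %s: adjusted p = %s\n", nm,
                  format.pval(x$pairwise[[nm]], digits = 3, eps = 1e-4)))
    }
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Welch two-sample t-test from group summaries
#'
#' Works from `(n, mean, sd)` triples, so published summary tables can be
#' re-tested without raw data. The unequal-variance (Welch) form is used:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value.
#'
#' @param summary1,summary2 Group summaries: [group_summary()] objects or
#'   lists/vectors with `n`, `mean`, `sd`.
#' @return A `pps_comparison` with `statistic` (t), `df` and `p`. When both
#'   SDs are zero and means equal, p = 1 by convention with an explanatory
#'   note.
#' @examples
#' welch_t(list(n = 15, mean = 36.7, sd = 12.7),
#'         list(n = 66, mean = 25.9, sd = 4.9)) # p = 0.0055
#' @export
welch_t <- function(summary1, summary2) {
  a <- as_group_summary(summary1)
  b <- as_group_summary(summary2)
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (va + vb == 0) {
    if (a$mean == b$mean) {
      return(comparison_result(0, NA_real_, 1,
                               note = "degenerate: both groups constant and equal"))
    }
    stop("both groups constant with different means: t undefined", call. = FALSE)
  }
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(t), df)
  comparison_result(t, df, p)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test on a 2x2 contingency table. The two-sided p-value
#' follows the probability-mass rule: with margins fixed, sum the
#' hypergeometric probabilities of every table whose probability does not
#' exceed that of the observed table (a relative tolerance of 1e-7 guards the
#' comparison, matching common practice).
#'
#' @param table A 2x2 matrix of non-negative integer counts with at least one
#'   positive margin.
#' @return A `pps_comparison` with `p`; `statistic` is the observed odds
#'   ratio estimate `ad/bc` (may be `Inf`), `df` is `NA`.
#' @examples
#' fisher_exact(matrix(c(4, 11, 30, 36), 2, byrow = TRUE)) # p = 0.25
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(tab) == 0) stop("all-zero table", call. = FALSE)
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  support <- lo:hi
  logp <- stats::dhyper(support, c1, n - c1, r1, log = TRUE)
  obs <- logp[support == a]
  p <- sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
  p <- min(1, p)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  comparison_result(or, NA_real_, p)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Omnibus F-test for a difference in means across two or more groups,
#' followed by all pairwise comparisons adjusted by the Tukey Honest
#' Significant Differences method (Tukey-Kramer for unbalanced groups). With
#' exactly two groups the F statistic equals the squared pooled-variance t.
#'
#' @param groups Named (or unnamed) list of numeric vectors, each of length
#'   >= 2.
#' @return A `pps_comparison` with `statistic` (F), `df` (c(between, within)),
#'   `p`, and `pairwise`: named vector of Tukey-adjusted p-values.
#' @export
one_way_anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 0L) < 2)) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 0L)),
                   levels = names(groups))
  )
  if (stats::var(dat$value) == 0) {
    return(comparison_result(0, c(length(groups) - 1, nrow(dat) - length(groups)),
                             1, note = "degenerate: all observations equal"))
  }
  fit <- stats::aov(value ~ group, data = dat)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- stats::setNames(tk[, "p adj"], rownames(tk))
  comparison_result(tab["group", "F value"],
                    c(tab["group", "Df"], tab["Residuals", "Df"]),
                    tab["group", "Pr(>F)"],
                    pairwise = pairwise)
}

#' Pearson correlation with two-sided test
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return A `pps_comparison` with `statistic` (r), `df` (n - 2) and the
#'   two-sided `p` from the t transform.
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  comparison_result(unname(ct$estimate), unname(ct$parameter), ct$p.value)
}
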