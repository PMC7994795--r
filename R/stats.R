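# Nonparametric statistics and summary reporting. Data are summarized as
# median with 25th/75th percentiles (type-7 linear-interpolation quartiles),
# with mean and SD included for parametric reporting.

#' Summarize a numeric sample
#'
#' @param values numeric vector, n >= 1.
#' @param label group label.
#' @return one-row data.frame: label, n, median, q25, q75, mean, sd.
#'   Quartiles use linear interpolation between order statistics (type 7),
#'   so published quartiles computed under other conventions may differ in
#'   the third decimal.
#' @export
summarizeValues <- function(values, label = "") {
  if (!length(values)) stop("empty input")
  if (anyNA(values)) stop("missing values in input")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(label = label, n = length(values), median = q[2], q25 = q[1],
             q75 = q[3], mean = mean(values),
             sd = if (length(values) > 1) sd(values) else 0)
}

#' Rank-based group comparisons
#'
#' Mann-Whitney rank-sum test for two groups, Kruskal-Wallis nonparametric
#' ANOVA for two or more. Both are tie-corrected; the Mann-Whitney p-value
#' is exact for small samples without ties and uses the continuity-corrected
#' normal approximation otherwise (the R default), Kruskal-Wallis uses the
#' chi-square approximation.
#'
#' @param groups list of numeric vectors (named or not).
#' @param kind "mann_whitney" (exactly 2 groups) or "kruskal_wallis" (>= 2).
#' @return list with `statistic` (U, or H) and `p` (two-tailed).
#' @export
rankTests <- function(groups, kind = c("mann_whitney", "kruskal_wallis")) {
  kind <- match.arg(kind)
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("empty group")
  if (kind == "mann_whitney") {
    if (length(groups) != 2) stop("mann_whitney needs exactly 2 groups")
    ht <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]],
                                       alternative = "two.sided"))
    list(statistic = unname(ht$statistic), p = ht$p.value, kind = kind)
  } else {
    if (length(groups) < 2) stop("kruskal_wallis needs >= 2 groups")
    ht <- kruskal.test(groups)
    list(statistic = unname(ht$statistic), p = ht$p.value, kind = kind)
  }
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the two-tailed p-value uses
#' the t-distribution approximation \eqn{t = r\sqrt{(n-2)/(1-r^2)}}.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list with `r`, `p` and `n`.
#' @export
spearmanCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant input")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Significance stars
#'
#' The conventional mapping: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `"n.s."` otherwise.
#'
#' @param p p-value(s).
#' @return character vector of star labels.
#' @export
significanceStars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) NA_character_
    else if (pp < 0.001) "***"
    else if (pp < 0.01) "**"
    else if (pp < 0.05) "*"
    else "n.s."
  }, character(1))
}
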