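## Method-comparison statistics: Pearson product-moment correlation with
## two-tailed significance (t transform, n - 2 df) and the one-sample
## Kolmogorov-Smirnov normality test against a normal with the sample
## moments. Both are written out explicitly so that stats::cor.test and
## stats::ks.test can serve as independent cross-checks in the test suite.

## Asymptotic CDF of the Kolmogorov distribution, P(K <= t). Two standard
## series: the theta-function form for small t, the alternating form for
## large t, switching at t = 1. Terms are truncated at the conventional
## 1e-6 tolerance of statistical software (below t = 1 that keeps odd k
## with k^2 < 2 - log(tol), i.e. the leading theta term), so p-values agree
## with the usual asymptotic K-S routines to well below that tolerance.
pKolmogorov <- function(t, tol = 1e-6) {
  if (t <= 0) return(0)
  if (t < 1) {
    kMax <- floor(sqrt(2 - log(tol)))
    k <- seq(1, kMax, by = 2)
    k <- k[k < kMax]
    sqrt(2 * pi) / t * sum(exp(-k^2 * pi^2 / (8 * t^2)))
  } else {
    k <- 1:20
    1 - 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  }
}

#' One-sample Kolmogorov-Smirnov normality test
#'
#' Tests a sample against a normal distribution with the sample mean and
#' sample standard deviation (the SPSS-style normality screen). The
#' statistic is the usual sup-distance D between the empirical CDF and the
#' fitted normal CDF; the p-value is the asymptotic Kolmogorov tail of
#' `sqrt(n) * D`. The test is location-scale invariant: shifting or
#' rescaling the sample leaves D unchanged.
#'
#' @param x Numeric sample, n >= 3, non-degenerate.
#' @return A list with `statistic` (D), `p` (asymptotic two-sided), `n`,
#'   `mean` and `sd`.
#' @examples
#' ksNormality(rnorm(100))
#' @export
ksNormality <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) vstop("sample must not contain NA", field = "x")
  n <- length(x)
  if (n < 3) vstop("at least 3 observations are required", field = "x")
  s <- stats::sd(x)
  if (s == 0) vstop("degenerate sample: zero variance", field = "x")
  m <- mean(x)
  u <- sort(stats::pnorm(x, mean = m, sd = s))
  i <- seq_len(n)
  D <- max(i / n - u, u - (i - 1) / n)
  list(statistic = D,
       p = max(0, min(1, 1 - pKolmogorov(sqrt(n) * D))),
       n = n, mean = m, sd = s)
}

#' Pearson correlation of paired measurements
#'
#' Product-moment correlation coefficient with its two-tailed significance
#' from the t transform, `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2
#' degrees of freedom, plus the ordinary least-squares line of y on x for
#' scatter-plot panels and K-S normality screens of both variables.
#'
#' @param x,y Paired numeric samples of equal length, n >= 3, each with
#'   non-zero variance.
#' @param label Panel label.
#' @param xLabel,yLabel Variable labels.
#' @return A [CorrelationReport-class] object.
#' @examples
#' pearsonCorrelation(c(1, 2, 3), c(1, 2, 4))
#' @export
pearsonCorrelation <- function(x, y, label = "", xLabel = "x", yLabel = "y") {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    vstop("x and y must have equal length (%d vs %d)", length(x), length(y),
          field = "y")
  if (anyNA(x) || anyNA(y)) vstop("samples must not contain NA")
  n <- length(x)
  if (n < 3) vstop("at least 3 pairs are required", field = "x")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0)
    vstop("degenerate sample: zero variance", field = if (sxx == 0) "x" else "y")
  sxy <- sum(dx * dy)
  r <- sxy / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (1 - r^2 <= 0) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  slope <- sxy / sxx
  normality <- do.call(rbind, lapply(
    list(x = list(v = x, lab = xLabel), y = list(v = y, lab = yLabel)),
    function(e) {
      ks <- ksNormality(e$v)
      data.frame(variable = e$lab, statistic = ks$statistic, p = ks$p)
    }))
  rownames(normality) <- NULL
  new("CorrelationReport",
      label = label, xLabel = xLabel, yLabel = yLabel,
      x = x, y = y, n = as.integer(n), r = r, p = p,
      slope = slope, intercept = mean(y) - slope * mean(x),
      normality = normality)
}

setMethod("show", "CorrelationReport", function(object) {
  cat(sprintf("CorrelationReport%s: n = %d\n",
              if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
              object@n))
  cat(sprintf("  %s vs %s: r = %.4f, two-tailed p = %.3g\n",
              object@yLabel, object@xLabel, object@r, object@p))
  cat(sprintf("  OLS line: y = %.4g + %.4g x\n",
              object@intercept, object@slope))
})

## Flatten a CorrelationReport for JSON reports.
reportToList <- function(rep) {
  list(label = rep@label, x = rep@xLabel, y = rep@yLabel,
       n = rep@n, r = rep@r, p = rep@p,
       slope = rep@slope, intercept = rep@intercept,
       normality = rep@normality)
}
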