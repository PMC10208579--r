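# Summary-statistics t tests and false-discovery-rate control.

#' Two-sample t test from summary statistics
#'
#' Two-sided t test of equal means given group means, standard deviations
#' and sample sizes, either with pooled variance (`var.equal = TRUE`) or
#' Welch's unequal-variance form with Welch-Satterthwaite degrees of
#' freedom. All arguments are vectorized.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return Tibble with columns `t`, `df`, `p`. When both standard
#'   deviations are zero the test is degenerate: `p = 1` for equal means
#'   and `p = 0` (with a warning) for unequal means.
#' @examples
#' t_test_summary(0, 0.1, 3, 0.3, 0.1, 3)
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  k <- max(length(mean1), length(mean2))
  mean1 <- rep_len(mean1, k); sd1 <- rep_len(sd1, k); n1 <- rep_len(n1, k)
  mean2 <- rep_len(mean2, k); sd2 <- rep_len(sd2, k); n2 <- rep_len(n2, k)
  if (any(c(sd1, sd2) < 0, na.rm = TRUE)) stop("standard deviations must be >= 0")
  if (any(c(n1, n2) < 2, na.rm = TRUE)) stop("both groups need n >= 2")

  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  p <- 2 * stats::pt(-abs(t), df)

  degen <- se == 0
  if (any(degen, na.rm = TRUE)) {
    # with no variance at all, compare means up to numerical round-off
    tol <- 1.5e-8 * pmax(1, abs(mean1), abs(mean2))
    same <- degen & (abs(mean1 - mean2) <= tol)
    t[same] <- 0; p[same] <- 1; df[same] <- n1[same] + n2[same] - 2
    diffm <- degen & !same
    if (any(diffm, na.rm = TRUE)) {
      warning("zero variance with unequal means: p set to 0")
      t[diffm] <- sign(mean1[diffm] - mean2[diffm]) * Inf
      p[diffm] <- 0
      df[diffm] <- n1[diffm] + n2[diffm] - 2
    }
  }
  tibble::tibble(t = t, df = df, p = p)
}

# Storey pi0 estimate with the smoother method: pi0(lambda) over a lambda
# grid, smoothed with a df = 3 spline and read off at the largest lambda.
storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, .Machine$double.eps), 1)
}

#' False-discovery-rate adjustment
#'
#' Converts p values into q values with significance flags, by one of:
#' `"storey"` — q values with the smoother \eqn{\pi_0} estimate
#' (\eqn{\lambda} grid 0.05 to 0.95 in steps of 0.05, spline df 3,
#' clamped to (0, 1]); `"bh"` — Benjamini-Hochberg adjusted p values;
#' `"bky"` — the two-stage Benjamini-Krieger-Yekutieli step-up procedure
#' at level `alpha`: stage one runs BH at `alpha / (1 + alpha)` to
#' estimate the number of true nulls m0, stage two re-runs BH with m0 in
#' place of m. For `"bky"` the reported q values are the m0/m-scaled BH
#' adjusted p values and the flags are the two-stage decisions at `alpha`.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @param method `"storey"`, `"bh"` or `"bky"`.
#' @param alpha Significance threshold on q; default 0.05.
#' @return Tibble with columns `p`, `q`, `significant`, plus a `pi0`
#'   attribute for `"storey"`.
#' @export
fdr_adjust <- function(p, method = c("storey", "bh", "bky"), alpha = 0.05) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  m <- sum(!is.na(p))
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pi0 <- NA_real_

  if (method == "bh") {
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    sig <- q < alpha
  } else if (method == "storey") {
    pi0 <- storey_pi0(p[ok])
    pv <- p[ok]
    o <- order(pv, decreasing = TRUE)
    r <- rank(pv, ties.method = "max")
    qv <- pi0 * m * pv[o] / r[o]
    qv <- pmin(1, cummin(qv))
    tmp <- numeric(m); tmp[o] <- qv
    q[ok] <- tmp
    sig <- q < alpha
  } else {
    alpha1 <- alpha / (1 + alpha)
    bh <- stats::p.adjust(p[ok], method = "BH")
    r1 <- sum(bh <= alpha1)
    m0 <- m - r1
    if (m0 == 0L) {
      q[ok] <- bh
      sig <- rep(TRUE, length(p)); sig[!ok] <- NA
    } else {
      q[ok] <- pmin(1, bh * m0 / m)
      sig <- q <= alpha1
    }
  }
  out <- tibble::tibble(p = p, q = q, significant = sig)
  attr(out, "pi0") <- pi0
  out
}
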