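#' Paired comparison of two response-time arms
#'
#' Holds the two equal-length vectors of per-demand-point seconds being
#' compared (e.g. ambulance vs bystander on the same simulated
#' occurrences). Non-finite entries must be excluded upstream; the
#' constructor refuses them so that exclusions are always explicit.
#'
#' @param a,b equal-length numeric vectors, finite entries only.
#' @param labels character(2), names of the two arms.
#' @return A list of class `paired_comparison`.
#' @export
paired_comparison <- function(a, b, labels = c("a", "b")) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 1) stop("need at least one pair")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("non-finite entries must be excluded upstream (with a reported count)")
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 labels = as.character(labels)),
            class = "paired_comparison")
}

# Exact null distribution of W+ for n tie-free pairs: counts of subset-sums
# of ranks 1..n, by dynamic programming (convolution). Returns the vector
# of counts for W+ = 0..n(n+1)/2.
signed_rank_null_counts <- function(n) {
  m <- n * (n + 1) / 2
  f <- numeric(m + 1)
  f[1] <- 1
  for (r in seq_len(n)) {
    g <- f
    g[(r + 1):(m + 1)] <- g[(r + 1):(m + 1)] + f[1:(m + 1 - r)]
    f <- g
  }
  f
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Computes the paired signed-rank test on `d = a - b`: zero differences
#' are dropped (Wilcoxon's convention; Pratt's method keeps them for
#' ranking), absolute differences are ranked with midranks for ties, and
#' the two-sided p-value comes from the exact permutation null (all
#' `2^n` sign assignments, evaluated by dynamic programming) whenever the
#' effective sample is small enough (`n_effective <= exact_limit`) and
#' tie-free; otherwise from the tie-corrected normal approximation. The
#' standardized statistic `z` is reported in both regimes, so results can
#' be compared with studies that print z rather than W.
#'
#' @param a,b paired numeric vectors, or a [paired_comparison()] as `a`.
#' @param exact_limit largest `n_effective` for which the exact null is
#'   enumerated (default 25).
#' @param continuity apply a 0.5 continuity correction to z (default
#'   `FALSE`; conventions differ between software packages).
#' @param zero_method `"wilcox"` (drop zero differences, default) or
#'   `"pratt"` (rank them, then drop; normal approximation only).
#' @return An object of class `wilcoxon_srt` with fields `w_plus`,
#'   `w_minus`, `n_effective`, `n_zero`, `z`, `p`, `method`
#'   (`"exact"` or `"normal_approx"`), `degenerate`.
#' @examples
#' wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))  # p = 0.0625
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, exact_limit = 25,
                                 continuity = FALSE,
                                 zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  if (inherits(a, "paired_comparison")) {
    labels <- a$labels; b <- a$b; a <- a$a
  } else {
    labels <- c("a", "b")
    pc <- paired_comparison(a, b)
    a <- pc$a; b <- pc$b
  }
  d <- a - b
  zero <- d == 0
  n_zero <- sum(zero)
  if (all(zero)) {
    return(structure(list(w_plus = 0, w_minus = 0, n_effective = 0L,
                          n_zero = n_zero, z = 0, p = 1,
                          method = "degenerate", degenerate = TRUE,
                          labels = labels), class = "wilcoxon_srt"))
  }
  if (zero_method == "wilcox") {
    d_used <- d[!zero]
    r <- rank(abs(d_used))
  } else {
    r_all <- rank(abs(d))       # zeros participate in ranking...
    d_used <- d[!zero]
    r <- r_all[!zero]           # ...then are dropped from the sums
  }
  n <- length(d_used)
  w_plus <- sum(r[d_used > 0])
  w_minus <- sum(r[d_used < 0])
  ties <- any(duplicated(abs(d_used))) || n_zero > 0 && zero_method == "pratt"
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  num <- w_plus - mu
  if (continuity) num <- num - sign(num) * 0.5
  z <- if (sigma2 > 0) num / sqrt(sigma2) else 0
  if (!ties && n <= exact_limit && zero_method == "wilcox") {
    counts <- signed_rank_null_counts(n)
    tot <- 2^n
    lower <- sum(counts[seq_len(w_plus + 1)]) / tot        # P(W+ <= w)
    upper <- sum(counts[(w_plus + 1):length(counts)]) / tot # P(W+ >= w)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  structure(list(w_plus = w_plus, w_minus = w_minus, n_effective = n,
                 n_zero = n_zero, z = z, p = p, method = method,
                 degenerate = FALSE, labels = labels),
            class = "wilcoxon_srt")
}

#' @export
print.wilcoxon_srt <- function(x, ...) {
  cat(sprintf("<wilcoxon signed-rank> %s vs %s\n", x$labels[1], x$labels[2]))
  if (x$degenerate) {
    cat("  degenerate: all paired differences are zero; p = 1\n")
    return(invisible(x))
  }
  cat(sprintf("  n = %d (%d zero difference(s) dropped)\n",
              x$n_effective, x$n_zero))
  cat(sprintf("  W+ = %g, W- = %g, z = %.3f, p = %.4g (%s)\n",
              x$w_plus, x$w_minus, x$z, x$p, x$method))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Gatekeeper before the nonparametric comparison: W compares the sample's
#' order statistics with their normal expectations (Royston's AS R94
#' approximation, valid for 3 <= n <= 5000).
#'
#' @param x numeric vector, 3 <= length <= 5000, non-constant.
#' @return An object of class `normality_result` with `w_statistic`, `p`,
#'   `n`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::var(x) == 0) stop("zero variance")
  sw <- stats::shapiro.test(x)
  structure(list(w_statistic = unname(sw$statistic), p = sw$p.value, n = n),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("<shapiro-wilk> W = %.4f, p = %.4g, n = %d\n",
              x$w_statistic, x$p, x$n))
  invisible(x)
}

#' Descriptive summary of a time vector
#'
#' Mean, median, sd and a confidence interval of the mean, by Student-t
#' (default) or seeded percentile bootstrap.
#'
#' @param times numeric vector (n >= 2 finite values).
#' @param ci_method `"t"` or `"bootstrap"`.
#' @param level confidence level (default 0.95).
#' @param B bootstrap replicates (default 10000).
#' @param seed seed for the bootstrap.
#' @return An object of class `summary_stats` with `n`, `mean`, `median`,
#'   `sd`, `ci_low`, `ci_high`, `level`, `ci_method`.
#' @export
summarize_times <- function(times, ci_method = c("t", "bootstrap"),
                            level = 0.95, B = 10000, seed = 1) {
  ci_method <- match.arg(ci_method)
  x <- times[is.finite(times)]
  n <- length(x)
  if (n < 2) stop("need at least 2 finite values")
  m <- mean(x); s <- stats::sd(x)
  if (ci_method == "t") {
    half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * s / sqrt(n)
    ci <- c(m - half, m + half)
  } else {
    ci <- with_seed(seed, {
      boots <- vapply(seq_len(B), function(i) mean(sample(x, n, TRUE)),
                      numeric(1))
      unname(stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                             type = 7))
    })
  }
  structure(list(n = n, mean = m, median = stats::median(x), sd = s,
                 ci_low = ci[1], ci_high = ci[2], level = level,
                 ci_method = ci_method),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "<summary> n = %d, mean %.1f s (%.0f%% CI %.1f, %.1f; %s), median %.1f s, sd %.1f\n",
    x$n, x$mean, 100 * x$level, x$ci_low, x$ci_high, x$ci_method,
    x$median, x$sd))
  invisible(x)
}
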