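#' Cronbach's alpha for a Likert-scale matrix
#'
#' Internal-consistency reliability of a multi-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total scores))`,
#' with sample variances (n-1 denominator). Respondents are rows, items
#' columns. For two items with equal variances and correlation r this
#' reduces to the Spearman-Brown form `2r / (1 + r)`.
#'
#' @param m numeric matrix or data.frame, respondents x items, no missing
#'   cells; k >= 2 items, n >= 2 respondents.
#' @return An object of class `cronbach_result` with `alpha`, `k`, `n`.
#' @examples
#' m <- cbind(q1 = c(7, 6, 5, 7), q2 = c(6, 6, 5, 7), q3 = c(7, 5, 5, 6))
#' cronbach_alpha(m)
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not supported")
  k <- ncol(m); n <- nrow(m)
  if (k < 2) stop("need at least 2 items")
  if (n < 2) stop("need at least 2 respondents")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop("zero variance of total scores")
  item_var <- apply(m, 2, stats::var)
  alpha <- k / (k - 1) * (1 - sum(item_var) / total_var)
  structure(list(alpha = alpha, k = k, n = n), class = "cronbach_result")
}

#' @export
print.cronbach_result <- function(x, ...) {
  cat(sprintf("<cronbach> alpha = %.3f (%d items, %d respondents)\n",
              x$alpha, x$k, x$n))
  invisible(x)
}

#' Read a Likert response matrix from CSV
#'
#' Respondents as rows, items as columns, a header row of item ids;
#' integer responses on a 1..`scale_max` scale (7-point by default, the
#' usual usability-questionnaire convention), no missing cells.
#'
#' @param path CSV file path.
#' @param scale_max top of the response scale (default 7).
#' @return integer matrix with item ids as colnames.
#' @export
read_likert_csv <- function(path, scale_max = 7) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "numeric"
  if (anyNA(m)) stop("missing cells are not supported")
  if (any(m != round(m)) || any(m < 1) || any(m > scale_max))
    stop(sprintf("responses must be integers in 1..%d", scale_max))
  storage.mode(m) <- "integer"
  m
}
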