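# Community diversity and cross-group comparison statistics.

#' Shannon-Wiener diversity index
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive abundance, natural
#' logarithm. Scale-invariant in the counts.
#'
#' @param counts Non-negative abundance vector with a positive sum.
#' @return The index `H`.
#' @examples
#' shannon_wiener(c(25, 25, 25, 25))  # log(4)
#' @export
shannon_wiener <- function(counts) {
  if (!is.numeric(counts) || any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative numbers", call. = FALSE)
  }
  s <- sum(counts)
  if (s <= 0) stop("counts must contain at least one positive entry", call. = FALSE)
  p <- counts[counts > 0] / s
  -sum(p * log(p))
}

#' Per-group arithmetic means
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length.
#' @param na.rm Drop missing values before averaging.
#' @return Named numeric vector of group means.
#' @export
group_mean <- function(values, groups, na.rm = FALSE) {
  stopifnot(length(values) == length(groups))
  if (na.rm) {
    keep <- !is.na(values)
    values <- values[keep]
    groups <- groups[keep]
  }
  if (length(values) == 0L) stop("no values to average", call. = FALSE)
  out <- tapply(values, groups, mean)
  if (any(is.na(out) & !(names(out) %in% groups))) {
    stop("empty group(s): ",
         paste(names(out)[is.na(out)], collapse = ", "), call. = FALSE)
  }
  c(out)
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value, computed from the textbook formulas:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)`. With `log_transform = TRUE`
#' the test runs on natural logs of the values (all values must then be
#' positive) -- the usual treatment of ratio-scale quantities such as
#' SAAV/SNV ratios.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @param log_transform Test natural logs of the values.
#' @return List of class `"welch_test"`: `mean_x`, `mean_y`, `var_x`,
#'   `var_y`, `n_x`, `n_y`, `statistic`, `df`, `p_value`. When both groups
#'   have zero variance and equal means, `p_value = 1` by convention.
#' @export
welch_t_test <- function(x, y, log_transform = FALSE) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least two values", call. = FALSE)
  }
  if (log_transform) {
    if (any(x <= 0) || any(y <= 0)) {
      stop("log transform requires strictly positive values", call. = FALSE)
    }
    x <- log(x)
    y <- log(y)
  }
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    res <- list(statistic = 0, df = n1 + n2 - 2,
                p_value = if (m1 == m2) 1 else 0)
  } else {
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    res <- list(statistic = tstat, df = df,
                p_value = 2 * stats::pt(-abs(tstat), df))
  }
  structure(c(list(mean_x = m1, mean_y = m2, var_x = v1, var_y = v2,
                   n_x = n1, n_y = n2), res),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat("Welch two-sample t-test\n")
  cat(sprintf("  t = %.4f, df = %.3f, p = %.4g\n", x$statistic, x$df, x$p_value))
  cat(sprintf("  means: %.4f vs %.4f (n = %d, %d)\n", x$mean_x, x$mean_y,
              x$n_x, x$n_y))
  invisible(x)
}

#' Shannon-Wiener indices for an abundance table
#'
#' @param abundance Matrix or data.frame, samples in rows, taxa in columns,
#'   non-negative entries.
#' @return Named numeric vector of per-sample indices.
#' @export
sample_diversity <- function(abundance) {
  m <- as.matrix(abundance)
  if (any(m < 0, na.rm = TRUE)) stop("negative abundances", call. = FALSE)
  apply(m, 1L, shannon_wiener)
}
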