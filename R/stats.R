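#' Welch's unequal-variance two-sample t-test
#'
#' The unpaired two-sample t-test assuming normal distributions with
#' unknown and unequal variances:
#' `t = (mean(x) - mean(y)) / sqrt(s1^2/n1 + s2^2/n2)`, with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' Used to compare induction-feature distributions (crossing time, maximal
#' rate, peak amplitude, decay half-time) between strains.
#'
#' When both samples have zero variance and equal means, `t = 0` and
#' `p = 1` by convention.
#'
#' @param x,y numeric vectors with at least 2 finite values each.
#' @return Object of class `welch_test`: a list with `t_statistic`, `dof`,
#'   `p_value`, `n1`, `n2`.
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 4, 6))
welch_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("insufficient data: samples must be finite", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    stop("insufficient data: need at least 2 values per sample", call. = FALSE)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    tt <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
    dof <- n1 + n2 - 2
    p <- if (tt == 0) 1 else 0
  } else {
    tt <- (mean(x) - mean(y)) / sqrt(se2)
    dof <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(tt), df = dof)
  }
  structure(list(t_statistic = tt, dof = dof, p_value = p, n1 = n1, n2 = n2),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t = %.4g, df = %.2f, p = %.4g (n = %d, %d)\n",
              x$t_statistic, x$dof, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Replicate mean and standard error of the mean
#'
#' Summaries across biological replicates as conventionally reported:
#' arithmetic mean and `sd/sqrt(n)` with the (n-1)-denominator sample
#' standard deviation.  A single replicate has SEM 0.
#'
#' @param values numeric vector of per-replicate values (>= 1).
#' @return List with `mean` and `sem`.
#' @export
#' @examples
#' replicate_sem(c(0.10, 0.12, 0.14))
replicate_sem <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("insufficient data: need at least 1 value", call. = FALSE)
  if (any(!is.finite(values)))
    stop("insufficient data: values must be finite", call. = FALSE)
  n <- length(values)
  list(mean = mean(values),
       sem = if (n == 1L) 0 else sd(values) / sqrt(n))
}
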