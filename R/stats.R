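#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value, as used for every two-group contrast in the package.
#' Degenerate inputs are resolved explicitly: two constant samples with equal
#' values give `t = 0, p = 1`; a constant-vs-constant difference (or any pair
#' whose pooled standard error is zero) gives `t = +/-Inf, p = 0`.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list of class `welch_test`: `statistic`, `dof`, `p_value`,
#'   `means`, `medians`, `n` (each a length-2 vector, x then y).
#' @export
welch_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_t_test needs at least 2 observations per group", call. = FALSE)
  }
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / length(x) + vy / length(y)
  if (se2 == 0) {
    delta <- mean(x) - mean(y)
    if (delta == 0) {
      statistic <- 0; p <- 1; dof <- length(x) + length(y) - 2
    } else {
      statistic <- sign(delta) * Inf; p <- 0; dof <- NA_real_
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    statistic <- unname(ht$statistic)
    dof <- unname(ht$parameter)
    p <- ht$p.value
  }
  structure(list(statistic = statistic, dof = dof, p_value = p,
                 means = c(mean(x), mean(y)),
                 medians = c(stats::median(x), stats::median(y)),
                 n = c(length(x), length(y))),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.2f, p = %.4g (n = %d, %d)\n",
              x$statistic, x$dof, x$p_value, x$n[1], x$n[2]))
  invisible(x)
}
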