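## Kendall's tau-b with tie correction and normal-approximation p-value,
## used to screen pilot items against resident perception questions.

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected tau-b computed by direct pair counting:
#' \deqn{\tau_b = \frac{C - D}{\sqrt{(n_0 - n_1)(n_0 - n_2)}}}
#' where \eqn{C}/\eqn{D} are concordant/discordant pair counts,
#' \eqn{n_0 = n(n-1)/2} and \eqn{n_1}, \eqn{n_2} are the tie terms of each
#' variable. The p-value uses the normal approximation for \eqn{C - D} with
#' the tie-adjusted variance, two-sided.
#'
#' Pairs with a missing value in either vector are deleted pairwise.
#'
#' @param x,y numeric (or ordered) vectors of equal length; at least 3
#'   complete pairs.
#' @return List with `tau_b`, `p_value`, `n` (complete pairs).
#' @export
kendall_tau_b <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) arg_error("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) arg_error("need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    data_error("correlation undefined: all values tied in x or y")

  C <- 0; D <- 0
  for (i in seq_len(n - 1L)) {
    dx <- x[(i + 1L):n] - x[i]
    dy <- y[(i + 1L):n] - y[i]
    s <- sign(dx) * sign(dy)
    C <- C + sum(s > 0)
    D <- D + sum(s < 0)
  }
  S <- C - D

  t_i <- table(x); u_j <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(t_i * (t_i - 1) / 2)
  n2 <- sum(u_j * (u_j - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))

  ## tie-adjusted variance of S (as in the classical normal approximation)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(t_i * (t_i - 1) * (2 * t_i + 5))
  vu <- sum(u_j * (u_j - 1) * (2 * u_j + 5))
  v1 <- sum(t_i * (t_i - 1)) * sum(u_j * (u_j - 1)) / (2 * n * (n - 1))
  v2 <- sum(t_i * (t_i - 1) * (t_i - 2)) *
        sum(u_j * (u_j - 1) * (u_j - 2)) / (9 * n * (n - 1) * (n - 2))
  v <- (v0 - vt - vu) / 18 + v1 + v2
  z <- S / sqrt(v)
  p <- 2 * pnorm(-abs(z))
  list(tau_b = tau, p_value = p, n = n)
}
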