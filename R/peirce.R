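# Peirce's criterion for outlier rejection, in Gould's iterative
# formulation, with the iteration cap that keeps the number of rejected
# points below half of the sample.

.erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Peirce rejection ratio R(n, k)
#'
#' Solves Gould's fixed-point formulation of Peirce's equations for the
#' maximum allowed ratio of deviation to sample standard deviation when `k`
#' of `n` observations are assumed spurious (with `m` fitted unknowns).
#' All powers are evaluated in log space, so large samples do not overflow.
#'
#' @param n sample size (>= 3).
#' @param k assumed number of outliers (1 <= k < n/2).
#' @param m number of model unknowns (default 1, the mean).
#' @param tol convergence tolerance on R.
#' @param max_iter iteration cap.
#' @return the dimensionless rejection ratio R (> 0).
#' @export
peirce_ratio <- function(n, k, m = 1, tol = 1e-10, max_iter = 1000) {
  if (n < 3) stop("peirce_ratio requires n >= 3")
  if (k < 1 || k >= n / 2) stop("k must satisfy 1 <= k < n/2")
  if (n - m - k <= 0) stop("too many unknowns/outliers for sample size")
  logQn <- k * log(k) + (n - k) * log(n - k) - n * log(n)  # log(Q^n)
  r_new <- 1; r_old <- 0
  for (it in seq_len(max_iter)) {
    # x^2 from the current R estimate
    x2 <- 1 + (n - m - k) / k *
      (1 - exp((2 / (n - m - k)) * (logQn - k * log(r_new))))
    if (is.na(x2)) stop("Peirce iteration diverged for n=", n, ", k=", k)
    if (x2 < 0) { x2 <- 0; break }
    r_old <- r_new
    x <- sqrt(x2)
    r_new <- exp((x2 - 1) / 2) * .erfc(x / sqrt(2))
    if (abs(r_new - r_old) < tol) break
    if (it == max_iter) stop("Peirce iteration did not converge")
  }
  sqrt(x2)
}

#' Identify outliers with Peirce's criterion
#'
#' Ross's iterative procedure: assume k = 1 outliers, compute the rejection
#' threshold `R(n, k) * sigma` (sigma is the standard deviation of the full
#' sample, not a trimmed one), flag points whose deviation from the mean
#' exceeds it, and increase k while more points than assumed are flagged.
#' The flagged set is capped below half of the sample. With
#' `circular = TRUE` deviations are measured on the circle (degrees) about
#' the circular mean.
#'
#' @param values numeric vector (n >= 3).
#' @param circular treat values as angles in degrees.
#' @return an `"rog_outliers"` object: `values`, `flagged` (indices),
#'   `rejection_ratio` (R at the accepting iteration), `deviations`.
#' @export
find_outliers <- function(values, circular = FALSE) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  if (circular) {
    mu <- circular_mean(values)
    dev <- abs(wrap_angle(values - mu))
    sigma <- stats::sd(wrap_angle(values - mu))
  } else {
    dev <- abs(values - mean(values))
    sigma <- stats::sd(values)
  }
  out <- structure(list(values = values, flagged = integer(),
                        rejection_ratio = NA_real_, deviations = dev),
                   class = "rog_outliers")
  if (!is.finite(sigma) || sigma == 0) return(out)
  k_max <- floor((n - 1) / 2)          # keeps |flagged| < n/2
  k <- 1
  repeat {
    R <- peirce_ratio(n, k)
    flagged <- which(dev > R * sigma)
    if (length(flagged) > k && k < k_max) { k <- k + 1; next }
    break
  }
  cap <- ceiling(n / 2) - 1
  if (length(flagged) > cap)
    flagged <- flagged[order(dev[flagged], decreasing = TRUE)][seq_len(cap)]
  out$flagged <- sort(flagged)
  out$rejection_ratio <- R
  out
}

#' @export
print.rog_outliers <- function(x, ...) {
  cat(sprintf("<outliers> %d of %d flagged (R = %.4f)\n", length(x$flagged),
              length(x$values), x$rejection_ratio))
  invisible(x)
}
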