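# Bilinear compartment differential model fitted to trait-fraction time
# series by closed-form least squares, with reconstruction, conservation
# diagnostics, decay fitting, and a synthetic-series generator for
# parameter-recovery tests.
#
# Model: sdot_k = sum_j beta_jk s_j + sum_{i<=j} mu_ijk s_i s_j, i.e. each
# compartment derivative is a linear combination of the m trait fractions
# and their m(m+1)/2 distinct pairwise products.

as_fraction_matrix <- function(ts) {
  if (inherits(ts, "trait_ts")) return(trait_fractions(ts, "six"))
  m <- as.matrix(ts)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

#' Estimate per-tick derivatives of trait fractions
#'
#' Finite-difference derivative of each column. \code{"central"} uses
#' central differences at interior points and one-sided differences at the
#' ends (exact for linear series). \code{"forward"} uses the forward
#' increment \eqn{s_{t+1} - s_t} (repeating the last increment at the final
#' point), which is the exact derivative of the discrete-time birth-death
#' process and of \code{\link{generate_synthetic_series}}.
#'
#' @param ts A \code{trait_ts} (converted to six-group fractions) or a
#'   numeric matrix of fractions, rows = time points.
#' @param method \code{"central"} (default) or \code{"forward"}.
#' @return Matrix of derivative estimates, same dimensions as the input.
#' @export
estimate_derivatives <- function(ts, method = c("central", "forward")) {
  method <- match.arg(method)
  s <- as_fraction_matrix(ts)
  n <- nrow(s)
  if (n < 3) stop("need at least 3 time points")
  d <- matrix(0, n, ncol(s), dimnames = dimnames(s))
  if (method == "central") {
    d[2:(n - 1), ] <- (s[3:n, , drop = FALSE] - s[1:(n - 2), , drop = FALSE]) / 2
    d[1, ] <- s[2, ] - s[1, ]
    d[n, ] <- s[n, ] - s[n - 1, ]
  } else {
    d[1:(n - 1), ] <- s[2:n, , drop = FALSE] - s[1:(n - 1), , drop = FALSE]
    d[n, ] <- d[n - 1, ]
  }
  d
}

design_colnames <- function(traits) {
  m <- length(traits)
  prods <- character(0)
  for (i in seq_len(m))
    for (j in i:m)
      prods <- c(prods, paste0(traits[i], "*", traits[j]))
  c(traits, prods)
}

#' Build the bilinear design matrix F
#'
#' Columns are the m trait fractions followed by the m(m+1)/2 distinct
#' pairwise products \eqn{s_i s_j} (i <= j) in lexicographic (i, j) order.
#'
#' @inheritParams estimate_derivatives
#' @return Numeric matrix with \code{m + m(m+1)/2} named columns.
#' @export
build_design <- function(ts) {
  s <- as_fraction_matrix(ts)
  m <- ncol(s)
  prods <- matrix(0, nrow(s), m * (m + 1) / 2)
  k <- 0
  for (i in seq_len(m))
    for (j in i:m) {
      k <- k + 1
      prods[, k] <- s[, i] * s[, j]
    }
  out <- cbind(s, prods)
  colnames(out) <- design_colnames(colnames(s))
  out
}

#' Closed-form least-squares fit of the bilinear compartment model
#'
#' Solves the normal equations \eqn{A = (F^T F)^{-1} F^T \dot{s}} per
#' target trait via a QR decomposition. If the design is rank deficient
#' the minimum-norm least-squares solution (via SVD pseudo-inverse) is
#' returned with a warning. Rows of A named after the linear columns are
#' the spontaneous (per capita per tick) conversion rates beta; rows named
#' after product columns are the meeting-induced rates mu.
#'
#' @param F Design matrix from \code{\link{build_design}}.
#' @param sdot Matrix of derivative estimates from
#'   \code{\link{estimate_derivatives}} (or a vector for a single trait).
#' @return An object of class \code{rate_estimates}: list with the
#'   coefficient matrix \code{A} (design columns x traits), \code{rank},
#'   and the residual norm per trait.
#' @export
fit_rates <- function(F, sdot) {
  F <- as.matrix(F)
  sdot <- as.matrix(sdot)
  stopifnot(nrow(F) == nrow(sdot))
  qrF <- qr(F)
  if (qrF$rank < ncol(F)) {
    warning("design matrix is rank deficient (rank ", qrF$rank, " < ",
            ncol(F), "); returning the minimum-norm least-squares solution")
    sv <- svd(F)
    pos <- sv$d > max(sv$d) * 1e-12
    A <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% sdot) / sv$d[pos])
  } else {
    A <- qr.coef(qrF, sdot)
  }
  dimnames(A) <- list(colnames(F), colnames(sdot))
  resid <- sdot - F %*% A
  structure(list(A = A, rank = qrF$rank,
                 residual_norm = sqrt(colSums(resid^2))),
            class = "rate_estimates")
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat(sprintf("bilinear compartment fit: %d coefficients x %d traits, rank %d\n",
              nrow(x$A), ncol(x$A), x$rank))
  cat("residual norms:",
      paste(sprintf("%.3g", x$residual_norm), collapse = ", "), "\n")
  invisible(x)
}

rate_matrix <- function(A) if (inherits(A, "rate_estimates")) A$A else as.matrix(A)

#' Predicted derivatives, reconstruction and conservation diagnostics
#'
#' Computes the least-squares predicted derivatives \eqn{E = F A},
#' reconstructs the compartment series by cumulative summation from the
#' initial fractions, and reports how well the total population fraction is
#' conserved: the maximum absolute drift of the compartment sum from its
#' initial value, expressed also as a number of stable decimal places.
#' When the observed fractions sum to 1 at every tick, the derivative rows
#' sum to zero and the predicted derivatives inherit this, so the
#' integrated estimates are conserved; the decimal-place count measures the
#' quality of the fitted model.
#'
#' @param F Design matrix.
#' @param A A \code{rate_estimates} object or coefficient matrix.
#' @param s0 Initial compartment fractions (first row of the series).
#' @param sdot Optional observed derivatives, to report residual
#'   orthogonality and norm.
#' @return An object of class \code{fit_report}: list with \code{E}
#'   (predicted derivatives), \code{reconstructed} (series of the same
#'   length as F's rows), \code{conservation_deviation},
#'   \code{conservation_decimal_places}, and, when \code{sdot} is given,
#'   \code{residual_norm} and \code{max_normal_eq_residual}.
#' @export
reconstruct_and_check <- function(F, A, s0, sdot = NULL) {
  F <- as.matrix(F)
  A <- rate_matrix(A)
  E <- F %*% A
  n <- nrow(F)
  recon <- matrix(0, n, ncol(E))
  recon[1, ] <- s0
  if (n > 1)
    recon[2:n, ] <- matrix(s0, n - 1, ncol(E), byrow = TRUE) +
      apply(E[1:(n - 1), , drop = FALSE], 2, cumsum)
  colnames(recon) <- colnames(E)
  tot <- rowSums(recon)
  dev <- max(abs(tot - tot[1]))
  places <- if (dev == 0) Inf else floor(-log10(dev))
  out <- list(E = E, reconstructed = recon, conservation_deviation = dev,
              conservation_decimal_places = places)
  if (!is.null(sdot)) {
    r <- as.matrix(sdot) - E
    out$residual_norm <- sqrt(colSums(r^2))
    out$max_normal_eq_residual <- max(abs(crossprod(F, r)))
  }
  structure(out, class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit report: conservation deviation %.3g (%s decimal places)\n",
              x$conservation_deviation,
              format(x$conservation_decimal_places)))
  invisible(x)
}

#' Exponential decay rate of a population transient
#'
#' Log-linear least-squares fit of \eqn{s(t) = s_0 e^{-r t}} over a window
#' of a single-trait fraction trace; used to compare decay transients of
#' diffusion episodes against other work on decay in message traffic.
#'
#' @param series Numeric vector of strictly positive fractions.
#' @param window Optional integer index range (e.g. \code{101:400}) into
#'   \code{series}; default the whole series.
#' @return The decay rate r per tick (positive for decaying series).
#' @export
fit_decay <- function(series, window = NULL) {
  if (is.null(window)) window <- seq_along(series)
  s <- series[window]
  if (any(!is.finite(s)) || any(s <= 0))
    stop("decay fitting requires strictly positive values in the window")
  t <- seq_along(s) - 1
  -unname(coef(lm(log(s) ~ t))[2])
}

#' Generate a synthetic trait-fraction series from known rates
#'
#' Forward-Euler integration of the bilinear model
#' \eqn{s_{t+1} = s_t + F(s_t) A}, with optional additive Gaussian
#' observation noise. Used as the recovery oracle for
#' \code{\link{fit_rates}}: with \code{noise_sd = 0}, fitting the forward
#' differences of the output recovers A exactly.
#'
#' @param A Coefficient matrix (design columns x m traits) or
#'   \code{rate_estimates}.
#' @param s0 Initial fractions, summing to 1.
#' @param ticks Number of integration steps.
#' @param noise_sd Observation noise standard deviation (default 0).
#' @return Matrix of fractions, \code{ticks + 1} rows.
#' @export
generate_synthetic_series <- function(A, s0, ticks, noise_sd = 0) {
  A <- rate_matrix(A)
  m <- length(s0)
  stopifnot(nrow(A) == m + m * (m + 1) / 2, ncol(A) == m)
  if (abs(sum(s0) - 1) > 1e-8) stop("s0 must sum to 1")
  traits <- colnames(A)
  if (is.null(traits)) traits <- paste0("s", seq_len(m))
  s <- matrix(0, ticks + 1, m, dimnames = list(NULL, traits))
  s[1, ] <- s0
  for (t in seq_len(ticks)) {
    f <- build_design(s[t, , drop = FALSE])
    s[t + 1, ] <- s[t, ] + as.vector(f %*% A)
    if (any(s[t + 1, ] < -1e-9) || any(s[t + 1, ] > 1 + 1e-9))
      stop("trajectory leaves [0, 1] at tick ", t,
           "; choose smaller rates or a shorter horizon")
  }
  if (noise_sd > 0)
    s <- s + matrix(rnorm(length(s), 0, noise_sd), nrow(s), ncol(s))
  s
}
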