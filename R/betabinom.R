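#' Beta-binomial distribution with mean/overdispersion parameterization
#'
#' Density and random generation for the beta-binomial distribution
#' parameterized by the mean success probability \code{p} and an
#' overdispersion parameter \code{rho} in \code{[0, 1)}:
#' \deqn{\alpha = p(1-\rho)/\rho, \quad \beta = (1-p)(1-\rho)/\rho.}
#' Under this parameterization \eqn{Var(X) = N p (1-p) [1 + (N-1)\rho]},
#' and \code{rho = 0} degenerates exactly to the binomial distribution.
#' This is the single parameterization used throughout the package, both
#' for simulating allele-depth data and for the mosaic-detection model.
#'
#' @param x vector of observed successes (alt read counts).
#' @param size vector of trials (site depths N).
#' @param p mean success probability (variant allele fraction).
#' @param rho overdispersion in \code{[0, 1)}; 0 gives the binomial.
#' @param log logical; return log density?
#' @return \code{dbetabinom}: (log) density; \code{rbetabinom}: integer draws.
#' @examples
#' dbetabinom(5, 10, 0.5, 0)      # equals dbinom(5, 10, 0.5)
#' rbetabinom(3, 100, 0.5, 0.05)
#' @export
dbetabinom <- function(x, size, p, rho, log = FALSE) {
  stopifnot(all(rho >= 0), all(rho < 1), all(p > 0), all(p < 1))
  n <- max(length(x), length(size), length(p), length(rho))
  x <- rep_len(x, n); size <- rep_len(size, n)
  p <- rep_len(p, n); rho <- rep_len(rho, n)
  out <- numeric(n)
  bin <- rho == 0
  if (any(bin)) {
    out[bin] <- stats::dbinom(x[bin], size[bin], p[bin], log = TRUE)
  }
  if (any(!bin)) {
    a <- p[!bin] * (1 - rho[!bin]) / rho[!bin]
    b <- (1 - p[!bin]) * (1 - rho[!bin]) / rho[!bin]
    out[!bin] <- lchoose(size[!bin], x[!bin]) +
      lbeta(x[!bin] + a, size[!bin] - x[!bin] + b) - lbeta(a, b)
  }
  bad <- x < 0 | x > size | x != round(x)
  out[bad] <- -Inf
  if (log) out else exp(out)
}

#' @rdname dbetabinom
#' @param n number of draws.
#' @export
rbetabinom <- function(n, size, p, rho) {
  stopifnot(all(rho >= 0), all(rho < 1))
  size <- rep_len(size, n); p <- rep_len(p, n); rho <- rep_len(rho, n)
  pr <- p
  od <- rho > 0
  if (any(od)) {
    a <- p[od] * (1 - rho[od]) / rho[od]
    b <- (1 - p[od]) * (1 - rho[od]) / rho[od]
    pr[od] <- stats::rbeta(sum(od), a, b)
  }
  stats::rbinom(n, size, pr)
}

# numerically stable log(mean(exp(x))) along rows of a matrix
.log_mean_exp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  fin <- is.finite(mx)
  out <- rep(-Inf, nrow(m))
  if (any(fin)) {
    out[fin] <- mx[fin] + log(rowMeans(exp(m[fin, , drop = FALSE] - mx[fin])))
  }
  out
}
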