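#' Negative binomial (NB2) negative log-likelihood
#'
#' Exact NB2 log-likelihood with mean `mu` and dispersion `theta`
#' (variance `mu + mu^2/theta`), negated. Used as the fitting target in the
#' brute-force optimizer that cross-checks the penalized IRLS fits.
#'
#' @param y nonnegative integer counts.
#' @param mu positive means (recycled).
#' @param theta positive dispersion; `theta -> Inf` approaches Poisson.
#' @return scalar negative log-likelihood.
#' @export
nb_neg_loglik <- function(y, mu, theta) {
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("NB response must be nonnegative integers")
  if (any(mu <= 0) || theta <= 0) stop("mu and theta must be positive")
  -sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
         theta * log(theta) + y * log(mu) - (theta + y) * log(theta + mu))
}

#' Tweedie compound Poisson-gamma density
#'
#' Density of the Tweedie family with power parameter `1 < p < 2` (point
#' mass at zero plus continuous positive part), evaluated with the
#' Dunn-Smyth series expansion. The series is summed in log space outward
#' from its largest term until terms fall 37 log-units below the maximum,
#' giving ~1e-15 relative truncation error.
#'
#' @param y nonnegative values.
#' @param mu positive mean.
#' @param p power parameter in (1, 2).
#' @param phi positive scale; variance is `phi * mu^p`.
#' @param log return log density?
#' @return vector of (log) densities.
#' @export
dtweedie_cpg <- function(y, mu, p, phi, log = FALSE) {
  if (p <= 1 || p >= 2) stop("power p must lie in (1, 2)")
  if (any(mu <= 0) || any(phi <= 0)) stop("mu and phi must be positive")
  if (any(y < 0)) stop("y must be nonnegative")
  n <- max(length(y), length(mu), length(phi))
  y <- rep_len(y, n); mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  alpha <- (2 - p) / (p - 1)
  # exponential-family part: theta = mu^(1-p)/(1-p), kappa = mu^(2-p)/(2-p)
  ll <- (y * mu^(1 - p) / (1 - p) - mu^(2 - p) / (2 - p)) / phi
  pos <- y > 0
  if (any(pos)) {
    ll[pos] <- ll[pos] + vapply(which(pos), function(i) {
      .tweedie_log_w(y[i], phi[i], p, alpha) - base::log(y[i])
    }, 0)
  }
  if (log) ll else exp(ll)
}

# log sum_{j>=1} W_j of the Dunn-Smyth series at one point
.tweedie_log_w <- function(y, phi, p, alpha) {
  logz <- alpha * base::log(y) - alpha * base::log(p - 1) -
    base::log(2 - p) - (1 + alpha) * base::log(phi)
  logw_at <- function(j) j * logz - lgamma(j + 1) - lgamma(j * alpha)
  jmax <- max(1, y^(2 - p) / ((2 - p) * phi))
  j0 <- max(1L, floor(jmax))
  lw0 <- logw_at(j0)
  drop <- 37
  # expand upward
  js <- j0; lws <- lw0
  j <- j0
  repeat {
    j <- j + 1L
    lw <- logw_at(j)
    js <- c(js, j); lws <- c(lws, lw)
    if (lw < max(lws) - drop) break
    if (j > j0 + 100000L) break
  }
  # expand downward
  j <- j0
  while (j > 1L) {
    j <- j - 1L
    lw <- logw_at(j)
    js <- c(js, j); lws <- c(lws, lw)
    if (lw < max(lws) - drop) break
  }
  m <- max(lws)
  m + base::log(sum(exp(lws - m)))
}

#' Tweedie negative log-likelihood
#'
#' @param y nonnegative values.
#' @param mu positive means.
#' @param p power in (1, 2).
#' @param phi positive scale.
#' @return scalar negative log-likelihood.
#' @export
tweedie_neg_loglik <- function(y, mu, p, phi) {
  -sum(dtweedie_cpg(y, mu, p, phi, log = TRUE))
}

#' Family specification for count GAMs
#'
#' @param kind `"nb"` (negative binomial, theta estimated by REML unless
#'   given) or `"tweedie"` (power profiled over a REML grid unless given).
#' @param theta optional fixed NB dispersion.
#' @param p optional fixed Tweedie power in (1, 2).
#' @return object of class `"dsm_family"`.
#' @export
dsm_family <- function(kind = c("nb", "tweedie"), theta = NULL, p = NULL) {
  kind <- match.arg(kind)
  if (!is.null(theta) && theta <= 0) stop("theta must be positive")
  if (!is.null(p) && (p <= 1 || p >= 2)) stop("p must lie in (1, 2)")
  structure(list(kind = kind, theta = theta, p = p), class = "dsm_family")
}
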