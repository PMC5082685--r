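#' Deviance residuals of a fitted count GAM
#'
#' Signed square roots of the per-segment deviance contributions; their
#' squares sum exactly to the model deviance.
#'
#' @param fit a `"dsm_fit"`.
#' @return numeric vector, one residual per (retained) segment.
#' @export
deviance_residuals <- function(fit) {
  stopifnot(inherits(fit, "dsm_fit"))
  stats::residuals(fit$gam, type = "deviance")
}

#' Within-transect residual autocorrelation (correlogram)
#'
#' Lag-k correlation of deviance residuals between segments k apart within
#' the same transect; pairs never cross transects. The 95% confidence band
#' half-width at each lag is `z / sqrt(n_pairs)`.
#'
#' @param residuals numeric residual vector.
#' @param transect_id transect identifier per residual.
#' @param seg_index within-transect segment order per residual.
#' @param max_lag largest lag (default 10); truncated with a warning when it
#'   reaches the longest transect.
#' @param z band quantile (default 1.96).
#' @return data.frame of class `"correlogram"`: lag, correlation, n_pairs,
#'   band.
#' @export
residual_lag_correlation <- function(residuals, transect_id, seg_index,
                                     max_lag = 10, z = 1.96) {
  stopifnot(length(residuals) == length(transect_id),
            length(residuals) == length(seg_index))
  longest <- max(tapply(seg_index, transect_id, length))
  if (max_lag >= longest) {
    warning("max_lag ", max_lag, " >= longest transect (", longest,
            " segments); truncating")
    max_lag <- longest - 1
  }
  mu <- mean(residuals); s2 <- stats::var(residuals)
  out <- lapply(seq_len(max_lag), function(lag) {
    a <- c(); b <- c()
    for (tr in unique(transect_id)) {
      i <- which(transect_id == tr)
      i <- i[order(seg_index[i])]
      if (length(i) > lag) {
        a <- c(a, residuals[i[seq_len(length(i) - lag)]])
        b <- c(b, residuals[i[-seq_len(lag)]])
      }
    }
    n <- length(a)
    r <- if (n >= 2) sum((a - mu) * (b - mu)) / ((n - 1) * s2) else NA_real_
    data.frame(lag = lag, correlation = r, n_pairs = n,
               band = if (n > 0) z / sqrt(n) else NA_real_)
  })
  structure(do.call(rbind, out), class = c("correlogram", "data.frame"))
}

#' Basis-dimension adequacy check (k-index)
#'
#' For each univariate smooth, the k-index is the ratio of the mean squared
#' difference between residuals at neighbouring covariate values to the
#' residual variance; values substantially below 1 indicate unmodelled
#' structure at the basis resolution. A randomization p-value is computed by
#' shuffling residuals (seeded, reproducible).
#'
#' @param fit a `"dsm_fit"`.
#' @param n_shuffle randomization replicates (default 200).
#' @param seed RNG seed.
#' @return data.frame: term, k, edf, k_index, p_value, flagged.
#' @export
basis_dim_check <- function(fit, n_shuffle = 200, seed = 1) {
  stopifnot(inherits(fit, "dsm_fit"))
  g <- fit$gam
  r <- stats::residuals(g, type = "deviance")
  v <- stats::var(r)
  if (!is.finite(v) || v == 0) {
    warning("constant residuals; basis check skipped")
    return(data.frame(term = character(0), k = numeric(0), edf = numeric(0),
                      k_index = numeric(0), p_value = numeric(0),
                      flagged = logical(0)))
  }
  kidx <- function(res, ord) {
    d <- diff(res[ord])
    mean(d^2) / (2 * stats::var(res))
  }
  set.seed(seed)
  out <- lapply(seq_along(g$smooth), function(i) {
    sm <- g$smooth[[i]]
    if (length(sm$term) != 1) {
      return(data.frame(term = sm$label, k = sm$bs.dim, edf = fit$edf[i],
                        k_index = NA_real_, p_value = NA_real_,
                        flagged = FALSE))
    }
    x <- g$model[[sm$term]]
    ord <- order(x)
    ki <- kidx(r, ord)
    null_ki <- vapply(seq_len(n_shuffle), function(b) {
      kidx(sample(r), ord)
    }, 0)
    pv <- mean(null_ki <= ki)
    data.frame(term = sm$label, k = sm$bs.dim, edf = fit$edf[i],
               k_index = ki, p_value = pv,
               flagged = ki < 1 && pv < 0.05, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Full diagnostics report for a fitted model
#'
#' @param fit a `"dsm_fit"`.
#' @param segments the segment data used for fitting (for transect ordering).
#' @param max_lag correlogram maximum lag.
#' @param seed randomization seed for the basis check.
#' @return list: `residuals`, `correlogram`, `k_check`.
#' @export
diagnose_fit <- function(fit, segments, max_lag = 10, seed = 1) {
  r <- deviance_residuals(fit)
  used <- as.integer(rownames(fit$gam$model))
  if (length(used) != length(r) || anyNA(used)) used <- seq_len(length(r))
  segs <- segments[used, , drop = FALSE]
  cg <- residual_lag_correlation(r, segs$transect_id, segs$seg_index,
                                 max_lag = max_lag)
  list(residuals = r, correlogram = cg,
       k_check = basis_dim_check(fit, seed = seed))
}
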