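test_that("cubic basis penalty matches the quadrature oracle", {
  set.seed(8)
  x <- sort(runif(80, 0, 10))
  b <- build_cubic_basis(x, k = 8, absorb_constraint = FALSE)
  # coefficients are function values at the knots of a natural cubic spline;
  # f'' is piecewise linear, so int f''^2 has the exact piecewise form
  beta <- rnorm(8)
  f <- stats::splinefun(b$knots, beta, method = "natural")
  d2 <- f(b$knots, deriv = 2)
  h <- diff(b$knots)
  exact <- sum(h / 3 * (d2[-8]^2 + d2[-8] * d2[-1] + d2[-1]^2))
  expect_equal(drop(beta %*% b$S %*% beta), exact, tolerance = 1e-6)

  # linear functions are in the penalty null space
  beta_lin <- 2 + 3 * b$knots
  expect_lt(drop(beta_lin %*% b$S %*% beta_lin), 1e-8)

  expect_warning(build_cubic_basis(rep(1:4, 5), k = 10), "reducing k")
  expect_error(build_cubic_basis(1:10, k = 2), "at least 3")
})

test_that("intercept-only Poisson-limit fit equals the closed form", {
  segs <- toy_segments()
  fit <- fit_gam(count ~ 1, segs, family = dsm_family("nb", theta = 1e7))
  expect_equal(unname(exp(fit$coefficients[1])),
               sum(segs$count) / sum(segs$area), tolerance = 1e-6)
  expect_equal(fit$dev_expl, 0)
})

test_that("PIRLS matches brute-force penalized-likelihood optimization", {
  # fixed lambda and theta: deviance + lambda b'Sb minimized directly
  segs <- toy_segments(60)
  th <- 1.5; lam <- 2
  fit <- fit_gam(count ~ s(x, bs = "cr", k = 6), segs,
                 family = dsm_family("nb", theta = th), sp = lam)
  g <- fit$gam
  X <- stats::predict(g, type = "lpmatrix")
  sm <- g$smooth[[1]]
  S <- matrix(0, ncol(X), ncol(X))
  S[sm$first.para:sm$last.para, sm$first.para:sm$last.para] <- sm$S[[1]]
  off <- log(segs$area)
  pen_dev <- function(beta) {
    mu <- exp(X %*% beta + off)
    2 * (nb_neg_loglik(segs$count, mu, th) -
           nb_neg_loglik(segs$count, pmax(segs$count, 1e-8), th)) +
      lam * drop(beta %*% S %*% beta)
  }
  o <- stats::optim(rep(0, ncol(X)), pen_dev, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-14))
  expect_equal(o$par, unname(fit$coefficients), tolerance = 1e-4)

  # same cross-check for a Tweedie fit at fixed p
  segsT <- segs; segsT$count <- segs$count + 0.0
  fitT <- fit_gam(count ~ s(x, bs = "cr", k = 6), segsT,
                  family = dsm_family("tweedie", p = 1.4), sp = lam)
  phi <- fitT$phi
  XT <- stats::predict(fitT$gam, type = "lpmatrix")
  # 2*phi*nll equals the Tweedie deviance up to a beta-free constant, so this
  # is the penalized deviance the inner PIRLS loop minimizes at fixed sp
  pen_devT <- function(beta) {
    mu <- exp(XT %*% beta + off)
    2 * phi * tweedie_neg_loglik(segsT$count, mu, 1.4, phi) +
      lam * drop(beta %*% S %*% beta)
  }
  oT <- stats::optim(unname(fitT$coefficients) * 0, pen_devT, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14))
  expect_equal(oT$par, unname(fitT$coefficients), tolerance = 1e-4)
})

test_that("EDF behaves at the penalty extremes and satisfies the trace identity", {
  segs <- toy_segments(80)
  # lambda -> infinity: cubic smooth collapses to a line, term EDF -> 1
  fit_inf <- fit_gam(count ~ s(x, bs = "cr", k = 8), segs,
                     family = dsm_family("nb", theta = 2), sp = 1e12)
  expect_equal(unname(fit_inf$edf[1]), 1, tolerance = 1e-3)
  # lambda -> 0: EDF equals the number of identifiable coefficients
  fit0 <- fit_gam(count ~ s(x, bs = "cr", k = 8), segs,
                  family = dsm_family("nb", theta = 2), sp = 0)
  expect_equal(fit0$total_edf, 8, tolerance = 1e-6)

  # trace identity computed from first principles
  fit <- fit_gam(count ~ s(x, bs = "cr", k = 6), segs,
                 family = dsm_family("nb", theta = 2), sp = 0.7)
  g <- fit$gam
  X <- stats::predict(g, type = "lpmatrix")
  W <- diag(g$weights)
  sm <- g$smooth[[1]]
  S <- matrix(0, ncol(X), ncol(X))
  S[sm$first.para:sm$last.para, sm$first.para:sm$last.para] <- sm$S[[1]]
  XtWX <- t(X) %*% W %*% X
  Fmat <- solve(XtWX + 0.7 * S, XtWX)
  e <- edf(fit)
  expect_equal(sum(diag(Fmat)), e$total, tolerance = 1e-6)
  expect_equal(sum(diag(Fmat)[sm$first.para:sm$last.para]),
               unname(e$per_term[1]), tolerance = 1e-6)
  expect_equal(e$parametric + sum(e$per_term), e$total, tolerance = 1e-8)
})

test_that("approximate p-values match an independent pseudo-inverse routine", {
  segs <- toy_segments(80)
  fit <- fit_gam(count ~ s(x, bs = "cr", k = 6), segs,
                 family = dsm_family("nb", theta = 2))
  pv <- approx_pvalue(fit, "s(x)")
  # separate routine: SVD-based rank-r pseudo-inverse on the fitted-value
  # scale (svd of the scaled term design replaces the QR route)
  sm <- fit$gam$smooth[[1]]
  cols <- sm$first.para:sm$last.para
  b <- fit$coefficients[cols]
  V <- fit$Vb[cols, cols]
  r <- max(1, round(fit$edf[1]))
  Xt <- stats::predict(fit$gam, type = "lpmatrix")[, cols]
  sx <- svd(Xt / sqrt(nrow(Xt)))
  R2 <- diag(sx$d) %*% t(sx$v)
  bt <- drop(R2 %*% b)
  Vt <- R2 %*% V %*% t(R2)
  sv <- svd((Vt + t(Vt)) / 2)
  Vinv <- sv$u[, 1:r, drop = FALSE] %*%
    diag(1 / sv$d[1:r], r) %*% t(sv$v[, 1:r, drop = FALSE])
  stat <- drop(bt %*% Vinv %*% bt)
  expect_equal(pv$statistic, stat, tolerance = 1e-10)
  expect_equal(pv$p_value, stats::pchisq(stat, r, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(approx_pvalue(fit, "s(depth)"), "not in model")
})

test_that("fit summaries are arithmetic identities of the deviances", {
  segs <- toy_segments(60)
  fit <- fit_gam(count ~ s(x, bs = "cr", k = 5), segs,
                 family = dsm_family("nb", theta = 2))
  s <- fit_summaries(fit)
  expect_equal(s$dev_expl, 100 * (1 - s$deviance / s$null_deviance))
  expect_true(s$dev_expl >= 0 && s$dev_expl <= 100)
})

test_that("Tweedie power is profiled over the REML grid", {
  fx <- scenario_fixture("shelf", 11)
  segs <- fx$segs
  fit <- suppressMessages(
    fit_gam(count ~ s(depth, bs = "cr", k = 5), segs,
            family = dsm_family("tweedie"),
            p_grid = c(1.2, 1.5, 1.8)))
  expect_true(fit$p %in% c(1.2, 1.5, 1.8))
  expect_equal(nrow(fit$p_profile), 3)
  expect_equal(fit$p, fit$p_profile$p[which.min(fit$p_profile$reml)])
  expect_true(all(diff(fit$p_profile$reml) != 0))
})

test_that("degenerate inputs are rejected", {
  segs <- toy_segments(30)
  segs$count <- 0
  expect_error(fit_gam(count ~ 1, segs, dsm_family("nb")), "all-zero")
  segs2 <- toy_segments(30); segs2$area <- NULL
  expect_error(fit_gam(count ~ 1, segs2, dsm_family("nb")), "offset")
  segs3 <- toy_segments(30); segs3$count <- segs3$count + 0.5
  expect_error(fit_gam(count ~ 1, segs3, dsm_family("nb")), "integer")
})
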