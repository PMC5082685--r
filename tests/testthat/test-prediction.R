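test_that("prediction grids tile the region and honour the coastal cap", {
  sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  g <- build_grid(sq, 100)
  expect_equal(nrow(g), 100)
  expect_equal(g$area, rep(100, 100))

  # cap: keep cells within 30 km of the western edge; brute-force check
  coast <- cbind(0, seq(0, 100, by = 5))
  g2 <- build_grid(sq, 100, coastline = coast, max_coast_distance = 30)
  brute <- g$cx <= 30
  expect_equal(nrow(g2), sum(brute))
  expect_setequal(paste(g2$cx, g2$cy), paste(g$cx[brute], g$cy[brute]))

  tiny <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))
  g3 <- build_grid(tiny, 100)
  expect_equal(nrow(g3), 1)   # degenerate region, centroid inside -> 1 cell
  # concave L-shape whose bounding-box centre falls in the notch -> no cell
  ell <- rbind(c(0, 0), c(4, 0), c(4, 4), c(3, 4), c(3, 1), c(0, 1))
  expect_error(build_grid(ell, 100), "empty")
})

test_that("seasonal dynamic-covariate averages skip missing months", {
  g <- data.frame(cell_id = 1:4, cx = c(5, 15, 5, 15), cy = c(5, 5, 15, 15),
                  area = 100)
  mk <- function(v) ascii_grid(matrix(v, 2, 2), 0, 0, 10)
  dyn <- list(sst = list("2013-01" = mk(10), "2013-02" = mk(10)))
  a <- average_dynamic_covariates(g, dyn, months = 1:2)
  expect_equal(a$sst, rep(10, 4))
  # one month missing in one cell: mean over available months
  v1 <- matrix(8, 2, 2); v2 <- matrix(12, 2, 2); v2[2, 1] <- NA
  dyn2 <- list(sst = list("2013-01" = ascii_grid(v1, 0, 0, 10),
                          "2013-02" = ascii_grid(v2, 0, 0, 10)))
  a2 <- average_dynamic_covariates(g, dyn2, months = 1:2)
  expect_equal(a2$sst[1], 8)        # cell (5,5): bottom-left, Feb missing
  expect_equal(a2$sst[2:4], rep(10, 3))
})

test_that("abundance prediction obeys its closed forms", {
  segs <- toy_segments()
  fit <- fit_gam(count ~ 1, segs, family = dsm_family("nb", theta = 1e7))
  grid <- data.frame(cell_id = 1:50, cx = runif(50), cy = runif(50),
                     area = 100)
  surf <- predict_abundance(fit, grid)
  b0 <- unname(fit$coefficients[1])
  expect_equal(surf$N, rep(100 * exp(b0), 50), tolerance = 1e-10)
  expect_equal(attr(surf, "total"), sum(surf$N), tolerance = 1e-12)
  # doubling all areas doubles the total (offset linearity)
  grid2 <- grid; grid2$area <- 200
  expect_equal(attr(predict_abundance(fit, grid2), "total"),
               2 * attr(surf, "total"), tolerance = 1e-12)
})

test_that("delta-method uncertainty agrees with posterior simulation", {
  segs <- toy_segments(80)
  fit <- fit_gam(count ~ s(x, bs = "cr", k = 5), segs,
                 family = dsm_family("nb", theta = 2))
  grid <- data.frame(cell_id = 1:40, x = seq(-0.9, 0.9, length.out = 40),
                     cx = 0, cy = 0, area = 25)
  del <- abundance_variance(fit, grid)
  sim <- abundance_variance(fit, grid, method = "simulation", B = 30000,
                            seed = 99)
  expect_equal(del$total$N, sim$total$N, tolerance = 1e-9)
  expect_lt(abs(sim$total$se / del$total$se - 1), 0.05)
  expect_lt(max(abs(sim$cells$se / del$cells$se - 1)), 0.15)
  expect_equal(del$total$cv, del$total$se / del$total$N)

  # zero coefficient covariance -> zero uncertainty
  fit0 <- fit
  fit0$Vb <- fit$Vb * 0
  fit0$Vc <- fit$Vc * 0
  z <- abundance_variance(fit0, grid)
  expect_equal(z$total$se, 0)
  expect_equal(z$cells$se, rep(0, 40))

  # bilinearity: total variance from summed per-cell gradients
  lp <- stats::predict(fit$gam, newdata = grid, type = "lpmatrix")
  Ncell <- grid$area * exp(drop(lp %*% fit$coefficients))
  a <- colSums(lp * Ncell)
  expect_equal(del$total$se^2, drop(a %*% fit$Vc %*% a), tolerance = 1e-9)
  # the corrected covariance never understates the posterior one
  del_p <- abundance_variance(fit, grid, covariance = "posterior")
  expect_gte(del$total$se, del_p$total$se * (1 - 1e-8))
})

test_that("multi-period combination sums covariances correctly", {
  segs <- toy_segments(80)
  fit <- fit_gam(count ~ s(x, bs = "cr", k = 5), segs,
                 family = dsm_family("nb", theta = 2))
  grid <- data.frame(cell_id = 1:30, x = seq(-0.9, 0.9, length.out = 30),
                     area = 25)
  # identical periods are perfectly correlated: var(mean) = var(single)
  cp <- combine_periods(fit, list(a = grid, b = grid, c = grid))
  single <- combine_periods(fit, list(a = grid))
  expect_equal(cp$N, single$N, tolerance = 1e-12)
  expect_equal(cp$se, single$se, tolerance = 1e-9)
  # sum mode: var = sum of all covariance entries
  cps <- combine_periods(fit, list(a = grid, b = grid), mode = "sum")
  expect_equal(cps$se^2, sum(cps$cov_matrix), tolerance = 1e-9)
  expect_equal(cps$N, sum(cps$per_period))
  # independence identity on an artificial block-diagonal covariance
  Cov <- cps$cov_matrix
  var_indep <- sum(diag(Cov))
  expect_equal(var_indep, Cov[1, 1] + Cov[2, 2])
  # delta-method mean vs posterior simulation across periods
  grid2 <- grid; grid2$x <- grid$x * 0.5
  cpm <- combine_periods(fit, list(a = grid, b = grid2), mode = "mean")
  sim <- abundance_variance(fit, list(a = grid, b = grid2),
                            combine = "mean", method = "simulation",
                            B = 30000, seed = 5)
  expect_lt(abs(sim$total$se / cpm$se - 1), 0.05)
  expect_error(combine_periods(fit, list()), "")
})

test_that("lognormal intervals match the worked example and identities", {
  # printed abundance 21,933 with CV 74% -> printed CI 6,013-80,012
  ci <- lognormal_ci(21933, 0.74)
  expect_lt(abs(ci[["lo"]] / 6013 - 1), 0.005)
  expect_lt(abs(ci[["hi"]] / 80012 - 1), 0.005)
  expect_equal(unname(lognormal_ci(100, 0)), c(100, 100))
  ci2 <- lognormal_ci(5000, 0.3)
  expect_equal(ci2[["hi"]] / 5000, 5000 / ci2[["lo"]], tolerance = 1e-12)
  expect_error(lognormal_ci(-1, 0.5))
})

test_that("per-cell CV grows away from surveyed effort", {
  cf <- coastal_fit_fixture()
  av <- abundance_variance(cf$fit, cf$grid)
  ok <- !is.na(av$cells$cv) & is.finite(av$cells$cv)
  dc <- cf$grid$dist_coast[ok]
  cv <- av$cells$cv[ok]
  bins <- cut(dc, breaks = c(0, 25, 60, 120, Inf))
  mcv <- tapply(cv, bins, median)
  # effort concentrates where animals are (coastal); uncertainty rises offshore
  expect_true(all(diff(mcv) > 0))
})
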