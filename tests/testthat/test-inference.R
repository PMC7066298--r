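# Composite likelihood, the simplex optimizer, the multi-round fitting
# protocol, AIC comparison and residuals.

test_that("theta_hat is the unmasked mass ratio and absorbs model scale", {
  set.seed(4)
  m <- jafs(matrix(rexp(24), 6, 4), kind = "expected")
  d <- jafs(2 * m$values)
  sl <- scaled_poisson_loglik(m, d)
  expect_equal(sl$theta_hat, 2, tolerance = 1e-12)
  m10 <- jafs(10 * m$values, kind = "expected")
  expect_equal(scaled_poisson_loglik(m10, d)$loglik, sl$loglik,
               tolerance = 1e-9)
})

test_that("the composite log-likelihood matches direct Poisson sums", {
  D <- jafs(matrix(c(0, 1, 3, 2), 2, 2))
  M <- jafs(matrix(c(0.5, 0.5, 1.5, 0.5), 2, 2), kind = "expected")
  sl <- scaled_poisson_loglik(M, D)
  u <- !M$mask
  th <- sum(D$values[u]) / sum(M$values[u])
  expect_equal(sl$theta_hat, 2, tolerance = 1e-12)
  expect_equal(sl$loglik,
               sum(dpois(D$values[u], th * M$values[u], log = TRUE)),
               tolerance = 1e-12)
  # zero model expectation with positive data is impossible
  M0 <- M; M0$values[1, 2] <- 0
  expect_identical(scaled_poisson_loglik(M0, D)$loglik, -Inf)
  expect_error(scaled_poisson_loglik(M, jafs(matrix(1, 3, 3))), "shape")
})

test_that("parameter perturbation respects fold range, bounds and seed", {
  p <- param_vector("IM", nu1 = 1, nu2 = 2, m12 = 0.5, m21 = 5, T_S = 1)
  expect_equal(as.numeric(perturb_params(p, fold = 0, seed = 3)),
               as.numeric(p))
  b <- default_bounds(p)
  for (s in 1:20) {
    q <- perturb_params(p, fold = 3, seed = s)
    expect_true(all(as.numeric(q) >= pmax(as.numeric(p) / 8, b$lower)))
    expect_true(all(as.numeric(q) <= pmin(as.numeric(p) * 8, b$upper)))
  }
  expect_identical(perturb_params(p, 2, seed = 9),
                   perturb_params(p, 2, seed = 9))
})

test_that("the simplex minimizer solves smooth problems", {
  quad <- function(x) (x[1] - 2)^2 + (x[2] + 1)^2
  res <- nelder_mead_minimize(quad, c(1, 1), max_iterations = 500,
                              tol = 1e-12)
  expect_equal(res$par, c(2, -1), tolerance = 1e-4)
  res0 <- nelder_mead_minimize(quad, c(1, 1), max_iterations = 0)
  expect_equal(res0$par, c(1, 1))
  expect_equal(res0$value, quad(c(1, 1)))
  expect_error(nelder_mead_minimize(function(x) NaN, c(1, 1)), "finite")
})

test_that("the simplex matches a reference implementation on Rosenbrock", {
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  mine <- nelder_mead_minimize(rosen, c(-1, 1), max_iterations = 2000,
                               tol = 1e-12)
  ref <- optim(c(-1, 1), rosen, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  expect_equal(mine$par, c(1, 1), tolerance = 1e-3)
  expect_equal(ref$par, c(1, 1), tolerance = 1e-3)
  expect_equal(mine$value, ref$value, tolerance = 1e-4)
})

test_that("bound clipping keeps iterates inside the box", {
  f <- function(x) sum((x - 5)^2)
  res <- nelder_mead_minimize(f, c(1, 1), max_iterations = 300,
                              lower = c(0, 0), upper = c(2, 2))
  expect_equal(res$par, c(2, 2), tolerance = 1e-5)
})

sim_jafs_for_fit <- function(p, n_loci, dip, seed) {
  sim <- simulate_divergence_dataset(p, n_loci, dip, seed = seed)
  g <- polarize_and_filter(sim$genotypes, "outgroup")
  build_jafs(g, "pop1", "pop2", 2 * dip[1], 2 * dip[2])
}

test_that("fit_model is reproducible, monotone across rounds and beats
           random parameter draws", {
  truth <- param_vector("IM", nu1 = 1.5, nu2 = 0.8, m12 = 2, m21 = 0.5,
                        T_S = 1)
  d <- sim_jafs_for_fit(truth, 800, c(4L, 4L), seed = 51)
  cfg <- fit_config(rounds = 2, replicates = 3, maxiter = 25,
                    n_genealogies = 1500, seed = 6)
  f1 <- fit_model(d, "IM", cfg)
  f2 <- fit_model(d, "IM", cfg)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(as.numeric(f1$best_params), as.numeric(f2$best_params))
  expect_equal(f1$aic, 2 * 5 - 2 * f1$loglik, tolerance = 1e-12)
  lls <- lapply(f1$round_log, function(r)
    vapply(r, `[[`, numeric(1), "loglik"))
  expect_gte(f1$loglik, max(lls[[1]]) - 1e-9)   # overall best is best
  expect_gte(max(lls[[2]]), max(lls[[1]]) - 1e-9)  # refinement round
  # optimality spot-check against random draws from the bounds
  obj <- divcoal:::make_objective(d, "IM", cfg)
  set.seed(99)
  rand_ll <- replicate(50, -obj(runif(5, -2, 1)))
  expect_true(all(f1$loglik >= rand_ll))
})

test_that("fit results serialize to JSON and back", {
  truth <- param_vector("SI", nu1 = 1, nu2 = 1, T_S = 1)
  d <- sim_jafs_for_fit(truth, 300, c(3L, 3L), seed = 52)
  f <- fit_model(d, "SI", fit_config(rounds = 1, replicates = 2,
                                     maxiter = 10, n_genealogies = 500,
                                     seed = 2))
  path <- tempfile(fileext = ".json")
  write_fit(f, path)
  r <- read_fit(path)
  expect_equal(r$model_id, "SI")
  expect_equal(as.numeric(r$best_params), as.numeric(f$best_params),
               tolerance = 1e-12)
  expect_equal(r$loglik, f$loglik, tolerance = 1e-12)
  expect_equal(r$aic, f$aic, tolerance = 1e-12)
})

test_that("compare_models sorts by AIC with smaller k breaking ties", {
  fits <- list(list(model_id = "IM", loglik = -100),
               list(model_id = "AM", loglik = -100),
               list(model_id = "SI", loglik = -120))
  tab <- compare_models(fits)
  expect_equal(tab$model, c("IM", "AM", "SI"))
  expect_equal(tab$AIC, c(210, 212, 246))
  # equal AIC (AM: 2*6+200, IM: 2*5+202): smaller k first
  fits2 <- list(list(model_id = "AM", loglik = -100),
                list(model_id = "IM", loglik = -101))
  tab2 <- compare_models(fits2)
  expect_equal(tab2$AIC, c(212, 212))
  expect_equal(tab2$model[1], "IM")
  expect_true(all(c("model", "loglik", "AIC", "theta", "nu1", "m12",
                    "T_SC", "P") %in% names(tab)))
})

test_that("residual grids are Pearson residuals with flagged corners", {
  m <- jafs(matrix(1, 3, 3), kind = "expected")
  d <- jafs(matrix(2, 3, 3))
  r0 <- residual_grid(m, d)  # theta_hat = 2 rescales exactly
  expect_true(all(abs(r0$residuals[!r0$mask]) < 1e-12))
  expect_true(all(is.na(r0$residuals[r0$mask])))
  d2 <- jafs(matrix(c(1, 4, 1, 1, 1, 1, 1, 1, 1), 3, 3))
  r1 <- residual_grid(m, d2, theta = 1)
  expect_equal(r1$residuals[2, 1], 3)  # D=4, theta*M=1 -> (4-1)/1
  expect_true(r1$mask[1, 1] && r1$mask[3, 3])
})
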