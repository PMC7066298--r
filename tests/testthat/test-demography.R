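# Scenario compilation and the Monte-Carlo expected-spectrum engine.

test_that("each model family exposes exactly its free parameters", {
  k <- vapply(model_free_params, length, integer(1))
  expect_equal(unname(k[c("SI", "IM", "AM", "SC", "IM2M", "AM2M", "SC2M")]),
               c(3L, 5L, 6L, 6L, 8L, 9L, 9L))
  expect_error(param_vector("SI", nu1 = 1, nu2 = 1),
               "requires exactly")
  expect_error(param_vector("IM", nu1 = 1, nu2 = 1, m12 = 1, m21 = 1,
                            T_S = 1, T_SC = 1), "requires exactly")
  expect_error(param_vector("IM2M", nu1 = 1, nu2 = 1, m12 = 1, m21 = 1,
                            me12 = 1, me21 = 1, T_S = 1, P = 1.4),
               "P must lie")
})

test_that("parameter files round-trip through the key-value format", {
  p <- param_vector("SC2M", nu1 = 1.7785, nu2 = 1.6024, m12 = 4.1314,
                    m21 = 0.0438, me12 = 0.0264, me21 = 0.0331,
                    T_S = 1.7599, T_SC = 0.714, P = 0.3721)
  f <- tempfile(fileext = ".cfg")
  write_params(p, f)
  q <- read_params(f)
  expect_identical(attr(q, "model_id"), "SC2M")
  expect_identical(as.numeric(q), as.numeric(p))
})

test_that("compiled epoch sequences match the scenario definitions", {
  sc <- compile_scenario(param_vector("SC", nu1 = 2, nu2 = 0.5, m12 = 3,
                                      m21 = 0.2, T_S = 1.5, T_SC = 0.3))
  expect_length(sc$epochs, 3L)
  expect_equal(sc$epochs[[1]]$duration, 0.3)
  expect_equal(sc$epochs[[1]]$mig[1, 2], 3)    # recent epoch migrates
  expect_equal(sc$epochs[[1]]$mig[2, 1], 0.2)
  expect_equal(sc$epochs[[2]]$duration, 1.5)
  expect_true(all(sc$epochs[[2]]$mig == 0))    # older epoch isolated
  expect_equal(sc$epochs[[3]]$sizes, 1)        # panmictic ancestral deme
  expect_true(is.infinite(sc$epochs[[3]]$duration))

  si <- compile_scenario(param_vector("SI", nu1 = 1, nu2 = 1, T_S = 2))
  expect_true(all(vapply(si$epochs, function(e) all(e$mig == 0),
                         logical(1))))

  am <- compile_scenario(param_vector("AM", nu1 = 1, nu2 = 1, m12 = 2,
                                      m21 = 1, T_S = 1, T_AM = 0.4))
  expect_true(all(am$epochs[[1]]$mig == 0))    # recent isolation
  expect_equal(am$epochs[[2]]$mig[1, 2], 2)    # older epoch migrates

  # AM collapses onto IM when the isolation epoch has zero duration
  am0 <- compile_scenario(param_vector("AM", nu1 = 1, nu2 = 1, m12 = 2,
                                       m21 = 1, T_S = 1, T_AM = 0))
  im <- compile_scenario(param_vector("IM", nu1 = 1, nu2 = 1, m12 = 2,
                                      m21 = 1, T_S = 1))
  expect_equal(am0$epochs[[1]]$duration, 0)
  expect_equal(am0$epochs[[2]][c("duration", "sizes", "mig")],
               im$epochs[[1]][c("duration", "sizes", "mig")])

  expect_error(compile_scenario(im$epochs, "restricted"))
  expect_error(compile_scenario(param_vector("IM", nu1 = 1, nu2 = 1,
                                             m12 = 1, m21 = 1, T_S = 1),
                                "restricted"), "only defined for 2M")
})

test_that("2M compilation swaps in the restricted migration rates", {
  p <- param_vector("SC2M", nu1 = 1, nu2 = 1, m12 = 4, m21 = 0.5,
                    me12 = 0.02, me21 = 0.01, T_S = 2, T_SC = 0.2,
                    P = 0.4)
  free <- compile_scenario(p, "free")
  restr <- compile_scenario(p, "restricted")
  expect_equal(free$epochs[[1]]$mig[1, 2], 4)
  expect_equal(restr$epochs[[1]]$mig[1, 2], 0.02)
  expect_equal(restr$epochs[[1]]$mig[2, 1], 0.01)
})

test_that("panmictic limit reproduces the standard neutral spectrum", {
  # merge at time 0: a single deme of size 1; E[xi_i] = theta / i
  s <- compile_scenario(param_vector("SI", nu1 = 1, nu2 = 1, T_S = 0))
  theta <- 2.5
  e <- expected_jafs(s, 4, 4, theta = theta, n_genealogies = 5e4,
                     seed = 2)
  se <- attr(e, "se")
  tot <- outer(0:4, 0:4, `+`)
  for (k in 1:7) {
    est <- sum(e$values[tot == k])
    se_k <- sum(se[tot == k])  # conservative: sd(sum) <= sum(sd)
    expect_lt(abs(est - theta / k), 3 * se_k)
  }
})

test_that("expected spectra are nonnegative and exactly linear in theta", {
  p <- param_vector("IM", nu1 = 1.5, nu2 = 0.7, m12 = 2, m21 = 0.3,
                    T_S = 1)
  e1 <- expected_jafs(compile_scenario(p), 5, 3, theta = 1,
                      n_genealogies = 3000, seed = 11)
  e2 <- expected_jafs(compile_scenario(p), 5, 3, theta = 3.7,
                      n_genealogies = 3000, seed = 11)
  expect_true(all(e1$values >= 0))
  expect_equal(e2$values, 3.7 * e1$values, tolerance = 1e-12)
})

test_that("swapping the populations transposes the expected spectrum", {
  pa <- param_vector("IM", nu1 = 2, nu2 = 0.5, m12 = 3, m21 = 0.2,
                     T_S = 0.8)
  pb <- param_vector("IM", nu1 = 0.5, nu2 = 2, m12 = 0.2, m21 = 3,
                     T_S = 0.8)
  a <- expected_jafs(compile_scenario(pa), 5, 4, n_genealogies = 2e5,
                     seed = 3)
  b <- expected_jafs(compile_scenario(pb), 4, 5, n_genealogies = 2e5,
                     seed = 4)
  tol <- 5 * (attr(a, "se") + t(attr(b, "se"))) + 1e-3
  expect_true(all(abs(a$values - t(b$values)) <= tol))
})

test_that("mixture spectra are the exact P-weighted combination", {
  p <- param_vector("IM2M", nu1 = 1, nu2 = 1, m12 = 3, m21 = 1,
                    me12 = 0.05, me21 = 0.02, T_S = 1, P = 0.3)
  mix <- expected_jafs_mixture(p, 4, 4, n_genealogies = 2000, seed = 21)
  free <- expected_jafs(compile_scenario(p, "free"), 4, 4,
                        n_genealogies = 2000, seed = 21)
  restr <- expected_jafs(compile_scenario(p, "restricted"), 4, 4,
                         n_genealogies = 2000,
                         seed = divcoal:::derive_seed(21, 1))
  expect_equal(mix$values, 0.3 * free$values + 0.7 * restr$values,
               tolerance = 1e-12)
  p1 <- param_vector("IM2M", nu1 = 1, nu2 = 1, m12 = 3, m21 = 1,
                     me12 = 0.05, me21 = 0.02, T_S = 1, P = 1)
  mix1 <- expected_jafs_mixture(p1, 4, 4, n_genealogies = 2000, seed = 21)
  expect_equal(mix1$values, free$values, tolerance = 1e-12)
  p0 <- param_vector("IM2M", nu1 = 1, nu2 = 1, m12 = 3, m21 = 1,
                     me12 = 0.05, me21 = 0.02, T_S = 1, P = 0)
  mix0 <- expected_jafs_mixture(p0, 4, 4, n_genealogies = 2000, seed = 21)
  expect_equal(mix0$values, restr$values, tolerance = 1e-12)
  expect_error(expected_jafs_mixture(
    param_vector("IM", nu1 = 1, nu2 = 1, m12 = 1, m21 = 1, T_S = 1),
    4, 4), "requires a 2M model")
})

test_that("deep strict isolation leaves almost no shared polymorphism", {
  s <- compile_scenario(param_vector("SI", nu1 = 1, nu2 = 1, T_S = 20))
  e <- expected_jafs(s, 6, 6, n_genealogies = 5e4, seed = 8)
  joint <- e$values[2:6, 2:6]  # i and j both in 1..n-1
  expect_lt(sum(joint) / jafs_mass(e), 1e-3)
})

test_that("the coalescent engine agrees with forward Wright-Fisher", {
  # one representative per epoch structure; the 2M mixtures are exact
  # linear combinations of these and are checked algebraically above
  cases <- list(
    list(p = param_vector("SI", nu1 = 1, nu2 = 1.5, T_S = 0.5),
         m = c(0, 0)),
    list(p = param_vector("IM", nu1 = 1, nu2 = 1, m12 = 1, m21 = 1,
                          T_S = 1), m = c(1, 1)),
    list(p = param_vector("AM", nu1 = 1, nu2 = 0.8, m12 = 2, m21 = 0.5,
                          T_S = 1, T_AM = 0.3), m = NULL),
    list(p = param_vector("SC", nu1 = 1.2, nu2 = 1, m12 = 2, m21 = 0.5,
                          T_S = 1.2, T_SC = 0.2), m = NULL))
  for (case in cases) {
    p <- case$p
    coal <- expected_jafs(compile_scenario(p), 4, 4,
                          n_genealogies = 2e5, seed = 31)
    fw <- forward_wf_oracle(p, 4, 4, theta = 2e4, seed = 32)
    a <- coal$values[!coal$mask] / jafs_mass(coal)
    b <- fw$values[!fw$mask] / jafs_mass(fw)
    big <- a >= 0.01
    expect_lt(max(abs(a[big] - b[big]) / a[big]), 0.08,
              label = paste("relative error,", attr(p, "model_id")))
  }
})
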