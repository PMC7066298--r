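#' Optimally rescaled Poisson composite log-likelihood
#'
#' The "multinomial" fit criterion of frequency-spectrum inference: the
#' model spectrum is rescaled by the analytically optimal factor
#' `theta_hat = sum(data) / sum(model)` over unmasked entries, and each
#' unmasked entry contributes an independent Poisson term
#' `D * log(theta_hat * M) - theta_hat * M - log(D!)`.  Entries where the
#' scaled model is 0 but the data positive contribute `-Inf`.  Because
#' the rescaling is optimal, the log-likelihood is invariant to
#' pre-multiplying the model by any positive constant, and `theta_hat` is
#' not a free parameter of the model.
#'
#' @param model expected [jafs()] (any positive scale).
#' @param data observed [jafs()] with the same shape and mask.
#' @return A list with `loglik` and `theta_hat`.
#' @export
scaled_poisson_loglik <- function(model, data) {
  if (!identical(dim(model$values), dim(data$values)) ||
      !identical(model$mask, data$mask))
    stop("model and data spectra must share shape and mask")
  u <- !model$mask
  M <- model$values[u]; D <- data$values[u]
  if (any(M < 0) || sum(M) <= 0)
    stop("model entries must be >= 0 with positive unmasked total")
  theta_hat <- sum(D) / sum(M)
  lam <- theta_hat * M
  ll <- numeric(length(lam))
  pos <- lam > 0
  ll[pos] <- D[pos] * log(lam[pos]) - lam[pos] - lgamma(D[pos] + 1)
  ll[!pos] <- ifelse(D[!pos] > 0, -Inf, 0)
  list(loglik = sum(ll), theta_hat = theta_hat)
}

#' Multiplicatively perturb model parameters
#'
#' Each free parameter is multiplied by `2^(fold * u)` with independent
#' `u ~ Uniform(-1, 1)` draws, then clipped to its bounds — the standard
#' way to scatter replicate starting points around an anchor.
#'
#' @param p a [param_vector()].
#' @param fold perturbation strength; `fold = 0` returns `p` unchanged.
#' @param bounds list with numeric vectors `lower` and `upper`, either
#'   length 1 (recycled) or named per parameter (see [default_bounds()]).
#' @param seed integer seed.
#' @return A perturbed [param_vector()].
#' @export
perturb_params <- function(p, fold, bounds = default_bounds(p), seed = 1L) {
  stopifnot(fold >= 0)
  u <- with_seed(seed, runif(length(p), -1, 1))
  out <- as.numeric(p) * 2^(fold * u)
  out <- pmin(pmax(out, bounds$lower[names(p)]), bounds$upper[names(p)])
  structure(setNames(out, names(p)), model_id = attr(p, "model_id"),
            class = "param_vector")
}

#' Default optimization bounds for a model's parameters
#'
#' Sizes, times and migration rates in `[1e-3, 1e2]`; the mixture
#' proportion `P` in `[1e-3, 1 - 1e-3]`.
#'
#' @param p a [param_vector()].
#' @return A list with named vectors `lower` and `upper`.
#' @export
default_bounds <- function(p) {
  nm <- names(p)
  lower <- setNames(rep(1e-3, length(nm)), nm)
  upper <- setNames(rep(1e2, length(nm)), nm)
  if ("P" %in% nm) upper["P"] <- 1 - 1e-3
  list(lower = lower, upper = upper)
}

default_start <- function(model_id) {
  nm <- model_free_params[[model_id]]
  p <- setNames(rep(1, length(nm)), nm)
  if ("P" %in% nm) p["P"] <- 0.5
  do.call(param_vector, c(list(model_id = model_id), as.list(p)))
}

#' Bounded Nelder-Mead simplex minimizer
#'
#' A standard Nelder-Mead simplex (reflection 1, expansion 2, contraction
#' 0.5, shrink 0.5) operating on the coordinates it is given, with
#' clipping to box bounds at every evaluation.  [fit_model()] supplies
#' log10-transformed parameters, so model fitting runs in log-parameter
#' space.  Iterations stop at `max_iterations` or when the simplex
#' function spread falls below `tol`.
#'
#' @param objective function of a numeric vector, finite at `start`.
#' @param start numeric starting vector.
#' @param max_iterations iteration cap; `0` returns `start` unchanged.
#' @param lower,upper optional box bounds (clipping).
#' @param tol simplex function-value spread tolerance.
#' @return A list with `par`, `value` and the iteration count `iters`.
#' @export
nelder_mead_minimize <- function(objective, start, max_iterations = 100L,
                                 lower = -Inf, upper = Inf, tol = 1e-6) {
  n <- length(start)
  clip <- function(x) pmin(pmax(x, lower), upper)
  f <- function(x) objective(clip(x))
  f0 <- f(start)
  if (!is.finite(f0)) stop("objective must be finite at the start point")
  if (max_iterations <= 0)
    return(list(par = clip(start), value = f0, iters = 0L))
  # initial simplex: displace each coordinate by 5% of its magnitude,
  # with an absolute floor so near-zero coordinates (e.g. log10 of a
  # parameter close to 1) still span a usable simplex
  simplex <- matrix(rep(start, n + 1L), n + 1L, n, byrow = TRUE)
  for (i in seq_len(n))
    simplex[i + 1L, i] <- start[i] + max(0.05 * abs(start[i]), 0.1)
  fv <- c(f0, apply(simplex[-1L, , drop = FALSE], 1L, f))
  iters <- 0L
  while (iters < max_iterations) {
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]; fv <- fv[ord]
    if (is.finite(fv[n + 1L]) && fv[n + 1L] - fv[1L] < tol) break
    iters <- iters + 1L
    centroid <- colMeans(simplex[seq_len(n), , drop = FALSE])
    xr <- centroid + (centroid - simplex[n + 1L, ])
    fr <- f(xr)
    if (fr < fv[1L]) {
      xe <- centroid + 2 * (centroid - simplex[n + 1L, ])
      fe <- f(xe)
      if (fe < fr) { simplex[n + 1L, ] <- xe; fv[n + 1L] <- fe }
      else { simplex[n + 1L, ] <- xr; fv[n + 1L] <- fr }
    } else if (fr < fv[n]) {
      simplex[n + 1L, ] <- xr; fv[n + 1L] <- fr
    } else {
      xc <- centroid + 0.5 * (simplex[n + 1L, ] - centroid)
      fc <- f(xc)
      if (fc < fv[n + 1L]) { simplex[n + 1L, ] <- xc; fv[n + 1L] <- fc }
      else {
        for (i in 2L:(n + 1L)) {
          simplex[i, ] <- simplex[1L, ] + 0.5 * (simplex[i, ] - simplex[1L, ])
          fv[i] <- f(simplex[i, ])
        }
      }
    }
  }
  best <- which.min(fv)
  list(par = clip(simplex[best, ]), value = fv[best], iters = iters)
}

#' Fitting configuration
#'
#' @param rounds number of optimization rounds.
#' @param replicates perturbed starts per round.
#' @param maxiter Nelder-Mead iteration cap per replicate.
#' @param folds perturbation strength per round (recycled/truncated to
#'   `rounds`); the classic protocol is 3-, then 2-, then 1-fold.
#' @param n_genealogies Monte-Carlo genealogies per likelihood
#'   evaluation; may be a vector per round (coarse early rounds, precise
#'   final round), recycled to `rounds`.
#' @param seed base seed; replicate starts and the common-random-numbers
#'   stream of the likelihood are derived from it, so a fit is
#'   bit-reproducible.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(rounds = 3L, replicates = 100L, maxiter = 100L,
                       folds = c(3, 2, 1),
                       n_genealogies = c(5000L, 10000L, 20000L),
                       seed = 1L) {
  folds <- rep_len(folds, rounds)
  structure(list(rounds = as.integer(rounds),
                 replicates = as.integer(replicates),
                 maxiter = as.integer(maxiter), folds = folds,
                 n_genealogies = rep_len(as.integer(n_genealogies), rounds),
                 seed = as.integer(seed)),
            class = "fit_config")
}

# Deterministic composite-likelihood objective for one model on one data
# spectrum.  The Monte-Carlo stream is re-seeded identically at every
# evaluation (common random numbers), so the objective is a deterministic
# function of the parameters given the configuration.
# Monte-Carlo effort for one likelihood evaluation.  Genealogy cost grows
# with deme sizes, epoch durations and migration (event count per
# genealogy), so the effort is scaled down deterministically at extreme
# parameter combinations (far outside the data-supported region in all
# fitted examples), with a floor that keeps the objective usable there.
mc_effort <- function(p, n_tips, n_genealogies, event_budget = 3e8) {
  numax <- max(p[names(p) %in% c("nu1", "nu2")], 1)
  ms <- p[names(p) %in% c("m12", "m21", "me12", "me21")]
  mmax <- if (length(ms)) max(ms) else 0
  t_tot <- sum(p[names(p) %in% c("T_S", "T_AM", "T_SC")])
  events <- (2 * numax * log(2 * n_tips) + t_tot) * n_tips * (1 + mmax / 2)
  max(as.integer(n_genealogies / 50),
      min(n_genealogies, as.integer(event_budget / events)))
}

make_objective <- function(data, model_id, config, n_genealogies = NULL) {
  if (is.null(n_genealogies))
    n_genealogies <- max(config$n_genealogies)
  mc_seed <- derive_seed(config$seed, 999983L)
  nm <- model_free_params[[model_id]]
  n_tips <- data$n1 + data$n2
  function(logpar) {
    p <- structure(setNames(10^logpar, nm), model_id = model_id,
                   class = "param_vector")
    m <- model_expected_jafs(p, data$n1, data$n2, theta = 1,
                             n_genealogies = mc_effort(p, n_tips,
                                                       n_genealogies),
                             seed = mc_seed)
    ll <- scaled_poisson_loglik(m, data)$loglik
    if (!is.finite(ll)) return(1e12)
    -ll
  }
}

#' Fit a divergence model to an observed spectrum
#'
#' Multi-round perturbed Nelder-Mead protocol: round 1 launches
#' `replicates` optimizations from fold-perturbed copies of the default
#' start (all parameters 1, `P = 0.5`); each later round re-perturbs the
#' best parameters found so far with a smaller fold.  The first
#' replicate of every round starts at the unperturbed anchor, so the
#' incumbent optimum is always re-polished.  Every replicate is capped
#' at `maxiter` simplex iterations; optimization runs in log10 parameter
#' space within the box bounds.  The returned fit is the
#' highest-log-likelihood replicate of the final round, re-scored at the
#' largest per-round Monte-Carlo effort.
#'
#' @param data observed [jafs()].
#' @param model_id model family (see [param_vector()]).
#' @param config a [fit_config()].
#' @param start optional [param_vector()] overriding the default start.
#' @param bounds optional bounds as in [perturb_params()].
#' @return A list of class `fit_result` with elements `model_id`,
#'   `best_params`, `loglik`, `theta_hat`, `aic`, `k` and the per-round,
#'   per-replicate `round_log`.
#' @export
fit_model <- function(data, model_id, config = fit_config(), start = NULL,
                      bounds = NULL) {
  model_id <- match.arg(model_id, names(model_free_params))
  if (is.null(start)) start <- default_start(model_id)
  if (is.null(bounds)) bounds <- default_bounds(start)
  nm <- names(start)
  anchor <- start
  round_log <- list()
  rep_counter <- 0L
  best <- NULL
  for (r in seq_len(config$rounds)) {
    objective <- make_objective(data, model_id, config,
                                config$n_genealogies[r])
    round_best <- list(par = NULL, value = Inf)
    entries <- vector("list", config$replicates)
    for (j in seq_len(config$replicates)) {
      rep_counter <- rep_counter + 1L
      p0 <- if (j == 1L) anchor else
        perturb_params(anchor, config$folds[r], bounds,
                       seed = derive_seed(config$seed, rep_counter))
      res <- nelder_mead_minimize(objective, log10(as.numeric(p0)),
                                  max_iterations = config$maxiter,
                                  lower = log10(bounds$lower[nm]),
                                  upper = log10(bounds$upper[nm]))
      entries[[j]] <- list(start = setNames(as.numeric(p0), nm),
                           end = setNames(10^res$par, nm),
                           loglik = -res$value)
      if (res$value < round_best$value) round_best <- res
    }
    round_log[[r]] <- entries
    best <- round_best
    anchor <- structure(setNames(10^best$par, nm), model_id = model_id,
                        class = "param_vector")
  }
  best_params <- anchor
  m <- model_expected_jafs(best_params, data$n1, data$n2, theta = 1,
                           n_genealogies = max(config$n_genealogies),
                           seed = derive_seed(config$seed, 999983L))
  sl <- scaled_poisson_loglik(m, data)
  k <- length(model_free_params[[model_id]])
  structure(list(model_id = model_id, best_params = best_params,
                 loglik = sl$loglik, theta_hat = sl$theta_hat,
                 aic = 2 * k - 2 * sl$loglik, k = k,
                 round_log = round_log, config = config),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result [%s]: loglik = %.2f, AIC = %.2f, theta = %.4g\n",
              x$model_id, x$loglik, x$aic, x$theta_hat))
  print(setNames(as.numeric(x$best_params), names(x$best_params)))
  invisible(x)
}

#' Rank fitted models by AIC
#'
#' Builds the model-comparison table: one row per fit with the
#' log-likelihood of its best replicate, `AIC = 2k - 2*loglik`, `theta`,
#' and all model parameters, sorted by ascending AIC (ties broken by
#' smaller `k`).
#'
#' @param fits list of [fit_model()] results (or minimal lists with
#'   `model_id`, `loglik`, and optionally `theta_hat`/`best_params`).
#' @return A data.frame sorted by AIC.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  all_par <- c("nu1", "nu2", "m12", "m21", "me12", "me21",
               "T_S", "T_AM", "T_SC", "P")
  rows <- lapply(fits, function(f) {
    k <- if (!is.null(f$k)) f$k else length(model_free_params[[f$model_id]])
    pv <- setNames(rep(NA_real_, length(all_par)), all_par)
    if (!is.null(f$best_params))
      pv[names(f$best_params)] <- as.numeric(f$best_params)
    cbind(data.frame(model = f$model_id, loglik = f$loglik,
                     AIC = 2 * k - 2 * f$loglik, k = k,
                     theta = if (is.null(f$theta_hat)) NA_real_
                             else f$theta_hat),
          as.data.frame(as.list(pv)))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC, tab$k), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Pearson residual grid of a fitted spectrum
#'
#' Standardized (Poisson/Pearson) residuals `(D - theta_hat*M) /
#' sqrt(theta_hat*M)` on unmasked entries; masked or zero-expectation
#' entries are `NA` and flagged in the returned mask.
#'
#' @param model expected [jafs()].
#' @param data observed [jafs()].
#' @param theta optional scaling for the model; by default the optimal
#'   `theta_hat` from [scaled_poisson_loglik()] is applied, so pass
#'   `theta = 1` if `model` is already scaled.
#' @return A list of class `residual_grid` with `residuals` and `mask`.
#' @export
residual_grid <- function(model, data, theta = NULL) {
  if (!identical(dim(model$values), dim(data$values)))
    stop("model and data spectra must share shape")
  if (is.null(theta)) theta <- scaled_poisson_loglik(model, data)$theta_hat
  lam <- theta * model$values
  flagged <- model$mask | data$mask | lam <= 0
  res <- matrix(NA_real_, nrow(lam), ncol(lam))
  res[!flagged] <- (data$values[!flagged] - lam[!flagged]) /
    sqrt(lam[!flagged])
  structure(list(residuals = res, mask = flagged), class = "residual_grid")
}

#' Serialize / restore a fit result as JSON
#'
#' @param fit a [fit_model()] result.
#' @param file path of the JSON file.
#' @return `file` invisibly for the writer; a `fit_result` for the reader.
#' @export
write_fit <- function(fit, file) {
  obj <- list(model_id = fit$model_id,
              best_params = as.list(fit$best_params),
              loglik = fit$loglik, theta_hat = fit$theta_hat,
              aic = fit$aic, k = fit$k,
              config = unclass(fit$config),
              round_log = fit$round_log)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_fit
#' @export
read_fit <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  bp <- unlist(obj$best_params)
  structure(list(model_id = obj$model_id,
                 best_params = structure(bp, model_id = obj$model_id,
                                         class = "param_vector"),
                 loglik = obj$loglik, theta_hat = obj$theta_hat,
                 aic = obj$aic, k = obj$k,
                 round_log = obj$round_log,
                 config = obj$config),
            class = "fit_result")
}
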