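#' Divergence-model parameter vectors
#'
#' The seven two-population divergence scenarios share a common parameter
#' vocabulary (all in the conventional diffusion scaling: sizes relative
#' to the ancestral reference size `Nref`, times in units of `2*Nref`
#' generations, migration as `2*Nref*m`):
#'
#' * `nu1`, `nu2` — population sizes of population 1 / population 2;
#' * `m12`, `m21` — migration; `m12` is gene flow *into* population 1
#'   *from* population 2, forward in time;
#' * `me12`, `me21` — effective migration of the restricted locus class
#'   (semi-permeable barrier; `2M` models only);
#' * `T_S` — duration of the older post-split epoch;
#' * `T_AM`, `T_SC` — duration of the most recent epoch for the ancient
#'   migration / secondary contact families;
#' * `P` — proportion of loci in the freely exchanging `(m12, m21)`
#'   class (`2M` models only).
#'
#' Model families: `SI` strict isolation (3 free parameters), `IM`
#' isolation-with-migration (5), `AM` ancient migration (6), `SC`
#' secondary contact (6), and their two-migration-class extensions
#' `IM2M` (8), `AM2M` (9), `SC2M` (9).
#'
#' @param model_id one of `"SI"`, `"IM"`, `"AM"`, `"SC"`, `"IM2M"`,
#'   `"AM2M"`, `"SC2M"`.
#' @param ... named numeric parameters, exactly those of `model_id`.
#' @return A named numeric vector of class `param_vector` with attribute
#'   `model_id`.
#' @export
param_vector <- function(model_id, ...) {
  model_id <- match.arg(model_id, names(model_free_params))
  p <- c(...)
  need <- model_free_params[[model_id]]
  if (!setequal(names(p), need))
    stop(sprintf("model %s requires exactly the parameters: %s",
                 model_id, paste(need, collapse = ", ")))
  p <- p[need]
  if (any(!is.finite(p)) || any(p < 0))
    stop("all parameters must be finite and >= 0")
  if ("P" %in% need && (p[["P"]] < 0 || p[["P"]] > 1))
    stop("P must lie in [0, 1]")
  structure(p, model_id = model_id, class = "param_vector")
}

#' @rdname param_vector
#' @format NULL
#' @export
model_free_params <- list(
  SI   = c("nu1", "nu2", "T_S"),
  IM   = c("nu1", "nu2", "m12", "m21", "T_S"),
  AM   = c("nu1", "nu2", "m12", "m21", "T_S", "T_AM"),
  SC   = c("nu1", "nu2", "m12", "m21", "T_S", "T_SC"),
  IM2M = c("nu1", "nu2", "m12", "m21", "me12", "me21", "T_S", "P"),
  AM2M = c("nu1", "nu2", "m12", "m21", "me12", "me21", "T_S", "T_AM", "P"),
  SC2M = c("nu1", "nu2", "m12", "m21", "me12", "me21", "T_S", "T_SC", "P"))

is_2m_model <- function(model_id) model_id %in% c("IM2M", "AM2M", "SC2M")

#' Write / read a parameter vector as a flat key-value file
#'
#' One `key = value` pair per line, with the model family under the key
#' `model`.
#'
#' @param p a [param_vector()].
#' @param file path of the text file.
#' @return `file` invisibly for the writer; a [param_vector()] for the
#'   reader.
#' @export
write_params <- function(p, file) {
  lines <- c(paste("model =", attr(p, "model_id")),
             sprintf("%s = %.17g", names(p), as.numeric(p)))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  lines <- grep("=", readLines(file), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  model_id <- vals[keys == "model"]
  if (length(model_id) != 1L) stop("parameter file must name one model")
  args <- as.list(as.numeric(vals[keys != "model"]))
  names(args) <- keys[keys != "model"]
  do.call(param_vector, c(list(model_id = model_id), args))
}

#' @export
print.param_vector <- function(x, ...) {
  cat("param_vector [", attr(x, "model_id"), "]\n", sep = "")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

make_epoch <- function(duration, sizes, mig, map) {
  list(duration = duration, sizes = sizes, mig = mig, map = as.integer(map))
}

two_deme_mig <- function(m12, m21) matrix(c(0, m21, m12, 0), 2L, 2L)

#' Compile a parameter vector into a backward-time epoch sequence
#'
#' Turns the parameters of a divergence model into the ordered list of
#' backward-time epochs consumed by the coalescent engine: for example a
#' secondary-contact model becomes (most recent first) a two-deme epoch of
#' duration `T_SC` with migration, a two-deme epoch of duration `T_S`
#' without migration, and the unbounded single-deme ancestral epoch of
#' relative size 1.  For the `2M` families, `locus_class = "restricted"`
#' substitutes `(me12, me21)` for `(m12, m21)`.
#'
#' @param p a [param_vector()].
#' @param locus_class `"free"` (default) or `"restricted"`; the latter is
#'   only valid for the `2M` families.
#' @return An object of class `demographic_scenario`: a list of epochs,
#'   each with `duration`, `sizes`, `mig` (scaled migration matrix, entry
#'   `[a, b]` = gene flow into deme `a` from deme `b`) and the deme
#'   relabelling `map` applied when entering the epoch.
#' @export
compile_scenario <- function(p, locus_class = c("free", "restricted")) {
  locus_class <- match.arg(locus_class)
  model_id <- attr(p, "model_id")
  if (locus_class == "restricted" && !is_2m_model(model_id))
    stop("locus_class = \"restricted\" is only defined for 2M models")
  nu <- c(p[["nu1"]], p[["nu2"]])
  mig0 <- two_deme_mig(0, 0)
  migp <- if (model_id == "SI") {
    mig0
  } else if (locus_class == "restricted") {
    two_deme_mig(p[["me12"]], p[["me21"]])
  } else {
    two_deme_mig(p[["m12"]], p[["m21"]])
  }
  base <- switch(sub("2M$", "", model_id),
    SI = list(make_epoch(p[["T_S"]], nu, mig0, 0:1)),
    IM = list(make_epoch(p[["T_S"]], nu, migp, 0:1)),
    SC = list(make_epoch(p[["T_SC"]], nu, migp, 0:1),
              make_epoch(p[["T_S"]], nu, mig0, 0:1)),
    AM = list(make_epoch(p[["T_AM"]], nu, mig0, 0:1),
              make_epoch(p[["T_S"]], nu, migp, 0:1)))
  ancestral <- make_epoch(Inf, 1, matrix(0, 1L, 1L), c(0L, 0L))
  structure(list(epochs = c(base, list(ancestral)), model_id = model_id,
                 locus_class = locus_class),
            class = "demographic_scenario")
}

#' Hierarchical island scenario (equilibrium, no splits)
#'
#' `groups` groups of `demes_per_group` demes each, all of relative size
#' 1.  Each lineage receives a total scaled migration `m_within` spread
#' uniformly over the other demes of its group and `m_among` spread over
#' all demes of the other groups.  This is the coalescent null used for
#' FCT outlier scans.
#'
#' @param groups,demes_per_group island-model dimensions (at least 2
#'   groups and 2 demes per group).
#' @param m_within,m_among total scaled (`2*Nref*m`) migration received
#'   from same-group and other-group demes; both must be positive so the
#'   equilibrium coalescent terminates.
#' @return A `demographic_scenario` with one unbounded epoch.
#' @export
island_scenario <- function(groups, demes_per_group, m_within, m_among) {
  stopifnot(groups >= 2, demes_per_group >= 2, m_within > 0, m_among > 0)
  D <- groups * demes_per_group
  grp <- rep(seq_len(groups), each = demes_per_group)
  mig <- matrix(0, D, D)
  for (a in seq_len(D)) for (b in seq_len(D)) {
    if (a == b) next
    mig[a, b] <- if (grp[a] == grp[b]) m_within / (demes_per_group - 1)
                 else m_among / (demes_per_group * (groups - 1))
  }
  ep <- make_epoch(Inf, rep(1, D), mig, seq_len(D) - 1L)
  structure(list(epochs = list(ep), model_id = "island",
                 deme_group = grp, locus_class = "free"),
            class = "demographic_scenario")
}

epochs_for_engine <- function(s) {
  lapply(s$epochs, function(e)
    list(duration = e$duration, sizes = as.numeric(e$sizes),
         mig = e$mig, map = as.integer(e$map)))
}

#' Expected unfolded JAFS of a scenario by Monte-Carlo coalescent
#'
#' Entry `(i, j)` is `theta/2` times the Monte-Carlo mean total branch
#' length (in `2*Nref`-generation units) subtending exactly `i` of the
#' `n1` population-1 tips and `j` of the `n2` population-2 tips, i.e. the
#' expected count of derived sites at joint frequency `(i, j)` under the
#' infinite-sites model.  Monomorphic corners are masked.  The attribute
#' `"se"` carries the per-entry Monte-Carlo standard error.
#'
#' @param s a `demographic_scenario` whose first epoch has (at least) two
#'   demes; samples are drawn from demes 1 and 2.
#' @param n1,n2 chromosome sample sizes.
#' @param theta scaled mutation rate multiplying the branch-length tally.
#' @param n_genealogies number of independent genealogies to average.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return A [jafs()] of kind `"expected"`.
#' @export
expected_jafs <- function(s, n1, n2, theta = 1, n_genealogies = 20000L,
                          seed = 1L) {
  stopifnot(inherits(s, "demographic_scenario"), n1 >= 1, n2 >= 1,
            n_genealogies >= 1)
  if (!is.finite(theta) || theta <= 0) stop("theta must be finite and > 0")
  res <- with_seed(seed,
    .coal_expected_jafs_cpp(as.integer(n1), as.integer(n2),
                            epochs_for_engine(s),
                            as.integer(n_genealogies)))
  out <- jafs(theta / 2 * res$mean, kind = "expected")
  attr(out, "se") <- theta / 2 * res$se
  out
}

#' Expected JAFS of a two-locus-class (2M) model
#'
#' Entrywise mixture `P * free + (1 - P) * restricted` of the expected
#' spectra of the two locus classes, modelling a genome in which a
#' proportion `P` of loci exchanges at the neutral rates `(m12, m21)` and
#' the rest at the barrier-reduced rates `(me12, me21)`.
#'
#' @param p a [param_vector()] of an `IM2M`, `AM2M` or `SC2M` model.
#' @inheritParams expected_jafs
#' @return A [jafs()] of kind `"expected"`.
#' @export
expected_jafs_mixture <- function(p, n1, n2, theta = 1,
                                  n_genealogies = 20000L, seed = 1L) {
  model_id <- attr(p, "model_id")
  if (!is_2m_model(model_id))
    stop("expected_jafs_mixture() requires a 2M model")
  P <- p[["P"]]
  free <- expected_jafs(compile_scenario(p, "free"), n1, n2, theta,
                        n_genealogies, seed)
  restr <- expected_jafs(compile_scenario(p, "restricted"), n1, n2, theta,
                         n_genealogies, derive_seed(seed, 1L))
  out <- jafs(P * free$values + (1 - P) * restr$values, kind = "expected")
  attr(out, "se") <- sqrt((P * attr(free, "se"))^2 +
                          ((1 - P) * attr(restr, "se"))^2)
  out
}

#' Expected JAFS of any model (single-class or mixture)
#'
#' Dispatches to [expected_jafs()] for the single-class families and to
#' [expected_jafs_mixture()] for the `2M` families.
#'
#' @inheritParams expected_jafs_mixture
#' @return A [jafs()] of kind `"expected"`.
#' @export
model_expected_jafs <- function(p, n1, n2, theta = 1,
                                n_genealogies = 20000L, seed = 1L) {
  if (is_2m_model(attr(p, "model_id")))
    expected_jafs_mixture(p, n1, n2, theta, n_genealogies, seed)
  else
    expected_jafs(compile_scenario(p), n1, n2, theta, n_genealogies, seed)
}

#' Forward Wright-Fisher expected JAFS (validation simulator)
#'
#' Independent forward-in-time check of the coalescent engine for the
#' split-with-migration models: per-site binomial Wright-Fisher frequency
#' dynamics in discrete generations, initialized at the single-population
#' neutral stationary spectrum (`E[S_i] = theta/i` sites at derived count
#' `i`), run forward through the post-split phases with per-generation
#' migration probabilities implied by the scaled rates, then projected to
#' `(n1, n2)` sampled chromosomes by hypergeometric expectation.  The
#' returned spectrum estimates the same quantity as [expected_jafs()] up
#' to an overall scale.
#'
#' @param nu1,nu2 relative deme sizes after the split.
#' @param phases data.frame with columns `duration` (in `2*Nref`
#'   generations), `m12`, `m21` (scaled rates), ordered forward in time
#'   (oldest phase first); e.g. a secondary-contact history is an
#'   isolation phase followed by a migration phase.
#' @param n1,n2 sample sizes for the output spectrum.
#' @param theta stationary mutation intensity; larger values give more
#'   segregating sites and a smoother estimate.
#' @param N_anc haploid ancestral population size in copies (the forward
#'   model's `2*Nref`).
#' @param extra_burnin additional ancestral burn-in generations before
#'   the split (0 relies on the stationary initialization).
#' @param seed integer seed.
#' @return A [jafs()] of kind `"expected"` (unnormalized site counts).
#' @export
forward_wf_jafs <- function(nu1, nu2, phases, n1, n2,
                            theta = 2e4, N_anc = 400L, extra_burnin = 0L,
                            seed = 1L) {
  stopifnot(all(c("duration", "m12", "m21") %in% names(phases)))
  N1 <- max(2L, as.integer(round(nu1 * N_anc)))
  N2 <- max(2L, as.integer(round(nu2 * N_anc)))
  vals <- with_seed(seed,
    .wf_expected_jafs_cpp(theta, as.integer(N_anc), N1, N2,
                          phases$m12 / (2 * N_anc),
                          phases$m21 / (2 * N_anc),
                          as.integer(round(phases$duration * N_anc)),
                          as.integer(n1), as.integer(n2),
                          as.integer(extra_burnin)))
  jafs(vals, kind = "expected")
}

#' Forward-phase table of a divergence model
#'
#' Helper mapping a [param_vector()] (single-class families, or one locus
#' class of a `2M` family) to the forward-in-time phase table consumed by
#' [forward_wf_jafs()].
#'
#' @param p a [param_vector()].
#' @param locus_class `"free"` or `"restricted"`.
#' @return A data.frame with `duration`, `m12`, `m21`, oldest phase
#'   first.
#' @export
forward_phases <- function(p, locus_class = "free") {
  s <- compile_scenario(p, locus_class)
  ep <- rev(s$epochs[-length(s$epochs)])  # drop ancestral, oldest first
  data.frame(duration = vapply(ep, `[[`, numeric(1), "duration"),
             m12 = vapply(ep, function(e) e$mig[1, 2], numeric(1)),
             m21 = vapply(ep, function(e) e$mig[2, 1], numeric(1)))
}
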