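# Drivers for the two uncertainty analyses: the adversarial GA search and
# the one-at-a-time (OAT) sensitivity baseline, plus the summary statistics
# reported for the resulting pairs of moment-rotation curves.

#' Perturbation bounds on the model parameters
#'
#' @param geometry_delta absolute half-width for the 29 geometric
#'   parameters, mm (default 0.50).
#' @param material_rel relative half-width for the 14 material parameters
#'   (default 0.05, i.e. +/-5 percent).
#' @return an object of class `perturbation_bounds`.
#' @export
perturbation_bounds <- function(geometry_delta = 0.50, material_rel = 0.05) {
  stopifnot(geometry_delta >= 0, material_rel >= 0)
  structure(list(geometry_delta = geometry_delta, material_rel = material_rel),
            class = "perturbation_bounds")
}

#' Decision-vector bounds around a reference model
#'
#' Geometric entries get `[p - delta, p + delta]` (absolute, mm); material
#' entries get `[p (1 - rel), p (1 + rel)]`, order-corrected should a
#' parameter be negative. The per-parameter bounds are duplicated across
#' both halves of the 86-element adversarial decision vector.
#'
#' @param reference a [joint_model()].
#' @param pb a [perturbation_bounds()].
#' @return a [bounds_set()] of dimension 86.
#' @export
build_bounds <- function(reference, pb = perturbation_bounds()) {
  v <- unname(flatten_model(reference))
  geo <- geometry_mask()
  lo <- hi <- v
  lo[geo] <- v[geo] - pb$geometry_delta
  hi[geo] <- v[geo] + pb$geometry_delta
  m1 <- v[!geo] * (1 - pb$material_rel)
  m2 <- v[!geo] * (1 + pb$material_rel)
  lo[!geo] <- pmin(m1, m2)
  hi[!geo] <- pmax(m1, m2)
  bounds_set(rep(lo, 2), rep(hi, 2))
}

#' One-at-a-time sensitivity baseline
#'
#' Perturbs each of the 43 parameters in turn to its upper and then its
#' lower bound (86 runs in total), sweeps the perturbed model, and scores it
#' against the unperturbed reference with the adversarial objective (the
#' reference as structure B). Non-converging perturbed models are penalised
#' through `not_passed`, never skipped.
#'
#' @param reference a [joint_model()].
#' @param pb a [perturbation_bounds()].
#' @param schedule a [load_schedule()].
#' @param control solver control, see [solver_control()].
#' @param engine solver engine, see [sweep_loads()].
#' @return list of class `oat_result`: `runs` (data frame with
#'   `param_index`, `param_name`, `sign`, `h`, `l1_term`, `not_passed`) and
#'   `best_h` (the lowest h over all 86 runs).
#' @export
oat_baseline <- function(reference, pb = perturbation_bounds(),
                         schedule = load_schedule(),
                         control = solver_control(),
                         engine = c("cpp", "minpack")) {
  engine <- match.arg(engine)
  v <- unname(flatten_model(reference))
  geo <- geometry_mask()
  nm <- parameter_names()
  runs <- vector("list", 2 * N_PARAMS)
  k <- 0
  for (sign in c(+1, -1)) {
    for (i in seq_len(N_PARAMS)) {
      p <- v
      p[i] <- if (geo[i]) v[i] + sign * pb$geometry_delta
              else v[i] * (1 + sign * pb$material_rel)
      ob <- adversarial_objective(c(p, v), reference, schedule, control, engine)
      k <- k + 1
      runs[[k]] <- data.frame(param_index = i, param_name = nm[i],
                              sign = sign, h = ob$h, l1_term = ob$l1_term,
                              not_passed = ob$not_passed)
    }
  }
  runs <- do.call(rbind, runs)
  structure(list(runs = runs, best_h = min(runs$h)), class = "oat_result")
}

#' @export
print.oat_result <- function(x, ...) {
  cat(sprintf("<oat_result> %d one-at-a-time runs, best h = %.4f\n",
              nrow(x$runs), x$best_h))
  invisible(x)
}

#' Adversarial worst-case search
#'
#' Builds the decision-vector bounds from the perturbation bounds, injects
#' the two-copy reference solution (objective 0 by construction when the
#' reference converges at every step), runs the GA, and reports the best
#' adversarial pair with its sweeps, objective breakdown and summary
#' statistics.
#'
#' @param reference a [joint_model()].
#' @param pb a [perturbation_bounds()].
#' @param config a [ga_config()].
#' @param schedule a [load_schedule()].
#' @param control solver control, see [solver_control()].
#' @param engine solver engine, see [sweep_loads()].
#' @param trace_file optional per-generation CSV trace path, see
#'   [run_rcga()].
#' @return list of class `adversarial_report`: `ga` (the [run_rcga()]
#'   result), `breakdown` (objective of the best vector), `model_A`,
#'   `model_B`, `sweep_A`, `sweep_B`, `stats` (Table-style displacement
#'   statistics at the moment extremes and for the range of motion) and
#'   `forces` (per-element force comparison).
#' @export
run_adversarial <- function(reference, pb = perturbation_bounds(),
                            config = ga_config(), schedule = load_schedule(),
                            control = solver_control(),
                            engine = c("cpp", "minpack"),
                            trace_file = NULL) {
  engine <- match.arg(engine)
  bounds <- build_bounds(reference, pb)
  injected <- rep(unname(flatten_model(reference)), 2)
  obj_fn <- function(dv) {
    adversarial_objective(dv, reference, schedule, control, engine)$h
  }
  ga <- run_rcga(config, bounds, obj_fn, injected, trace_file)
  breakdown <- adversarial_objective(ga$best_vector, reference, schedule,
                                     control, engine)
  halves <- split_decision_vector(ga$best_vector)
  model_A <- unflatten_model(halves$A, reference)
  model_B <- unflatten_model(halves$B, reference)
  sweep_A <- breakdown$sweeps$A
  sweep_B <- breakdown$sweeps$B
  structure(list(ga = ga, breakdown = breakdown,
                 model_A = model_A, model_B = model_B,
                 sweep_A = sweep_A, sweep_B = sweep_B,
                 stats = sweep_pair_stats(sweep_A, sweep_B),
                 forces = force_comparison(sweep_A, sweep_B)),
            class = "adversarial_report")
}

#' @export
print.adversarial_report <- function(x, ...) {
  cat(sprintf("<adversarial_report> best h = %.4f (l1 = %.4f, not_passed = %d)\n",
              x$breakdown$h, x$breakdown$l1_term, x$breakdown$not_passed))
  print(x$stats)
  invisible(x)
}

#' Average / absolute / relative difference of two displacements
#'
#' The reporting convention for pairs of adversarial outputs:
#' avg = (A + B) / 2, abs_diff = |A - B| and
#' rel_diff = (abs_diff / |avg|) x 100 percent. A zero average leaves the
#' relative difference undefined and it is reported as `NaN`.
#'
#' @param dtheta_A,dtheta_B angular displacements, deg (vectorised).
#' @return data frame with columns `avg`, `abs_diff` (deg) and `rel_diff`
#'   (percent).
#' @export
displacement_stats <- function(dtheta_A, dtheta_B) {
  stopifnot(length(dtheta_A) == length(dtheta_B))
  avg <- (dtheta_A + dtheta_B) / 2
  abs_diff <- abs(dtheta_A - dtheta_B)
  rel_diff <- ifelse(avg == 0, NaN, abs_diff / abs(avg) * 100)
  data.frame(avg = avg, abs_diff = abs_diff, rel_diff = rel_diff)
}

#' Range of motion of one sweep
#'
#' Angular displacement at the largest scheduled moment minus the
#' displacement at the smallest (most negative) scheduled moment, deg.
#'
#' @param sweep a `sweep_result`.
#' @return scalar, deg.
#' @export
range_of_motion <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  sweep$dtheta_deg[which.max(sweep$moments)] -
    sweep$dtheta_deg[which.min(sweep$moments)]
}

#' Displacement statistics for an adversarial sweep pair
#'
#' Rows: displacement at the maximum moment (plantarflexion extreme),
#' displacement at the minimum moment (dorsiflexion extreme), and the range
#' of motion, each with the avg / abs_diff / rel_diff convention of
#' [displacement_stats()].
#'
#' @param sweep_A,sweep_B `sweep_result`s over the same schedule.
#' @return data frame with columns `quantity`, `A`, `B`, `avg`, `abs_diff`,
#'   `rel_diff`.
#' @export
sweep_pair_stats <- function(sweep_A, sweep_B) {
  stopifnot(identical(sweep_A$moments, sweep_B$moments))
  i_max <- which.max(sweep_A$moments)
  i_min <- which.min(sweep_A$moments)
  a <- c(sweep_A$dtheta_deg[i_max], sweep_A$dtheta_deg[i_min],
         range_of_motion(sweep_A))
  b <- c(sweep_B$dtheta_deg[i_max], sweep_B$dtheta_deg[i_min],
         range_of_motion(sweep_B))
  st <- displacement_stats(a, b)
  cbind(data.frame(quantity = c(
    sprintf("dtheta(M_ext = %+.2f Nm)", sweep_A$moments[i_max]),
    sprintf("dtheta(M_ext = %+.2f Nm)", sweep_A$moments[i_min]),
    "range of motion"), A = a, B = b), st)
}

#' Per-element force comparison of two sweeps
#'
#' For each of the six ligaments and the contact pair: the maximum over load
#' steps of the absolute force difference |F_A - F_B|, the moment at which
#' that maximum occurs, and the relative difference at that step computed
#' with the same average-denominator convention as [displacement_stats()].
#'
#' @param sweep_A,sweep_B `sweep_result`s over the same schedule.
#' @return data frame with columns `element`, `max_abs_diff_N`,
#'   `at_moment_Nm`, `rel_diff_pct`.
#' @export
force_comparison <- function(sweep_A, sweep_B) {
  stopifnot(identical(sweep_A$moments, sweep_B$moments))
  elements <- colnames(sweep_A$element_forces)
  out <- lapply(seq_along(elements), function(j) {
    fa <- sweep_A$element_forces[, j]
    fb <- sweep_B$element_forces[, j]
    dif <- abs(fa - fb)
    i <- which.max(dif)
    avg <- (fa[i] + fb[i]) / 2
    data.frame(element = elements[j],
               max_abs_diff_N = dif[i],
               at_moment_Nm = sweep_A$moments[i],
               rel_diff_pct = if (avg == 0) {
                 if (dif[i] == 0) 0 else NaN
               } else {
                 dif[i] / abs(avg) * 100
               })
  })
  do.call(rbind, out)
}

#' Multi-seed adversarial search
#'
#' Repeats [run_adversarial()] with GA seeds derived from one master seed
#' and returns every report plus the index of the best run (lowest best h),
#' mirroring the protocol of restarting a stochastic search several times
#' and keeping its best outcome.
#'
#' @param reference a [joint_model()].
#' @param n_seeds number of runs.
#' @param master_seed integer; run k uses `master_seed * 1000 + k`.
#' @param ... passed on to [run_adversarial()].
#' @param pb a [perturbation_bounds()].
#' @param config a [ga_config()]; its `rng_seed` is overridden per run.
#' @return list with `reports`, `best_hs` and `best_index`.
#' @export
run_adversarial_multiseed <- function(reference, n_seeds = 10,
                                      master_seed = 1,
                                      pb = perturbation_bounds(),
                                      config = ga_config(), ...) {
  reports <- vector("list", n_seeds)
  for (k in seq_len(n_seeds)) {
    cfg <- config
    cfg$rng_seed <- as.integer((master_seed * 1000 + k) %% .Machine$integer.max)
    reports[[k]] <- run_adversarial(reference, pb, cfg, ...)
  }
  best_hs <- vapply(reports, function(r) r$ga$best_h, numeric(1))
  list(reports = reports, best_hs = best_hs,
       best_index = which.min(best_hs))
}
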