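# Adversarial encoding and objective: two complete 43-parameter models in one
# 86-element decision vector, scored by the negative weighted L1 distance of
# their moment-rotation curves plus a penalty on non-converged load steps.

W2_PENALTY <- 10.0

#' Split an 86-element decision vector into its two parameter sets
#'
#' @param dv numeric vector of length 86; the first 43 entries encode model
#'   A, the last 43 model B, each in the canonical flattening order.
#' @return list with numeric `A` and `B`, both length 43.
#' @export
split_decision_vector <- function(dv) {
  if (!is.numeric(dv) || length(dv) != 2 * N_PARAMS) {
    stop("decision vector must hold 86 numeric values", call. = FALSE)
  }
  list(A = dv[1:N_PARAMS], B = dv[(N_PARAMS + 1):(2 * N_PARAMS)])
}

#' Endpoint-emphasising weights for the load steps
#'
#' Weight 2 at the first and last load step (the moment extremes), weight 1
#' at all interior steps.
#'
#' @param m_steps number of load steps (>= 2).
#' @return numeric weight vector of length `m_steps`.
#' @export
endpoint_weights <- function(m_steps) {
  if (!is.numeric(m_steps) || length(m_steps) != 1 || m_steps < 2) {
    stop("m_steps must be a single count >= 2", call. = FALSE)
  }
  w <- rep(1, m_steps)
  w[c(1, m_steps)] <- 2
  w
}

#' Weighted L1 distance between two angular-displacement curves
#'
#' @param curve_A,curve_B angular displacements per load step, deg.
#' @param weights per-step weights, same length (default:
#'   [endpoint_weights()]).
#' @return the scalar weighted L1 distance, weighted deg.
#' @export
weighted_l1 <- function(curve_A, curve_B, weights = endpoint_weights(length(curve_A))) {
  if (length(curve_A) != length(curve_B) || length(weights) != length(curve_A)) {
    stop("curves and weights must have equal lengths", call. = FALSE)
  }
  sum(weights * abs(curve_A - curve_B))
}

#' Evaluate the adversarial objective for one decision vector
#'
#' Builds models A and B from the two halves of `dv` (fixed configuration
#' taken from `template`), sweeps both over the schedule, and returns
#' h = -sum_i w1i |dtheta_A,i - dtheta_B,i| + w2 * not_passed, with w2 = 10.00
#' and not_passed summed over both structures. A half that cannot be built
#' into a valid model (for example singular geometry) scores all its steps as
#' failed rather than aborting the search.
#'
#' @param dv 86-element decision vector.
#' @param template a [joint_model()] supplying clearance, contact mode and
#'   reference pose.
#' @param schedule a [load_schedule()].
#' @param control solver control, see [solver_control()].
#' @param engine solver engine, see [sweep_loads()].
#' @return list of class `objective_breakdown`: `h`, `l1_term`, `not_passed`,
#'   `penalty` (= w2 * not_passed) and the two `sweeps` (NULL for a failed
#'   build). `h = -l1_term + penalty` exactly.
#' @export
adversarial_objective <- function(dv, template, schedule = load_schedule(),
                                  control = solver_control(),
                                  engine = c("cpp", "minpack")) {
  engine <- match.arg(engine)
  halves <- split_decision_vector(dv)
  n_steps <- length(schedule$moments)

  eval_half <- function(p) {
    model <- tryCatch(unflatten_model(p, template), error = function(e) NULL)
    if (is.null(model)) {
      return(list(sweep = NULL, dtheta = rep(0, n_steps), np = n_steps))
    }
    sw <- tryCatch(sweep_loads(model, schedule, control, engine),
                   error = function(e) NULL)
    if (is.null(sw)) {
      return(list(sweep = NULL, dtheta = rep(0, n_steps), np = n_steps))
    }
    list(sweep = sw, dtheta = sw$dtheta_deg, np = sw$not_passed)
  }

  A <- eval_half(halves$A)
  B <- eval_half(halves$B)
  l1 <- weighted_l1(A$dtheta, B$dtheta)
  np <- A$np + B$np
  structure(list(h = -l1 + W2_PENALTY * np,
                 l1_term = l1,
                 not_passed = np,
                 penalty = W2_PENALTY * np,
                 sweeps = list(A = A$sweep, B = B$sweep)),
            class = "objective_breakdown")
}

#' @export
print.objective_breakdown <- function(x, ...) {
  cat(sprintf("<objective_breakdown> h = %.4f (l1 = %.4f, not_passed = %d, penalty = %.2f)\n",
              x$h, x$l1_term, x$not_passed, x$penalty))
  invisible(x)
}
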