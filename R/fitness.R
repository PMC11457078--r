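#' Fitness-cost weighting
#'
#' The default (`full_cost`) fitness of the induced strategy charges every
#' produced pathway species equally: `exp(-(B + N + L + P + S + A))`, where
#' bars denote time averages. The `amp_only` variant charges only bacteria
#' and AMP, `exp(-(weight_A * A + weight_B * B))`, modeling a host whose
#' dominant cost is immunopathology rather than protein synthesis; the
#' weights let either bacterial load or AMP production count double.
#'
#' @param weight_A multiplier on the AMP average (amp_only mode).
#' @param weight_B multiplier on the bacterial average (amp_only mode).
#' @param mode `"full_cost"` or `"amp_only"`.
#' @return A `fitness_weights` list.
#' @export
fitness_weights <- function(weight_A = 1, weight_B = 1,
                            mode = c("full_cost", "amp_only")) {
  mode <- match.arg(mode)
  if (weight_A <= 0 || weight_B <= 0) abort("weights must be > 0")
  if (mode == "full_cost" && (weight_A != 1 || weight_B != 1)) {
    abort("full_cost mode uses unit weights")
  }
  structure(list(weight_A = weight_A, weight_B = weight_B, mode = mode),
            class = "fitness_weights")
}

#' Time average of one trajectory component
#'
#' Arithmetic mean of a state variable over the recorded time points of a
#' trajectory.
#'
#' @param traj an `imd_trajectory` from [integrate_model()].
#' @param component column name (`"B"`, `"G"`, ..., `"A"`).
#' @return Scalar mean.
#' @export
time_average <- function(traj, component) {
  stopifnot(inherits(traj, "imd_trajectory"))
  if (nrow(traj) == 0) abort("trajectory is empty")
  if (!component %in% names(traj)) {
    abort(paste0("unknown component: ", component))
  }
  mean(traj[[component]])
}

#' Fitness of the induced strategy
#'
#' `exp(-cost)` where the cost is the sum of the time-averaged produced
#' species. In `full_cost` mode the cost is `B + N + L + P + S + A` (free
#' peptidoglycan, free receptors and the receptor complex are signaling
#' intermediates, not synthesized effectors, and carry no cost); in
#' `amp_only` mode it is `weight_A * A + weight_B * B`.
#'
#' @param means named numeric vector (or one-row data frame) of
#'   non-negative time-averaged components, containing at least the names
#'   the chosen mode uses.
#' @param weights a [fitness_weights()].
#' @return Fitness in (0, 1].
#' @examples
#' fitness_induced(c(B = 1, N = 0, L = 0, P = 0, S = 0, A = 0))
#' @export
fitness_induced <- function(means, weights = fitness_weights()) {
  if (is.data.frame(means)) means <- unlist(means[1, , drop = TRUE])
  need <- if (weights$mode == "full_cost") {
    c("B", "N", "L", "P", "S", "A")
  } else {
    c("B", "A")
  }
  miss <- setdiff(need, names(means))
  if (length(miss) > 0) {
    abort(paste0("means is missing: ", paste(miss, collapse = ", ")))
  }
  m <- means[need]
  if (any(!is.finite(m) & !is.infinite(m)) || any(m < 0)) {
    abort("means must be non-negative")
  }
  cost <- if (weights$mode == "full_cost") sum(m) else
    weights$weight_A * m[["A"]] + weights$weight_B * m[["B"]]
  exp(-cost)
}

#' Fitness of the constitutive strategy
#'
#' `exp(-(B + A))`: the time-averaged bacterial load plus the constant AMP
#' level itself (always on, so the full standing level is charged).
#'
#' @param B_mean non-negative time-averaged bacterial load.
#' @param A_const non-negative constant AMP level.
#' @param weights a [fitness_weights()]; weights apply in `amp_only` mode.
#' @return Fitness in (0, 1].
#' @examples
#' fitness_constitutive(B_mean = 1, A_const = 1)
#' @export
fitness_constitutive <- function(B_mean, A_const,
                                 weights = fitness_weights()) {
  if (is.na(B_mean) || B_mean < 0 || A_const < 0) {
    abort("B_mean and A_const must be >= 0")
  }
  exp(-(weights$weight_B * B_mean + weights$weight_A * A_const))
}

#' Fitness difference between the strategies
#'
#' `delta_F = F_constitutive - F_induced`; negative values mean the
#' induced strategy wins.
#'
#' @param F_constitutive,F_induced fitness values in (0, 1].
#' @return Signed difference.
#' @export
delta_fitness <- function(F_constitutive, F_induced) {
  F_constitutive - F_induced
}

# per-walk fitness from a run_encounter_simulation() summary table;
# strategy fitness over a walk set is mean(per-walk fitness), never the
# fitness of mean components (exp is nonlinear, order matters)
induced_walk_fitness <- function(summaries, weights = fitness_weights()) {
  need <- if (weights$mode == "full_cost") {
    c("B", "N", "L", "P", "S", "A")
  } else {
    c("B", "A")
  }
  apply(as.matrix(summaries[, need, drop = FALSE]), 1, function(m) {
    fitness_induced(setNames(m, need), weights)
  })
}
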