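#' Rate constants and binding energies of the induced Imd model
#'
#' Bundles the 14 rate constants of the nine-equation induced-defense model.
#' Three of them describe the bacteria and their peptidoglycan (PG) signal —
#' `alpha` (PG released per unit bacterial proliferation), `k0` (bacterial
#' proliferation rate in the gut) and `lambda1` (PG degradation rate) — and
#' the remaining 11 describe the host pathway and are the free dimensions of
#' [optimize_induced()]: `lambda2` (shared degradation rate of R, N, L, P, S
#' and A), `lambda3` (receptor–PG complex dissociation rate), `R0` (basal
#' receptor production), `beta1`–`beta6` (Relish-driven production rates of
#' receptors, Relish activation, PGRP-LB, Pirk, repressosome and AMP), and
#' the promoter binding energies `Zn` (Relish) and `Zs` (repressosome).
#' Binding energies are inversely proportional to binding probability, so a
#' smaller `Zs` means stronger repression of AMP transcription.
#'
#' Defaults follow the study conditions used throughout the package:
#' `alpha = 2`, `lambda1 = 0.01`, `k0 = 0.1`; the host parameters default to
#' order-one values and are normally replaced by an optimization run.
#'
#' @param alpha PG-release rate per unit bacterial proliferation.
#' @param k0 bacterial proliferation rate per unit time.
#' @param lambda1 degradation rate of free PG.
#' @param lambda2 shared degradation rate of R, N, L, P, S, A.
#' @param lambda3 dissociation rate of the receptor–PG complex.
#' @param R0 basal receptor production rate.
#' @param beta1,beta2,beta3,beta4,beta5,beta6 production/activation rates
#'   (receptor induction, Relish activation, PGRP-LB, Pirk, repressosome,
#'   AMP).
#' @param Zn binding energy of Relish to its target promoters.
#' @param Zs binding energy of the repressosome at the AMP promoter.
#' @return An object of class `imd_params` (a validated named list).
#' @examples
#' p <- imd_params(k0 = 0.5, beta6 = 2)
#' p$beta6
#' @export
imd_params <- function(alpha = 2, k0 = 0.1, lambda1 = 0.01, lambda2 = 0.1,
                       lambda3 = 0.1, R0 = 0.1, beta1 = 1, beta2 = 1,
                       beta3 = 1, beta4 = 1, beta5 = 1, beta6 = 1,
                       Zn = 5, Zs = 5) {
  p <- list(
    alpha = alpha, k0 = k0, lambda1 = lambda1, lambda2 = lambda2,
    lambda3 = lambda3, R0 = R0, beta1 = beta1, beta2 = beta2,
    beta3 = beta3, beta4 = beta4, beta5 = beta5, beta6 = beta6,
    Zn = Zn, Zs = Zs
  )
  validate_imd_params(p)
  structure(p, class = "imd_params")
}

#' Names of the 11 host parameters optimized by the hill climb
#' @return Character vector of parameter names.
#' @export
free_param_names <- function() {
  c("lambda2", "lambda3", "R0", "beta1", "beta2", "beta3", "beta4",
    "beta5", "beta6", "Zn", "Zs")
}

validate_imd_params <- function(p) {
  need <- c("alpha", "k0", "lambda1", "lambda2", "lambda3", "R0",
            paste0("beta", 1:6), "Zn", "Zs")
  missing <- setdiff(need, names(p))
  if (length(missing) > 0) {
    abort(paste0("imd_params is missing: ", paste(missing, collapse = ", ")))
  }
  vals <- unlist(p[need])
  # production rates may be zero (knockouts); everything else — rates that
  # divide or feed denominators — must be strictly positive
  zero_ok <- paste0("beta", 1:6)
  bad <- need[!is.finite(vals) | vals < 0 |
                (vals == 0 & !need %in% zero_ok)]
  if (length(bad) > 0) {
    abort(paste0("imd_params must be finite and positive ",
                 "(beta rates may be zero); offending: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(p)
}

# numeric vector in the layout the C++ kernels expect
param_vector <- function(p) {
  unlist(p[c("alpha", "k0", "lambda1", "lambda2", "lambda3", "R0",
             paste0("beta", 1:6), "Zn", "Zs")], use.names = FALSE)
}

#' @export
print.imd_params <- function(x, ...) {
  cat("<imd_params>\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 8), " ",
             format(v, digits = 4)), sep = "\n")
  invisible(x)
}

state_names <- function() c("B", "G", "R", "C", "N", "L", "P", "S", "A")

#' Zero initial state of the induced model
#'
#' The naive-host convention: all nine concentrations start at zero (no
#' bacteria, no signaling, no effectors), so the pathway is silent until
#' bacteria arrive.
#'
#' @return Named numeric vector of length 9 (B, G, R, C, N, L, P, S, A).
#' @export
zero_state <- function() setNames(numeric(9), state_names())
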