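#' Isolated side-chain torsion model
#'
#' A one-degree-of-freedom model of a single side-chain-like torsion with a
#' cosine-series potential.  This mirrors how torsional potentials of mean
#' force are produced for boosting-potential fits in the original protocol:
#' the residue of interest is isolated (one helix, other side chains
#' stripped) so that its chi torsion is umbrella-sampled free of binding-site
#' coupling.  Supports the same umbrella bias and boost modifiers as the
#' full binding-site model, at a fraction of the evaluation cost.
#'
#' @param torsion data.frame with columns `k` (kcal/mol), `n`
#'   (multiplicity), `chi0` (degrees).
#' @param temperature Kelvin.
#' @return An object of class `torsion_model`.
#' @export
#' @examples
#' tm <- torsion_model(data.frame(k = 1.5, n = 1, chi0 = 0))
#' total_energy(tm, list(chi = 180))  # 0
torsion_model <- function(torsion = data.frame(k = c(1.5, 0.8), n = c(3L, 1L),
                                               chi0 = c(0, 60)),
                          temperature = .DEFAULT_T) {
  torsion <- as.data.frame(torsion)
  stopifnot(all(c("k", "n", "chi0") %in% names(torsion)))
  structure(list(tk = as.numeric(torsion$k), tn = as.numeric(torsion$n),
                 tchi0 = as.numeric(torsion$chi0), torsion = torsion,
                 temperature = temperature),
            class = "torsion_model")
}

#' @export
initial_state.torsion_model <- function(model, ...) list(chi = 0)

#' @export
total_energy.torsion_model <- function(model, state, ion = NULL,
                                       modifiers = NULL, decompose = FALSE,
                                       ...) {
  chi <- wrap_deg(state$chi[1])
  e_tor <- sum(model$tk * (1 + cos((model$tn * (chi - model$tchi0)) *
                                   (pi / 180))))
  if (!is.null(modifiers$boosts))
    for (bo in modifiers$boosts)
      e_tor <- e_tor - bo$strength * evaluate_boost(bo$bp, chi)
  e_bias <- if (is.null(modifiers$bias)) 0 else {
    d <- wrap_rad((chi - modifiers$bias$center) * (pi / 180))
    0.5 * modifiers$bias$k * d * d
  }
  tot <- e_tor + e_bias
  if (decompose)
    list(coulomb = 0, lj = 0, torsion = e_tor, wall = 0, restraint = 0,
         bias = e_bias, total = tot)
  else tot
}

#' @export
mc_moves.torsion_model <- function(model, state) {
  list(chi = list(count = 1L, default = 40,
                  propose = function(st, i, s) {
                    st$chi <- wrap_deg(st$chi + (stats::runif(1) * 2 - 1) * s)
                    st
                  }))
}

#' @export
print.torsion_model <- function(x, ...) {
  cat(sprintf("isolated torsion model: %d cosine terms, T=%g K\n",
              length(x$tk), x$temperature))
  invisible(x)
}
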