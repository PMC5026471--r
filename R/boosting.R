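#' Boosting potential: a cosine series fitted to a torsional PMF
#'
#' The boosting potential for a side-chain-like torsion chi is
#' \deqn{U_{BP}(\chi) = \sum_{n=1}^{N} k_n \{1 + \cos[n(\chi - \chi_{0,n})]\},}
#' a cosine Fourier series approximating the torsional potential of mean
#' force.  Applied with a reversed sign and a fractional strength it
#' flattens the rotamer barriers of that torsion (see [apply_boost()]).
#'
#' @param k Coefficients k_n, kcal/mol (term n has multiplicity n).
#' @param chi0 Phases chi_0,n, degrees; same length as `k`.
#' @param residue Optional source-residue label.
#' @param residual Optional RMS fit residual, kcal/mol.
#' @param fitted Logical: was this instance produced by
#'   [fit_boosting_potential()]?  Fitted instances must have 3--6 terms.
#' @return An object of class `boost_potential`.
#' @export
boosting_potential <- function(k, chi0, residue = NA_character_,
                               residual = NA_real_, fitted = FALSE) {
  if (length(k) != length(chi0)) stop("k and chi0 lengths differ")
  if (fitted && (length(k) < 3 || length(k) > 6))
    stop("fitted boosting potentials use 3 to 6 cosine terms")
  structure(list(k = as.numeric(k), chi0 = as.numeric(chi0),
                 n_terms = length(k), residue = residue,
                 residual = residual, fitted = fitted),
            class = "boost_potential")
}

#' Evaluate a boosting potential
#'
#' @param bp A [boosting_potential()].
#' @param chi Torsion angle(s), degrees (vectorised); evaluation is
#'   360-degree periodic.
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' bp <- boosting_potential(k = 1, chi0 = 0)
#' evaluate_boost(bp, c(0, 180))  # 2, 0
evaluate_boost <- function(bp, chi) {
  n <- seq_len(bp$n_terms)
  vapply(chi, function(x)
    sum(bp$k * (1 + cos(deg2rad(n * (x - bp$chi0))))), numeric(1))
}

#' Fit a boosting potential to a torsional PMF
#'
#' For each candidate term count N the PMF is fitted, by linear least
#' squares, with the expansion a_n cos(n chi) + b_n sin(n chi) plus a free
#' additive constant (the "+1" of each series term is absorbed into that
#' constant and restored on evaluation, so the result evaluates exactly as
#' the cosine series above).  Coefficients convert to k_n =
#' sqrt(a_n^2 + b_n^2) >= 0 and chi_0,n = atan2(b_n, a_n)/n, making the fit
#' convex and deterministic.  The N with the smallest RMS residual on the
#' PMF grid wins; ties go to the smaller N.
#'
#' @param pmf A [wham_umbrella()] `torsion_pmf`, or a list/data.frame with
#'   elements `chi` (degrees) and `w` (kcal/mol).
#' @param n_range Candidate term counts (default 3:6).
#' @param residue Label carried into the result.
#' @return A fitted [boosting_potential()] with its RMS residual and, as
#'   attribute `"offset"`, the fitted additive constant c such that
#'   `evaluate_boost(bp, chi) + c` approximates the PMF.
#' @export
fit_boosting_potential <- function(pmf, n_range = 3:6,
                                   residue = NA_character_) {
  chi <- pmf$chi
  w <- pmf$w
  keep <- is.finite(w)
  if (sum(keep) < 2 * max(n_range) + 1)
    stop("PMF has too many gaps to fit the requested series")
  covered <- diff(range(chi[keep]))
  if (covered < 300)
    stop("PMF must cover the full torsional period")
  chi <- chi[keep]; w <- w[keep]
  cr <- deg2rad(chi)
  best <- NULL
  for (N in sort(unique(n_range))) {
    X <- cbind(1, do.call(cbind, lapply(seq_len(N), function(n)
      cbind(cos(n * cr), sin(n * cr)))))
    fit <- stats::lm.fit(X, w)
    rms <- sqrt(mean(fit$residuals^2))
    if (is.null(best) || rms < best$rms - 1e-12) {
      cf <- fit$coefficients
      a <- cf[seq(2, 2 * N, by = 2)]
      b <- cf[seq(3, 2 * N + 1, by = 2)]
      best <- list(N = N, a = a, b = b, c0 = cf[1], rms = rms)
    }
  }
  k <- sqrt(best$a^2 + best$b^2)
  chi0 <- rad2deg(atan2(best$b, best$a) / seq_len(best$N))
  bp <- boosting_potential(k, chi0, residue = residue, residual = best$rms,
                           fitted = TRUE)
  attr(bp, "offset") <- unname(best$c0 - sum(k))
  bp
}

#' Apply a boosting potential to a model torsion
#'
#' Modifies one ligand's torsion potential to intrinsic minus
#' `strength * U_BP(chi)`: the sign of the boosting potential is reversed so
#' that, at full strength on a torsion whose intrinsic potential equals
#' U_BP, the rotamer barriers cancel exactly.  `strength = 0` returns a
#' model whose energies are bit-identical to the input.
#'
#' @param model A [binding_site_model()].
#' @param torsion Ligand index or id.
#' @param bp A [boosting_potential()].
#' @param strength Boost strength s in \[0, 1\].
#' @return The modified model.
#' @export
apply_boost <- function(model, torsion, bp, strength) {
  stopifnot(inherits(model, "binding_site_model"),
            inherits(bp, "boost_potential"))
  if (strength < 0 || strength > 1) stop("strength must lie in [0, 1]")
  idx <- resolve_ligand(model, torsion)
  if (strength == 0) return(model)
  add <- data.frame(k = -strength * bp$k, n = seq_len(bp$n_terms),
                    chi0 = bp$chi0)
  model$ligands[[idx]]$torsion <- rbind(model$ligands[[idx]]$torsion, add)
  precompute_site_tables(model)
}

#' @export
print.boost_potential <- function(x, ...) {
  cat(sprintf("boosting potential%s: %d cosine terms%s\n",
              if (is.na(x$residue)) "" else paste0(" [", x$residue, "]"),
              x$n_terms,
              if (is.na(x$residual)) ""
              else sprintf(", RMS residual %.3g kcal/mol", x$residual)))
  print(data.frame(n = seq_len(x$n_terms), k = x$k, chi0 = x$chi0),
        row.names = FALSE)
  invisible(x)
}
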