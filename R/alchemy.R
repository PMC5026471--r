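#' Lambda schedules for the alchemical legs
#'
#' Returns the default coupling schedule for one alchemical leg: evenly
#' spaced lambda values in \[0, 1\] including both endpoints.  Default window
#' counts per leg follow the study protocol: 16 for the binding-site ion
#' swap, 11 for the bulk ion swap, 16 for the restraint-decoupling legs, 24
#' for the binding-site deprotonation and 10 for the bulk deprotonation.
#'
#' @param leg One of `"site_ion_swap"`, `"bulk_ion_swap"`,
#'   `"trans_decouple_Na"`, `"trans_decouple_K"`, `"deprot_site"`,
#'   `"deprot_bulk"`.
#' @param n Optional window-count override (>= 2).
#' @return Numeric vector of lambda values, ascending, with attribute
#'   `"leg"`.
#' @export
lambda_schedule <- function(leg = c("site_ion_swap", "bulk_ion_swap",
                                    "trans_decouple_Na", "trans_decouple_K",
                                    "deprot_site", "deprot_bulk"),
                            n = NULL) {
  leg <- match.arg(leg)
  defaults <- c(site_ion_swap = 16, bulk_ion_swap = 11,
                trans_decouple_Na = 16, trans_decouple_K = 16,
                deprot_site = 24, deprot_bulk = 10)
  n <- as.integer(n %||% defaults[[leg]])
  if (n < 2) stop("a schedule needs at least the two endpoints")
  structure(seq(0, 1, length.out = n), leg = leg)
}

# shared estimator: WHAM over a cross-energy matrix plus 10-block error on
# the end-to-end free-energy difference
fep_from_cross <- function(xmat, n_blocks = 10, label = "fep",
                           ess_warn = 50) {
  wh <- wham_multistate(xmat)
  K <- nrow(xmat$u)
  dg <- wh$f[K] - wh$f[1]
  if (any(wh$ess < ess_warn))
    warning(sprintf(
      "poor phase-space overlap: min effective sample size %.1f < %d",
      min(wh$ess), ess_warn), call. = FALSE)
  bid <- unlist(lapply(xmat$n_k, block_index, n_blocks = n_blocks))
  dg_blocks <- vapply(seq_len(n_blocks), function(b) {
    cols <- bid == b
    sub <- structure(list(u = xmat$u[, cols, drop = FALSE],
                          origin = xmat$origin[cols],
                          n_k = tabulate(xmat$origin[cols], nbins = K),
                          temperature = xmat$temperature),
                     class = "cross_energy")
    wb <- wham_multistate(sub)
    wb$f[K] - wb$f[1]
  }, numeric(1))
  structure(list(dg = dg, err = stats::sd(dg_blocks), f = wh$f,
                 dg_blocks = dg_blocks, ess = wh$ess, wham = wh,
                 n_frames = sum(xmat$n_k), label = label,
                 temperature = xmat$temperature),
            class = "fep_result")
}

#' @export
print.fep_result <- function(x, ...) {
  cat(sprintf("%s: dG = %.3f +/- %.3f kcal/mol (%d states, %d frames)\n",
              x$label, x$dg, x$err, length(x$f), x$n_frames))
  invisible(x)
}

#' Three-point alchemical ion transformation at a site
#'
#' Estimates the free energy of transforming one ion species into another in
#' a binding environment with the three-point interpolation protocol: three
#' samplings are run -- the starting ion, the hybrid at the middle of the
#' linear Lennard-Jones/pair-override interpolation, and the final ion.
#' Every frame is cross-evaluated under all three parameter sets and the two
#' adjacent free-energy differences are solved self-consistently with
#' multistate WHAM; their sum is the reported transformation free energy,
#' with a 10-block error.
#'
#' Works on binding-site models (giving the site leg) and on bulk droplet
#' models (giving the bulk leg).
#'
#' @param model A model containing a mobile ion.
#' @param from,to [ion_params()] of the two end states (default packaged
#'   Na+ and K+).
#' @param n_steps MC steps per state.
#' @param seed Base seed; state `i` uses `seed + i - 1`.
#' @param thin,tune,n_tune Sampling controls passed to [run_mc()].
#' @param n_blocks Blocks for the error estimate.
#' @param ess_warn Overlap diagnostic: warn when any state's effective
#'   sample size falls below this many frames.
#' @return A `fep_result` with fields `dg` (kcal/mol, from -> to), `err`,
#'   per-state free energies `f` (the middle entry is the hybrid), `ess`,
#'   and block estimates.
#' @export
three_point_alchemy <- function(model, from = default_ion_params("Na"),
                                to = default_ion_params("K"),
                                n_steps = 3000, seed = 1, thin = 5L,
                                tune = TRUE, n_tune = 600L, n_blocks = 10,
                                ess_warn = 50) {
  if (is.null(model$ion)) stop("model has no bound ion to transform")
  lambdas <- c(0, 0.5, 1)
  mods <- lapply(lambdas, function(l)
    list(ion = interpolate_ion_params(from, to, l)))
  series <- lapply(seq_along(lambdas), function(i)
    run_mc(model, n_steps = n_steps, seed = seed + i - 1L, thin = thin,
           tune = tune, n_tune = n_tune, modifiers = mods[[i]],
           scenario = sprintf("alchemy_lambda%.2f", lambdas[i])))
  xmat <- cross_energies(model, series, mods)
  fep_from_cross(xmat, n_blocks = n_blocks, ess_warn = ess_warn,
                 label = sprintf("%s->%s", from$species, to$species))
}

#' Restraint-decoupling leg for one ion species
#'
#' Gradually switches the translational/orientational restraint off along a
#' coupling schedule (restraint scale 1-lambda), samples every window, and
#' combines the windows with multistate WHAM.  The returned free energy is
#' the cost of releasing the restraint, G(unrestrained) - G(restrained),
#' for the given species; the species difference enters the selectivity
#' decomposition (see [assemble_binding_dg()]).
#'
#' @param model A restrained [binding_site_model()].
#' @param ion [ion_params()] of the bound species.
#' @param lambdas Decoupling schedule from [lambda_schedule()] (0 = fully
#'   restrained, 1 = restraint off).
#' @param n_steps MC steps per window.
#' @param seed Base seed.
#' @param thin,tune,n_tune,n_blocks As in [three_point_alchemy()].
#' @return A `fep_result`; `dg` is the release free energy in kcal/mol.
#' @export
decouple_restraint_leg <- function(model, ion = model$ion,
                                   lambdas = lambda_schedule("trans_decouple_Na", n = 8),
                                   n_steps = 1500, seed = 1, thin = 5L,
                                   tune = TRUE, n_tune = 400L,
                                   n_blocks = 10) {
  if (is.null(model$restraint))
    stop("model carries no restraint to decouple")
  scales <- 1 - lambdas
  series <- lapply(seq_along(scales), function(i)
    run_mc(model, n_steps = n_steps, seed = seed + i - 1L, thin = thin,
           tune = tune, n_tune = n_tune,
           modifiers = list(ion = ion, restraint_scale = scales[i]),
           scenario = sprintf("decouple_s%.3f", scales[i])))
  # the restraint enters linearly, so cross energies decompose exactly into
  # a base term and the per-frame restraint energy
  base <- unlist(lapply(series, function(s) vapply(s$states, function(f)
    total_energy(model, f, modifiers = list(ion = ion, restraint_scale = 0)),
    numeric(1))))
  urest <- unlist(lapply(series, function(s) vapply(s$states, function(f)
    restraint_energy(f$ion, model$restraint, model$anchors), numeric(1))))
  u <- outer(scales, urest) + matrix(base, nrow = length(scales),
                                     ncol = length(base), byrow = TRUE)
  n_k <- vapply(series, function(s) length(s$states), integer(1))
  xmat <- structure(list(u = u, origin = rep(seq_along(series), n_k),
                         n_k = n_k, temperature = series[[1]]$temperature),
                    class = "cross_energy")
  fep_from_cross(xmat, n_blocks = n_blocks,
                 label = sprintf("release_%s", ion$species))
}

#' Deprotonation leg (charge-scaling alchemy)
#'
#' Gradually deprotonates one protonatable ligand (or the droplet solute)
#' along evenly spaced lambda windows: the terminal formal charge is
#' interpolated linearly from the protonated (neutral) to the deprotonated
#' (charged) set, charges only.  Windows are combined with multistate WHAM
#' and a block error is attached.  Run once on the binding-site model and
#' once on a bulk droplet with the same solute to feed [pka_from_legs()].
#'
#' @param model A [binding_site_model()] or [bulk_droplet_model()] (the
#'   latter must carry a protonatable `solute`).
#' @param target Ligand index/id for binding sites (ignored for droplets).
#' @param lambdas Schedule, e.g. `lambda_schedule("deprot_site")`; defaults
#'   to 24 windows for binding sites and 10 for droplets.
#' @param n_steps MC steps per window.
#' @param seed Base seed.
#' @param thin,tune,n_tune,n_blocks As in [three_point_alchemy()].
#' @return A `fep_result`; `dg` is the deprotonation free energy,
#'   protonated -> deprotonated, in kcal/mol.
#' @export
deprotonation_leg <- function(model, target = 1, lambdas = NULL,
                              n_steps = 1200, seed = 1, thin = 5L,
                              tune = TRUE, n_tune = 400L, n_blocks = 10) {
  is_droplet <- inherits(model, "bulk_droplet_model")
  if (is_droplet && is.null(model$solute))
    stop("droplet has no protonatable solute")
  if (!is_droplet) {
    idx <- resolve_ligand(model, target)
    if (model$ligands[[idx]]$charge == 0)
      stop("target ligand is not protonatable")
    target <- idx
  }
  lambdas <- lambdas %||%
    lambda_schedule(if (is_droplet) "deprot_bulk" else "deprot_site")
  mods <- lapply(lambdas, function(l)
    list(deprot = list(id = target, lambda = l)))
  series <- lapply(seq_along(lambdas), function(i)
    run_mc(model, n_steps = n_steps, seed = seed + i - 1L, thin = thin,
           tune = tune, n_tune = n_tune, modifiers = mods[[i]],
           scenario = sprintf("deprot_l%.3f", lambdas[i])))
  xmat <- cross_energies(model, series, mods)
  fep_from_cross(xmat, n_blocks = n_blocks, label = "deprotonation")
}
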