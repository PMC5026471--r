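# Metropolis Monte Carlo engine shared by run_mc, umbrella_scan and the
# replica-exchange driver.  Only equilibrium averages feed the estimators
# downstream, so MC replaces the dynamics of the original protocol; step
# counts play the role of simulation-time budgets.

# move catalogue per model class: names, target counts, proposal functions
mc_moves <- function(model, state) UseMethod("mc_moves")

#' @export
mc_moves.binding_site_model <- function(model, state) {
  n <- model$tables$n
  list(
    ion = list(count = 1L, default = 0.3,
               propose = function(st, i, s) {
                 st$ion <- st$ion + stats::rnorm(3, sd = s); st
               }),
    chi = list(count = n, default = 40,
               propose = function(st, i, s) {
                 st$chi[i] <- wrap_deg(st$chi[i] + (stats::runif(1) * 2 - 1) * s)
                 st
               }))
}

#' @export
mc_moves.bulk_droplet_model <- function(model, state) {
  mv <- list(
    solv_trans = list(count = model$n_solvent, default = 0.4,
                      propose = function(st, i, s) {
                        st$solvent_pos[i, ] <- st$solvent_pos[i, ] +
                          stats::rnorm(3, sd = s); st
                      }),
    solv_rot = list(count = model$n_solvent, default = 0.6,
                    propose = function(st, i, s) {
                      d <- st$solvent_dir[i, ] + stats::rnorm(3, sd = s)
                      st$solvent_dir[i, ] <- d / vnorm(d); st
                    }))
  if (!is.null(model$ion))
    mv$ion <- list(count = 1L, default = 0.3,
                   propose = function(st, i, s) {
                     st$ion <- st$ion + stats::rnorm(3, sd = s); st
                   })
  if (!is.null(model$solute))
    mv$chi <- list(count = 1L, default = 40,
                   propose = function(st, i, s) {
                     st$chi <- wrap_deg(st$chi + (stats::runif(1) * 2 - 1) * s)
                     st
                   })
  mv
}

#' @export
mc_moves.toy_model <- function(model, state) {
  list(coord = list(count = length(model$state0), default = 0.5,
                    propose = function(st, i, s) {
                      st$x[i] <- st$x[i] + stats::rnorm(1, sd = s); st
                    }))
}

# raw Metropolis chain; caller owns the RNG stream.  Returns final state and
# (optionally thinned) recorded frames.
mc_chunk <- function(model, state, n_steps, sizes, beta, modifiers = NULL,
                     thin = 0L, energy = NULL) {
  moves <- mc_moves(model, state)
  sizes <- sizes[names(moves)]
  counts <- vapply(moves, function(m) as.numeric(m$count), numeric(1))
  pcum <- cumsum(counts) / sum(counts)
  e <- energy %||% total_energy(model, state, modifiers = modifiers)
  if (!is.finite(e)) stop("non-finite energy at chain start")
  nt <- length(moves)
  acc <- att <- stats::setNames(numeric(nt), names(moves))
  rec <- thin > 0L
  nrec <- if (rec) n_steps %/% thin else 0L
  frames <- if (rec) vector("list", nrec)
  energies <- if (rec) numeric(nrec)
  ri <- 0L
  for (step in seq_len(n_steps)) {
    ti <- findInterval(stats::runif(1), pcum) + 1L
    mv <- moves[[ti]]
    tgt <- if (mv$count > 1L) sample.int(mv$count, 1L) else 1L
    prop <- mv$propose(state, tgt, sizes[[ti]])
    e2 <- total_energy(model, prop, modifiers = modifiers)
    if (is.nan(e2)) stop("NaN energy encountered during sampling")
    att[ti] <- att[ti] + 1
    if (e2 <= e || stats::runif(1) < exp(-beta * (e2 - e))) {
      state <- prop
      e <- e2
      acc[ti] <- acc[ti] + 1
    }
    if (rec && step %% thin == 0L) {
      ri <- ri + 1L
      frames[[ri]] <- state
      energies[ri] <- e
    }
  }
  list(state = state, energy = e, frames = frames, energies = energies,
       acc = acc, att = att)
}

# short pre-run that adapts step sizes towards 30-50% acceptance, then
# freezes them (tuning never overlaps production)
tune_step_sizes <- function(model, state, sizes, beta, modifiers,
                            n_tune = 600L, batch = 120L) {
  done <- 0L
  while (done < n_tune) {
    nb <- min(batch, n_tune - done)
    out <- mc_chunk(model, state, nb, sizes, beta, modifiers)
    state <- out$state
    rate <- ifelse(out$att > 0, out$acc / out$att, NA)
    for (nm in names(sizes)) {
      if (is.na(rate[nm])) next
      if (rate[nm] > 0.5) sizes[nm] <- sizes[nm] * 1.25
      else if (rate[nm] < 0.3) sizes[nm] <- sizes[nm] * 0.8
    }
    if ("chi" %in% names(sizes)) sizes["chi"] <- min(sizes["chi"], 180)
    done <- done + nb
  }
  list(sizes = sizes, state = state)
}

#' Run a Metropolis Monte Carlo sampling of a model
#'
#' Samples the Boltzmann distribution of `model` (optionally under modified
#' potentials) with a Metropolis acceptance criterion.  The move set mixes
#' Gaussian ion displacements with uniform single-torsion rotations (plus
#' solvent translations/rotations for droplets); a frozen pre-run tunes each
#' move size towards 30--50% acceptance before production starts.  Identical
#' `(model, seed, n_steps)` give bit-identical output.
#'
#' @param model A `binding_site_model`, `bulk_droplet_model` or `toy_model`.
#' @param n_steps Number of production MC steps (> 0).
#' @param seed Integer RNG seed (recorded in the output).
#' @param temperature Kelvin; defaults to the model temperature.
#' @param modifiers Potential modifiers, see [total_energy()].
#' @param state Starting state; defaults to [initial_state()].
#' @param thin Record every `thin`-th step.
#' @param tune Run the step-size tuning pre-phase?
#' @param n_tune Tuning steps (discarded).
#' @param step_sizes Named numeric vector overriding the per-move-type step
#'   sizes (and skipping tuning for those types).
#' @param scenario Free-text tag stored in the series.
#' @return An object of class `sample_series`: recorded states, energies
#'   (kcal/mol, including any bias), per-move-type acceptance fractions, and
#'   the sampling metadata (seed, temperature, thinning).
#' @export
run_mc <- function(model, n_steps, seed, temperature = NULL,
                   modifiers = NULL, state = NULL, thin = 10L, tune = TRUE,
                   n_tune = 600L, step_sizes = NULL, scenario = "mc") {
  if (!is.numeric(n_steps) || n_steps < 1) stop("n_steps must be > 0")
  n_steps <- as.integer(n_steps)
  thin <- max(1L, as.integer(thin))
  if (missing(seed)) stop("a seed is required")
  temperature <- temperature %||% model$temperature
  beta <- 1 / (.KB * temperature)
  set.seed(as.integer(seed))
  state <- state %||% initial_state(model)
  moves <- mc_moves(model, state)
  sizes <- vapply(moves, `[[`, numeric(1), "default")
  if (!is.null(step_sizes)) sizes[names(step_sizes)] <- step_sizes
  if (any(sizes <= 0)) stop("move sizes must be positive (zero-measure move set)")
  if (tune) {
    tn <- tune_step_sizes(model, state, sizes, beta, modifiers,
                          n_tune = as.integer(n_tune))
    sizes <- tn$sizes
    state <- tn$state
    if (!is.null(step_sizes)) sizes[names(step_sizes)] <- step_sizes
  }
  out <- mc_chunk(model, state, n_steps, sizes, beta, modifiers, thin = thin)
  if (!length(out$frames)) stop("no frames recorded; decrease thin")
  series_from_frames(out, model, modifiers, scenario, seed, temperature,
                     thin, n_steps, sizes)
}

series_from_frames <- function(out, model, modifiers, scenario, seed,
                               temperature, thin, n_steps, sizes) {
  frames <- out$frames
  ion <- if (!is.null(frames[[1]]$ion))
    t(vapply(frames, `[[`, numeric(3), "ion"))
  chi <- if (!is.null(frames[[1]]$chi) && length(frames[[1]]$chi)) {
    matrix(unlist(lapply(frames, function(f) as.numeric(f$chi))),
           nrow = length(frames), byrow = TRUE)
  }
  structure(list(scenario = scenario, states = frames, ion = ion, chi = chi,
                 energy = out$energies, n_steps = n_steps, thin = thin,
                 seed = as.integer(seed), temperature = temperature,
                 acceptance = ifelse(out$att > 0, out$acc / out$att, NA),
                 step_sizes = sizes, bias = modifiers$bias),
            class = "sample_series")
}

#' @export
print.sample_series <- function(x, ...) {
  cat(sprintf("sample series '%s': %d frames (thin %d), T=%g K, seed %d\n",
              x$scenario, length(x$energy), x$thin, x$temperature, x$seed))
  cat("  acceptance:",
      paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance),
            collapse = ", "), "\n")
  invisible(x)
}

#' Umbrella window protocol for a torsional scan
#'
#' Default protocol: windows every 5 degrees around the full period (72
#' windows) with a harmonic bias of 100 kcal/mol/rad^2.
#'
#' @param spacing Window spacing in degrees; must divide 360.
#' @param force_k Bias force constant, kcal/mol/rad^2 (>= 0; 0 gives a
#'   single unbiased window protocol when combined with `spacing = 360`).
#' @return data.frame with columns `index`, `center` (degrees), `k`.
#' @export
#' @examples
#' nrow(umbrella_windows())  # 72
umbrella_windows <- function(spacing = 5, force_k = 100) {
  if (spacing <= 0 || 360 %% spacing != 0)
    stop("spacing must be a positive divisor of 360")
  if (force_k < 0) stop("force constant must be >= 0")
  centers <- seq(-180, 180 - spacing, by = spacing)
  data.frame(index = seq_along(centers), center = centers, k = force_k)
}

#' Umbrella-sampling scan of one torsion
#'
#' Runs one biased MC sampling per umbrella window on the chosen torsion;
#' each output series carries its bias specification, and its recorded
#' energies are the biased ones (unbiased + harmonic window bias).
#' Feed the result to [wham_umbrella()] to recover the torsional potential
#' of mean force.
#'
#' @param model A model with at least one torsion.
#' @param torsion Ligand index (or id) of the torsion to scan.
#' @param windows data.frame from [umbrella_windows()].
#' @param n_steps MC steps per window.
#' @param seed Base seed; window `i` uses `seed + i - 1`.
#' @param thin,step_chi Sampling controls (fixed torsion step, no tuning,
#'   so the per-window protocol is identical).
#' @return List of [run_mc()] series, one per window.
#' @export
umbrella_scan <- function(model, torsion = 1, windows = umbrella_windows(),
                          n_steps = 500, seed = 1, thin = 5L,
                          step_chi = 10) {
  if (!nrow(windows)) stop("window list is empty")
  if (anyDuplicated(windows$center)) stop("duplicate window centers")
  ti <- resolve_ligand(model, torsion)
  lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    st <- initial_state(model)
    st$chi[ti] <- w$center
    run_mc(model, n_steps = n_steps, seed = seed + i - 1L,
           modifiers = list(bias = list(torsion = ti, center = w$center,
                                        k = w$k, index = w$index)),
           state = st, thin = thin, tune = FALSE,
           step_sizes = c(chi = step_chi),
           scenario = sprintf("umbrella_w%03d", w$index))
  })
}
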