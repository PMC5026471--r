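#' Two-dimensional replica-exchange topology
#'
#' Builds the replica topology of the boosted alchemical scheme: `n_lambda`
#' alchemical windows, each coupled to `n_boost` replicas whose boosting
#' strength scales from 0 to 1.  Exchange edges exist only (a) between
#' neighbouring boost levels within one lambda window and (b) between
#' neighbouring lambda windows at zero boost, so the edge count is
#' `n_lambda * (n_boost - 1) + (n_lambda - 1)`.  The study-scale topology
#' (16, 8) has 128 replicas and 127 edges.
#'
#' @param n_lambda Number of alchemical windows (>= 1).
#' @param n_boost Number of boost levels per window (>= 1).
#' @param lambda_values,boost_values Optional value grids (ascending;
#'   boosts must start at 0); default evenly spaced in \[0, 1\].
#' @return An object of class `replica_topology` with a `replicas`
#'   data.frame (`index`, `i_lambda`, `i_boost`, `lambda`, `boost`) and an
#'   `edges` data.frame (`a`, `b`, `type`).
#' @export
#' @examples
#' topo <- build_topology(16, 8)
#' nrow(topo$replicas); nrow(topo$edges)  # 128, 127
build_topology <- function(n_lambda, n_boost,
                           lambda_values = NULL, boost_values = NULL) {
  if (n_lambda < 1 || n_boost < 1) stop("replica counts must be >= 1")
  n_lambda <- as.integer(n_lambda); n_boost <- as.integer(n_boost)
  lambda_values <- lambda_values %||%
    (if (n_lambda == 1) 0 else seq(0, 1, length.out = n_lambda))
  boost_values <- boost_values %||%
    (if (n_boost == 1) 0 else seq(0, 1, length.out = n_boost))
  stopifnot(length(lambda_values) == n_lambda,
            length(boost_values) == n_boost)
  if (is.unsorted(lambda_values, strictly = TRUE) && n_lambda > 1)
    stop("lambda values must be ascending")
  if (boost_values[1] != 0) stop("the first boost strength must be 0")
  idx <- function(il, ib) (il - 1L) * n_boost + ib
  replicas <- data.frame(
    index = idx(rep(seq_len(n_lambda), each = n_boost),
                rep(seq_len(n_boost), n_lambda)),
    i_lambda = rep(seq_len(n_lambda), each = n_boost),
    i_boost = rep(seq_len(n_boost), n_lambda))
  replicas$lambda <- lambda_values[replicas$i_lambda]
  replicas$boost <- boost_values[replicas$i_boost]
  edges <- list()
  for (il in seq_len(n_lambda))
    for (ib in seq_len(n_boost - 1L))
      edges[[length(edges) + 1L]] <-
        data.frame(a = idx(il, ib), b = idx(il, ib + 1L), type = "boost")
  for (il in seq_len(max(0L, n_lambda - 1L)))
    edges[[length(edges) + 1L]] <-
      data.frame(a = idx(il, 1L), b = idx(il + 1L, 1L), type = "lambda")
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(a = integer(), b = integer(), type = character())
  structure(list(n_lambda = n_lambda, n_boost = n_boost,
                 lambda_values = lambda_values, boost_values = boost_values,
                 replicas = replicas, edges = edges),
            class = "replica_topology")
}

#' @export
print.replica_topology <- function(x, ...) {
  cat(sprintf("replica topology: %d lambda x %d boost = %d replicas, %d exchange edges\n",
              x$n_lambda, x$n_boost, nrow(x$replicas), nrow(x$edges)))
  invisible(x)
}

#' Metropolis exchange attempt between two replicas
#'
#' Attempts to swap the configurations of two replicas under their
#' respective potentials with the replica-exchange criterion: the swap is
#' accepted with probability `min(1, exp(-beta * Delta))` where
#' `Delta = [U_a(x_b) + U_b(x_a)] - [U_a(x_a) + U_b(x_b)]`.  Consumes one
#' uniform variate from the R RNG stream when the decision is not forced.
#'
#' @param state_a,state_b Current configurations of the two replicas.
#' @param u_a,u_b Potential functions (`state -> kcal/mol`).
#' @param temperature Kelvin.
#' @return List with `accepted` (logical) and `delta` (kcal/mol).
#' @export
attempt_exchange <- function(state_a, state_b, u_a, u_b,
                             temperature = .DEFAULT_T) {
  delta <- (u_a(state_b) + u_b(state_a)) - (u_a(state_a) + u_b(state_b))
  if (is.nan(delta)) stop("NaN exchange energy")
  accepted <- if (delta <= 0) TRUE
              else if (!is.finite(delta)) FALSE
              else stats::runif(1) < exp(-delta / (.KB * temperature))
  list(accepted = accepted, delta = delta)
}

#' Run the boosted alchemical replica-exchange sampler
#'
#' Drives the two-dimensional replica topology: every replica samples its
#' own modified potential (its lambda window's alchemical parameters plus
#' its boost level's scaled boosting potentials) with short MC bouts, and
#' after each sweep every allowed edge is attempted once in alternating
#' even/odd order.  Only the zero-boost replicas contribute frames to the
#' downstream estimators; boosted replicas exist to shuttle rotamer
#' transitions down to them.
#'
#' @param model The base model.
#' @param topology A [build_topology()] object.
#' @param make_modifiers Function `(lambda, boost) -> modifiers` defining
#'   each replica's potential (see [total_energy()]).
#' @param n_sweeps Number of sweeps; one frame per zero-boost replica is
#'   recorded per sweep.
#' @param steps_per_sweep MC steps per replica between exchange rounds.
#' @param seed Integer seed for the whole replica walk.
#' @param temperature Kelvin.
#' @param exchange Set `FALSE` to freeze exchanges (independent-window
#'   reference mode).
#' @param tune,n_tune Step-size tuning (done once on the base potential and
#'   shared by all replicas).
#' @return A list with `frames` (per lambda window: list of zero-boost
#'   states), `energies` (matching self-energies), `exchange_stats`
#'   (per-edge attempts/accepts data.frame), `visits` (configuration ->
#'   boost-level visit counts), `topology`, `seed`.
#' @export
run_hremd <- function(model, topology, make_modifiers, n_sweeps = 50,
                      steps_per_sweep = 40, seed = 1,
                      temperature = model$temperature, exchange = TRUE,
                      tune = TRUE, n_tune = 400L) {
  stopifnot(inherits(topology, "replica_topology"))
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  beta <- 1 / (.KB * temperature)
  reps <- topology$replicas
  R <- nrow(reps)
  mods <- lapply(seq_len(R), function(r)
    make_modifiers(reps$lambda[r], reps$boost[r]))
  st0 <- initial_state(model)
  moves <- mc_moves(model, st0)
  sizes <- vapply(moves, `[[`, numeric(1), "default")
  if (tune) {
    tn <- tune_step_sizes(model, st0, sizes, beta, mods[[1]],
                          n_tune = as.integer(n_tune))
    sizes <- tn$sizes
  }
  states <- rep(list(st0), R)
  config_id <- seq_len(R)             # configuration labels walk with swaps
  visits <- matrix(0L, R, topology$n_boost,
                   dimnames = list(NULL, NULL))
  edges <- topology$edges
  ne <- nrow(edges)
  att <- acc <- integer(ne)
  zb <- which(reps$i_boost == 1L)     # zero-boost replicas, one per lambda
  frames <- lapply(zb, function(i) vector("list", n_sweeps))
  energies <- lapply(zb, function(i) numeric(n_sweeps))
  names(frames) <- names(energies) <- sprintf("lambda_%02d", seq_along(zb))
  for (sw in seq_len(n_sweeps)) {
    for (r in seq_len(R)) {
      out <- mc_chunk(model, states[[r]], steps_per_sweep, sizes, beta,
                      mods[[r]])
      states[[r]] <- out$state
    }
    if (exchange && ne) {
      order_groups <- list(seq(1L, ne, by = 2L),
                           if (ne > 1) seq(2L, ne, by = 2L) else integer())
      for (grp in order_groups) for (e in grp) {
        a <- edges$a[e]; b <- edges$b[e]
        res <- attempt_exchange(states[[a]], states[[b]],
                                function(s) total_energy(model, s, modifiers = mods[[a]]),
                                function(s) total_energy(model, s, modifiers = mods[[b]]),
                                temperature = temperature)
        att[e] <- att[e] + 1L
        if (res$accepted) {
          tmp <- states[[a]]; states[[a]] <- states[[b]]; states[[b]] <- tmp
          tmp <- config_id[a]; config_id[a] <- config_id[b]; config_id[b] <- tmp
          acc[e] <- acc[e] + 1L
        }
      }
    }
    for (r in seq_len(R))
      visits[config_id[r], reps$i_boost[r]] <-
        visits[config_id[r], reps$i_boost[r]] + 1L
    for (j in seq_along(zb)) {
      frames[[j]][[sw]] <- states[[zb[j]]]
      energies[[j]][sw] <- total_energy(model, states[[zb[j]]],
                                        modifiers = mods[[zb[j]]])
    }
  }
  stats <- cbind(edges, data.frame(attempts = att, accepts = acc,
                                   rate = ifelse(att > 0, acc / att, NA)))
  list(frames = frames, energies = energies, exchange_stats = stats,
       visits = visits, topology = topology, seed = as.integer(seed),
       temperature = temperature, modifiers = mods[zb])
}

#' Alchemical ion swap via boosted replica exchange
#'
#' Convenience wrapper composing [build_topology()], [run_hremd()] and
#' [wham_multistate()]: transforms `from` into `to` across `n_lambda`
#' windows, each with `n_boost` boost levels applying the given boosting
#' potentials, and estimates the transformation free energy from the
#' zero-boost frames only.
#'
#' @param model A [binding_site_model()].
#' @param from,to End-state [ion_params()].
#' @param n_lambda,n_boost Topology dimensions.
#' @param boosts List of `list(id=, bp=)` boosting assignments (strength is
#'   scaled by each replica's boost level).
#' @param n_sweeps,steps_per_sweep,seed,exchange Passed to [run_hremd()].
#' @param n_blocks Blocks for the error estimate.
#' @return A `fep_result` (see [three_point_alchemy()]).
#' @export
hremd_ion_swap <- function(model, from = default_ion_params("Na"),
                           to = default_ion_params("K"), n_lambda = 4,
                           n_boost = 1, boosts = list(), n_sweeps = 150,
                           steps_per_sweep = 30, seed = 1, exchange = TRUE,
                           n_blocks = 10) {
  topo <- build_topology(n_lambda, n_boost)
  mk <- function(lambda, boost) {
    mods <- list(ion = interpolate_ion_params(from, to, lambda))
    if (length(boosts) && boost > 0)
      mods$boosts <- lapply(boosts, function(b)
        list(id = b$id, bp = b$bp, strength = boost))
    mods
  }
  out <- run_hremd(model, topo, mk, n_sweeps = n_sweeps,
                   steps_per_sweep = steps_per_sweep, seed = seed,
                   exchange = exchange)
  # cross-evaluate zero-boost frames under every lambda's ion parameters
  lam <- topo$lambda_values
  ion_mods <- lapply(lam, function(l)
    list(ion = interpolate_ion_params(from, to, l)))
  frames <- unlist(out$frames, recursive = FALSE)
  n_k <- vapply(out$frames, length, integer(1))
  u <- matrix(NA_real_, length(lam), length(frames))
  for (k in seq_along(lam))
    u[k, ] <- vapply(frames, function(f)
      total_energy(model, f, modifiers = ion_mods[[k]]), numeric(1))
  xmat <- structure(list(u = u, origin = rep(seq_along(lam), n_k),
                         n_k = n_k, temperature = out$temperature),
                    class = "cross_energy")
  res <- fep_from_cross(xmat, n_blocks = n_blocks,
                        label = sprintf("%s->%s (H-REMD)", from$species,
                                        to$species))
  res$exchange_stats <- out$exchange_stats
  res$visits <- out$visits
  res
}
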