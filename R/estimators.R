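#' Cross-energy matrix for multistate reweighting
#'
#' Evaluates every frame of every sample series under every potential in
#' `modifier_list`, producing the states-by-frames energy matrix that the
#' self-consistent WHAM estimator consumes.  Frame provenance (which
#' potential generated each frame) is recorded.
#'
#' @param model The sampled model.
#' @param series_list List of [run_mc()] series, one per sampled state, in
#'   the same order as `modifier_list`.
#' @param modifier_list List of modifier lists (see [total_energy()]), one
#'   per potential/state.
#' @param temperature Kelvin; defaults to the first series' temperature.
#' @return An object of class `cross_energy`: matrix `u` (K states x N
#'   frames, kcal/mol), integer `origin` (generating state per frame),
#'   counts `n_k`, and `temperature`.
#' @export
cross_energies <- function(model, series_list, modifier_list,
                           temperature = NULL) {
  stopifnot(length(series_list) == length(modifier_list))
  temperature <- temperature %||% series_list[[1]]$temperature
  frames <- unlist(lapply(series_list, `[[`, "states"), recursive = FALSE)
  n_k <- vapply(series_list, function(s) length(s$states), integer(1))
  origin <- rep(seq_along(series_list), n_k)
  u <- matrix(NA_real_, nrow = length(modifier_list), ncol = length(frames))
  for (k in seq_along(modifier_list))
    u[k, ] <- vapply(frames, function(f)
      total_energy(model, f, modifiers = modifier_list[[k]]), numeric(1))
  if (!all(is.finite(u))) stop("non-finite cross energies")
  structure(list(u = u, origin = origin, n_k = n_k,
                 temperature = temperature),
            class = "cross_energy")
}

#' Self-consistent multistate WHAM (binless) free energies
#'
#' Solves the weighted-histogram/multistate-reweighting equations for the
#' per-state free energies f_k given a cross-energy matrix: each frame is
#' evaluated under every state's potential and the f_k are iterated to
#' self-consistency (the histogram-free WHAM fixed point, equivalent to
#' iterated Bennett across all states).  The result is deterministic given
#' the matrix.
#'
#' @param x A [cross_energies()] object, or a plain K x N energy matrix (then
#'   `origin` and `temperature` are required).
#' @param temperature Kelvin (taken from `x` when it is a `cross_energy`).
#' @param origin Integer vector of generating states (matrix input only).
#' @param tol Convergence tolerance: max |change in f_k| per iteration,
#'   kcal/mol.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return An object of class `wham_result`: `f` (kcal/mol, `f[1] == 0`),
#'   `residual`, `iterations`, `ess` (per-state effective sample size of the
#'   reweighting weights), `residual_history`.
#' @export
wham_multistate <- function(x, temperature = NULL, origin = NULL,
                            tol = 1e-8, max_iter = 1e5) {
  if (inherits(x, "cross_energy")) {
    u <- x$u
    origin <- x$origin
    temperature <- temperature %||% x$temperature
  } else u <- x
  if (is.null(temperature) || is.null(origin))
    stop("temperature and origin are required")
  if (!all(is.finite(u))) stop("non-finite energies in cross matrix")
  K <- nrow(u)
  N_k <- tabulate(origin, nbins = K)
  kT <- .KB * temperature
  ur <- u / kT                        # reduced energies
  ur <- sweep(ur, 2, apply(ur, 2, min))  # per-frame shift, cancels in WHAM
  f <- numeric(K)                     # reduced free energies
  logN <- ifelse(N_k > 0, log(N_k), -Inf)
  # the self-consistency equations are the stationarity conditions of a
  # convex objective; a quasi-Newton solve gives a near-converged start and
  # self-consistent iteration then polishes to the stated tolerance
  if (K > 1) {
    for (nw in seq_len(100L)) {
      denom <- row_logsumexp(t(logN + f - ur))
      lw <- logN + f - ur - rep(denom, each = K)   # log w_kn, sums to 1 per n
      w <- exp(lw)
      g <- rowSums(w) - N_k
      H <- diag(rowSums(w), K) - tcrossprod(w)
      Hr <- H[-1, -1, drop = FALSE] + diag(1e-10, K - 1L)
      step <- tryCatch(solve(Hr, -g[-1]), error = function(e) NULL)
      if (is.null(step)) break
      sc <- min(1, 2 / max(abs(step), 1e-12))     # damp very large steps
      f[-1] <- f[-1] + sc * step
      if (max(abs(step)) * kT < 0.1 * tol) break
    }
  }
  it <- 0L
  hist <- numeric(0)
  repeat {
    it <- it + 1L
    # log denominator per frame: logsumexp_k (log N_k + f_k - u_kn)
    denom <- row_logsumexp(t(logN + f - ur))
    fnew <- -vapply(seq_len(K), function(k)
      logsumexp(-ur[k, ] - denom), numeric(1))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f)) * kT
    f <- fnew
    if (length(hist) < 1000L) hist <- c(hist, delta)
    if (delta <= tol) break
    if (it >= max_iter)
      stop("WHAM failed to converge within ", max_iter, " iterations")
  }
  denom <- row_logsumexp(t(logN + f - ur))
  logw <- sweep(-ur, 2, denom, "-")   # log weights per state x frame
  ess <- vapply(seq_len(K), function(k) {
    lw <- logw[k, ] - logsumexp(logw[k, ])
    1 / sum(exp(2 * lw))
  }, numeric(1))
  structure(list(f = f * kT, residual = delta, iterations = it, ess = ess,
                 n_k = N_k, temperature = temperature,
                 residual_history = hist),
            class = "wham_result")
}

#' @export
print.wham_result <- function(x, ...) {
  cat(sprintf("WHAM: %d states, %d frames, converged in %d iterations (residual %.2g kcal/mol)\n",
              length(x$f), sum(x$n_k), x$iterations, x$residual))
  cat("  f (kcal/mol):", paste(sprintf("%.4f", x$f), collapse = "  "), "\n")
  invisible(x)
}

#' Torsional potential of mean force from umbrella sampling (WHAM)
#'
#' Unbiases a set of harmonically biased torsion samplings with the
#' weighted histogram analysis method on a periodic grid, iterating the
#' window free energies to self-consistency and anchoring the PMF at its
#' minimum.
#'
#' @param series List of biased series from [umbrella_scan()] (each must
#'   carry its `bias` specification).
#' @param windows Optional window data.frame; defaults to the specs carried
#'   by the series.
#' @param temperature Kelvin.
#' @param n_bins Number of periodic histogram bins (default 180, i.e. 2
#'   degree bins).
#' @param tol,max_iter Convergence controls (see [wham_multistate()]).
#' @return An object of class `torsion_pmf`: `chi` (bin centres, degrees),
#'   `w` (kcal/mol, min 0; `NA` for unvisited bins), `counts`, window free
#'   energies `f`, `residual`, `iterations`, `residual_history`.
#' @export
wham_umbrella <- function(series, windows = NULL, temperature = NULL,
                          n_bins = 180, tol = 1e-8, max_iter = 1e5) {
  if (length(series) < 1) stop("at least one window series is required")
  temperature <- temperature %||% series[[1]]$temperature
  kT <- .KB * temperature
  biases <- lapply(series, `[[`, "bias")
  if (any(vapply(biases, is.null, logical(1))))
    stop("every series must carry its umbrella bias specification")
  edges <- seq(-180, 180, length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  K <- length(series)
  H <- matrix(0, K, n_bins)
  for (k in seq_len(K)) {
    ti <- biases[[k]]$torsion
    chi <- wrap_deg(series[[k]]$chi[, ti])
    H[k, ] <- tabulate(findInterval(chi, edges, rightmost.closed = TRUE),
                       nbins = n_bins)
  }
  N_k <- rowSums(H)
  total <- colSums(H)
  occ <- total > 0
  if (sum(occ) < 2) stop("umbrella windows have no overlapping support")
  # reduced bias energy of each window at each bin centre
  ub <- matrix(0, K, n_bins)
  for (k in seq_len(K)) {
    dchi <- wrap_rad(deg2rad(mids - biases[[k]]$center))
    ub[k, ] <- 0.5 * biases[[k]]$k * dchi^2 / kT
  }
  f <- numeric(K)
  it <- 0L
  hist <- numeric(0)
  logN <- log(N_k)
  repeat {
    it <- it + 1L
    # log rho_b = log(sum_k H_kb) - logsumexp_k(log N_k + f_k - ub_kb)
    lden <- row_logsumexp(t(logN + f - ub))
    lrho <- ifelse(occ, log(total) - lden, -Inf)
    fnew <- -vapply(seq_len(K), function(k)
      logsumexp(lrho[occ] - ub[k, occ]), numeric(1))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f)) * kT
    f <- fnew
    if (length(hist) < 1000L) hist <- c(hist, delta)
    if (delta <= tol) break
    if (it >= max_iter)
      stop("umbrella WHAM failed to converge within ", max_iter,
           " iterations")
  }
  lden <- row_logsumexp(t(logN + f - ub))
  w <- ifelse(occ, -kT * (log(total) - lden), NA_real_)
  w <- w - min(w, na.rm = TRUE)
  structure(list(chi = mids, w = w, counts = total, f = f * kT,
                 residual = delta, iterations = it, temperature = temperature,
                 residual_history = hist),
            class = "torsion_pmf")
}

#' @export
print.torsion_pmf <- function(x, ...) {
  cat(sprintf("torsional PMF on %d bins, range %.2f kcal/mol (%d empty bins)\n",
              length(x$chi), max(x$w, na.rm = TRUE), sum(is.na(x$w))))
  invisible(x)
}

#' Block standard error of a trajectory estimator
#'
#' Splits a per-frame series into `n_blocks` contiguous blocks, applies the
#' estimator to each block, and reports the sample standard deviation of the
#' block estimates (the convention used for all error bars in this package).
#'
#' @param x Numeric vector of per-frame values.
#' @param n_blocks Number of contiguous blocks (default 10).
#' @param statistic Per-block estimator, default [mean()].
#' @return The standard deviation across block estimates.
#' @export
#' @examples
#' block_error(rep(1, 100))                 # 0
#' block_error(rnorm(1000), n_blocks = 10)  # ~ sd/sqrt(100)
block_error <- function(x, n_blocks = 10, statistic = mean) {
  n <- length(x)
  if (n < n_blocks) stop("fewer frames than blocks")
  idx <- block_index(n, n_blocks)
  est <- vapply(seq_len(n_blocks), function(b) statistic(x[idx == b]),
                numeric(1))
  stats::sd(est)
}

# contiguous block assignment of n frames into n_blocks
block_index <- function(n, n_blocks) ceiling(seq_len(n) * n_blocks / n)
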