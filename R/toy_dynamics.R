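#' Simulate the Lorenz system
#'
#' Fixed-step 4th-order Runge-Kutta integration of
#' dx/dt = sigma (y - x), dy/dt = x (rho - z) - y, dz/dt = x y - beta z.
#' A burn-in segment is integrated and discarded so the retained states lie on
#' the attractor. Fully deterministic given its arguments.
#'
#' @param n Number of retained states (>= 2).
#' @param dt Integration/sampling time step.
#' @param sigma,rho,beta Lorenz parameters (classic chaotic values by default).
#' @param x0 Initial state (length 3).
#' @param burn_in Number of initial steps discarded.
#' @return A `trajectory`: list with `states` (n x 3 matrix), `dt`, `params`.
#' @export
simulate_lorenz <- function(n, dt = 0.01, sigma = 10, rho = 28, beta = 8 / 3,
                            x0 = c(1, 1, 1), burn_in = 1000) {
  deriv <- function(t, y, p) {
    list(c(p$sigma * (y[2] - y[1]),
           y[1] * (p$rho - y[3]) - y[2],
           y[1] * y[2] - p$beta * y[3]))
  }
  simulate_ode(deriv, list(sigma = sigma, rho = rho, beta = beta),
               n = n, dt = dt, x0 = x0, burn_in = burn_in,
               model = "lorenz")
}

#' Simulate the Rössler system
#'
#' Fixed-step RK4 integration of
#' dx/dt = -y - z, dy/dt = x + a y, dz/dt = b + z (x - c).
#'
#' @inheritParams simulate_lorenz
#' @param a,b,c Rössler parameters (classic chaotic values by default).
#' @return A `trajectory`.
#' @export
simulate_rossler <- function(n, dt = 0.05, a = 0.2, b = 0.2, c = 5.7,
                             x0 = c(1, 1, 1), burn_in = 1000) {
  deriv <- function(t, y, p) {
    list(c(-y[2] - y[3],
           y[1] + p$a * y[2],
           p$b + y[3] * (y[1] - p$c)))
  }
  simulate_ode(deriv, list(a = a, b = b, c = c),
               n = n, dt = dt, x0 = x0, burn_in = burn_in,
               model = "rossler")
}

simulate_ode <- function(deriv, params, n, dt, x0, burn_in, model) {
  if (!is.numeric(n) || n < 2 || n != round(n)) {
    rlang::abort("`n` must be an integer >= 2.")
  }
  if (!is.numeric(dt) || dt <= 0) rlang::abort("`dt` must be positive.")
  if (length(x0) != 3) rlang::abort("`x0` must have length 3.")
  times <- seq(0, (burn_in + n - 1) * dt, by = dt)
  out <- deSolve::ode(y = c(x = x0[1], y = x0[2], z = x0[3]), times = times,
                      func = deriv, parms = params, method = "rk4")
  states <- unname(as.matrix(out[, 2:4]))
  states <- states[(burn_in + 1):(burn_in + n), , drop = FALSE]
  if (any(!is.finite(states))) {
    rlang::abort(sprintf(
      "Integration of the %s system diverged (non-finite state); reduce dt.",
      model))
  }
  structure(list(states = states, dt = dt,
                 params = c(params, list(model = model, burn_in = burn_in))),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d states of dimension %d (%s, dt = %g)\n",
              nrow(x$states), ncol(x$states),
              x$params$model %||% "custom", x$dt))
  invisible(x)
}

#' Recurrence plot of a trajectory
#'
#' The recurrence matrix marks every pair of states closer than a threshold:
#' R(i, j) = 1 iff ||x_i - x_j|| <= epsilon (Euclidean norm), 0 otherwise.
#' Instead of `epsilon`, a `target_rate` may be given: the fraction of
#' off-diagonal pairs to plot, in which case epsilon is set to the
#' corresponding quantile of all off-diagonal pairwise distances.
#'
#' @param traj A `trajectory`, an `rpr_structure`, or an n x d coordinate
#'   matrix.
#' @param epsilon Distance threshold. Exactly one of `epsilon`/`target_rate`.
#' @param target_rate Fraction of off-diagonal pairs to plot, in (0, 1\].
#' @param bins Optional `genomic_bins` table attached to the result.
#' @return A `contact_map` (the recurrence matrix).
#' @export
recurrence_plot <- function(traj, epsilon = NULL, target_rate = NULL,
                            bins = NULL) {
  X <- trajectory_coords(traj)
  if (is.null(epsilon) == is.null(target_rate)) {
    rlang::abort("Give exactly one of `epsilon` or `target_rate`.")
  }
  d <- as.matrix(stats::dist(X))
  if (!is.null(target_rate)) {
    if (target_rate <= 0 || target_rate > 1) {
      rlang::abort("`target_rate` must be in (0, 1].")
    }
    epsilon <- pair_quantile(d, target_rate)
  }
  if (epsilon < 0) rlang::abort("`epsilon` must be non-negative.")
  contact_map((d <= epsilon) * 1L, bins = bins)
}

# epsilon such that ~fraction of off-diagonal pairs satisfy d <= epsilon
pair_quantile <- function(dmat, fraction) {
  v <- sort(dmat[upper.tri(dmat)])
  m <- max(1L, round(fraction * length(v)))
  v[m]
}

trajectory_coords <- function(x) {
  if (inherits(x, "trajectory")) return(x$states)
  if (inherits(x, "rpr_structure")) return(x$coordinates)
  as.matrix(x)
}

#' Corruption settings for a recurrence matrix
#'
#' @param flip_rate Probability, per unordered off-diagonal pair, of
#'   inverting the bit (false positives and false negatives).
#' @param loss_rate Probability, per remaining 1-entry, of deletion
#'   (mimics the sparse detection of single-cell Hi-C).
#' @param seed Integer seed making the corruption reproducible.
#' @return A `corruption_spec` list.
#' @export
corruption_spec <- function(flip_rate = 0, loss_rate = 0, seed = 1L) {
  if (flip_rate < 0 || flip_rate > 1 || loss_rate < 0 || loss_rate > 1) {
    rlang::abort("Rates must be in [0, 1].")
  }
  structure(list(flip_rate = flip_rate, loss_rate = loss_rate,
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Corrupt a recurrence matrix
#'
#' Applies, independently to each unordered off-diagonal pair, first a bit
#' flip with probability `flip_rate`, then — if the entry is currently 1 —
#' deletion with probability `loss_rate`. One random draw per unordered pair
#' keeps the matrix symmetric; the diagonal is untouched. Deterministic given
#' the seed in `spec`.
#'
#' @param R A `contact_map`.
#' @param spec A [corruption_spec()].
#' @return A corrupted `contact_map`.
#' @export
corrupt <- function(R, spec) {
  stopifnot(inherits(R, "contact_map"), inherits(spec, "corruption_spec"))
  m <- R$R
  n <- nrow(m)
  ut <- upper.tri(m)
  v <- m[ut]
  withr::with_seed(spec$seed, {
    u_flip <- stats::runif(length(v))
    u_loss <- stats::runif(length(v))
  })
  v <- ifelse(u_flip < spec$flip_rate, 1L - v, v)
  v <- ifelse(v == 1L & u_loss < spec$loss_rate, 0L, v)
  out <- matrix(0L, n, n)
  out[ut] <- v
  out <- out + t(out)
  diag(out) <- 1L
  contact_map(out, bins = R$bins)
}

#' Keep only the closest fraction of interactions
#'
#' Builds the recurrence plot whose threshold is the `fraction`-quantile of
#' all off-diagonal pairwise distances, so only the closest `fraction` of
#' pairs are plotted (plus the diagonal). `fraction = 0.002` mimics the very
#' sparse contact detection of single-cell Hi-C.
#'
#' @param traj A `trajectory`, `rpr_structure`, or coordinate matrix.
#' @param fraction Fraction of pairs to keep, in (0, 1\].
#' @param bins Optional `genomic_bins` table attached to the result.
#' @return A `contact_map`.
#' @export
keep_nearest_fraction <- function(traj, fraction, bins = NULL) {
  recurrence_plot(traj, target_rate = fraction, bins = bins)
}

#' Generate a synthetic chromosome-like 3D curve
#'
#' A smoothed 3D random walk with momentum-correlated unit steps, standing in
#' for a chromatin fiber: each step direction is a convex mix of the previous
#' direction and fresh Gaussian noise, renormalized to `step_size`, so
#' consecutive bins are always exactly `step_size` apart and the curve is
#' locally smooth but globally folded. Deterministic given `seed`.
#'
#' @param n_bins Number of bins/monomers (>= 10).
#' @param step_size Spatial distance between consecutive bins.
#' @param smoothness Momentum weight in \[0, 1); higher is straighter.
#' @param seed Integer seed.
#' @param resolution Genomic bin width (bp) for the attached bin table.
#' @param chrom Chromosome name for the attached bin table.
#' @return An `rpr_structure` holding the true coordinates and a bin table
#'   (eigenvalues are `NA`: the curve is generated, not embedded).
#' @export
synthetic_chromosome <- function(n_bins = 200, step_size = 1,
                                 smoothness = 0.8, seed = 1L,
                                 resolution = 250000, chrom = "chrS") {
  if (n_bins < 10) rlang::abort("`n_bins` must be at least 10.")
  if (smoothness < 0 || smoothness >= 1) {
    rlang::abort("`smoothness` must be in [0, 1).")
  }
  X <- matrix(0, n_bins, 3)
  withr::with_seed(as.integer(seed), {
    noise <- matrix(stats::rnorm(3 * (n_bins - 1)), n_bins - 1, 3)
  })
  dir <- noise[1, ] / sqrt(sum(noise[1, ]^2))
  X[2, ] <- X[1, ] + step_size * dir
  for (i in seq_len(n_bins - 2) + 1L) {
    raw <- smoothness * dir + (1 - smoothness) * noise[i, ]
    dir <- raw / sqrt(sum(raw^2))
    X[i + 1, ] <- X[i, ] + step_size * dir
  }
  X <- sweep(X, 2, colMeans(X))
  bins <- make_bins(stats::setNames(n_bins * resolution, chrom), resolution)
  new_rpr_structure(X, eigenvalues = rep(NA_real_, 3), bins = bins,
                    params = list(generator = "synthetic_chromosome",
                                  n_bins = n_bins, step_size = step_size,
                                  smoothness = smoothness, seed = seed))
}

#' Contact map of a 3D structure
#'
#' Applies [recurrence_plot()] to the coordinates of a structure, carrying its
#' bin table along, e.g. to derive the contact map a synthetic chromosome
#' would produce.
#'
#' @param structure An `rpr_structure`.
#' @inheritParams recurrence_plot
#' @return A `contact_map` over the structure's bins.
#' @export
contact_map_from_structure <- function(structure, epsilon = NULL,
                                       target_rate = NULL) {
  stopifnot(inherits(structure, "rpr_structure"))
  recurrence_plot(structure$coordinates, epsilon = epsilon,
                  target_rate = target_rate, bins = structure$bins)
}

#' Write a trajectory as TSV
#'
#' Columns `t`, `x`, `y`, `z` (time in integration units).
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @export
write_trajectory_tsv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- tibble::as_tibble(traj$states, .name_repair = ~c("x", "y", "z"))
  df <- dplyr::bind_cols(tibble::tibble(t = (seq_len(nrow(df)) - 1) * traj$dt),
                         df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
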