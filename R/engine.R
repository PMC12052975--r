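#' Langevin integrator parameters
#'
#' Parameters of the underdamped Langevin (BAOAB) propagator. Temperature and
#' timestep follow the production-run setup (303.15 K, 2 fs); friction and
#' mass are effective 1-D parameters that set timescales only — equilibrium
#' distributions do not depend on them.
#'
#' @param temperature K (default 303.15).
#' @param timestep ps (default 0.002, i.e. 2 fs).
#' @param friction 1/ps (default 1).
#' @param mass g/mol (default 50).
#' @return object of class `langevin_params`.
#' @export
langevin_params <- function(temperature = 303.15, timestep = 0.002,
                            friction = 1.0, mass = 50) {
  stopifnot(temperature > 0, timestep > 0, friction > 0, mass > 0)
  structure(list(temperature = temperature, timestep = timestep,
                 friction = friction, mass = mass, kB = KB),
            class = "langevin_params")
}

#' Harmonic wall restraints
#'
#' One-sided power restraints that confine the coordinate to the
#' translocation pathway (default bounds -1.1 and 2.0 nm, matching the
#' lower/upper walls used to keep the ligand between the helices). Inside
#' `[lower_at, upper_at]` the walls contribute nothing; beyond a bound the
#' energy is `0.5 * kappa * excess^exponent`.
#'
#' @param lower_at,upper_at bounds in nm.
#' @param kappa stiffness, kJ/mol/nm^2 (default 1000).
#' @param exponent even integer >= 2 (default 2).
#' @return object of class `wall_spec`.
#' @export
wall_spec <- function(lower_at = -1.1, upper_at = 2.0, kappa = 1000,
                      exponent = 2L) {
  stopifnot(lower_at < upper_at, kappa >= 0,
            exponent >= 2, exponent %% 2 == 0)
  structure(list(lower_at = lower_at, upper_at = upper_at, kappa = kappa,
                 exponent = as.integer(exponent)), class = "wall_spec")
}

#' Wall energy and force
#'
#' @param walls a [wall_spec()].
#' @param z numeric vector of positions (nm).
#' @return list of numeric vectors `energy` (kJ/mol) and `force` (kJ/mol/nm);
#'   the force pushes back toward the allowed interval.
#' @examples
#' wall_energy(wall_spec(), 2.1)$energy # 0.5 * 1000 * 0.1^2 = 5
#' @export
wall_energy <- function(walls, z) {
  stopifnot(inherits(walls, "wall_spec"), is.numeric(z))
  cpp_eval_wall(unclass(walls), as.numeric(z))
}

#' Run underdamped Langevin dynamics
#'
#' BAOAB-discretised Langevin propagation on a landscape with wall restraints
#' and an optional external bias. The total force (landscape + walls + bias)
#' is evaluated once per step at the current position. Trajectories are
#' bit-reproducible for a fixed seed and configuration.
#'
#' `bias` may be `NULL`, a [hill_log()] (static Gaussian bias, evaluated in
#' compiled code), or an R function `function(z)` returning
#' `list(energy=, force=)` (propagated in R; intended for short runs).
#'
#' @param land an [landscape()].
#' @param params a [langevin_params()].
#' @param walls a [wall_spec()].
#' @param bias external bias (see Details).
#' @param n_steps number of steps (>= 1).
#' @param z0 initial position (nm), within the landscape domain.
#' @param seed integer seed for the trajectory's own RNG stream.
#' @param stride record every `stride` steps (default 1).
#' @param v0 initial velocity (nm/ps); `NULL` draws from Maxwell-Boltzmann
#'   at `temperature` using the run seed.
#' @return an `abcg_trajectory`: data.frame with columns `time` (ps), `z`
#'   (nm), `velocity` (nm/ps), `bias_energy` (kJ/mol), `total_force`
#'   (kJ/mol/nm); attributes `seed` and `stride`.
#' @export
run_langevin <- function(land, params = langevin_params(),
                         walls = wall_spec(), bias = NULL, n_steps, z0,
                         seed, stride = 1L, v0 = NULL) {
  stopifnot(inherits(land, "abcg_landscape"), n_steps >= 1,
            z0 >= land$domain[1], z0 <= land$domain[2])
  n_steps <- as.integer(n_steps); stride <- as.integer(stride)
  if (is.function(bias)) {
    raw <- run_langevin_rbias(land, params, walls, bias, n_steps, z0, seed,
                              stride, v0)
  } else {
    hills <- NULL
    if (!is.null(bias)) {
      stopifnot(inherits(bias, "hill_log"))
      hills <- list(center = bias$hills$center, height = bias$hills$height,
                    sigma = bias$config$sigma)
    }
    raw <- cpp_run_langevin(unclass(land), unclass(params), unclass(walls),
                            hills, n_steps, z0, as.integer(seed), stride, v0)
  }
  traj <- as.data.frame(raw)
  attr(traj, "seed") <- as.integer(seed)
  attr(traj, "stride") <- stride
  class(traj) <- c("abcg_trajectory", "data.frame")
  traj
}

# R-level BAOAB for function-valued biases; mirrors the compiled kernel,
# with its own RNG stream (seeded mt-equivalent via set.seed is avoided so
# compiled and R paths stay independent sources of randomness).
run_langevin_rbias <- function(land, params, walls, bias, n_steps, z0, seed,
                               stride, v0) {
  dt <- params$timestep; m <- params$mass
  kT <- KB * params$temperature
  c1 <- exp(-params$friction * dt); c2 <- sqrt(1 - c1^2)
  sv <- sqrt(kT / m)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  z <- z0
  v <- if (is.null(v0)) sv * rnorm(1) else v0
  forces <- function(zz) {
    zc <- min(max(zz, land$domain[1]), land$domain[2])
    l <- cpp_eval_landscape(unclass(land), zc)
    w <- cpp_eval_wall(unclass(walls), zz)
    b <- bias(zz)
    list(force = l$force + w$force + b$force, bias = b$energy)
  }
  f <- forces(z)
  n_rec <- n_steps %/% stride + 1L
  out <- matrix(NA_real_, n_rec, 5L)
  out[1L, ] <- c(0, z, v, f$bias, f$force)
  ir <- 2L
  for (step in seq_len(n_steps)) {
    v <- v + 0.5 * dt * f$force / m
    z <- z + 0.5 * dt * v
    v <- c1 * v + c2 * sv * rnorm(1)
    z <- z + 0.5 * dt * v
    f <- forces(z)
    if (!is.finite(f$force))
      stop("non-finite force at step ", step, " (z = ", signif(z, 6), ")")
    v <- v + 0.5 * dt * f$force / m
    if (step %% stride == 0L) {
      out[ir, ] <- c(step * dt, z, v, f$bias, f$force)
      ir <- ir + 1L
    }
  }
  setNames(as.data.frame(out),
           c("time", "z", "velocity", "bias_energy", "total_force"))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write / read a trajectory as COLVAR-style text
#'
#' Whitespace table with header line `#! FIELDS time dz bias force`
#' (velocity is carried as a trailing column so the round trip is lossless).
#'
#' @param traj an `abcg_trajectory`.
#' @param path file path.
#' @return `read_colvar` returns the trajectory; `write_colvar` returns
#'   `path` invisibly.
#' @export
write_colvar <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time dz bias force velocity", con)
  writeLines(sprintf("%.17g %.17g %.17g %.17g %.17g", traj$time, traj$z,
                     traj$bias_energy, traj$total_force, traj$velocity), con)
  invisible(path)
}

#' @rdname write_colvar
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#!")]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  traj <- data.frame(time = m[, 1], z = m[, 2], velocity = m[, 5],
                     bias_energy = m[, 3], total_force = m[, 4])
  class(traj) <- c("abcg_trajectory", "data.frame")
  traj
}
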