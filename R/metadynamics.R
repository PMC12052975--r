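#' Well-tempered metadynamics configuration
#'
#' Defaults are the production bias parameters: hills of initial height 0.6
#' kJ/mol and width 0.05 nm deposited every 500 steps (1 ps at a 2 fs step),
#' bias factor 10, 303.15 K, grid from -1.5 to 2.4 nm, four walkers. The
#' grid bin count (not part of the published parameter line) defaults to 390,
#' i.e. 0.01 nm bins.
#'
#' @param pace_steps deposition cadence in steps (default 500).
#' @param height0 initial hill height, kJ/mol (default 0.6).
#' @param sigma hill width, nm (default 0.05).
#' @param biasfactor well-tempering factor gamma > 1 (default 10).
#' @param temperature K (default 303.15).
#' @param grid_min,grid_max grid bounds, nm (defaults -1.5, 2.4).
#' @param grid_bins number of bins (default 390; the grid has
#'   `grid_bins + 1` nodes).
#' @param n_walkers number of walkers sharing the bias (default 4).
#' @return object of class `metad_config`.
#' @export
metad_config <- function(pace_steps = 500L, height0 = 0.6, sigma = 0.05,
                         biasfactor = 10.0, temperature = 303.15,
                         grid_min = -1.5, grid_max = 2.4, grid_bins = 390L,
                         n_walkers = 4L) {
  stopifnot(pace_steps >= 1, height0 > 0, sigma > 0, biasfactor > 1,
            temperature > 0, grid_min < grid_max, grid_bins >= 1,
            n_walkers >= 1)
  structure(list(pace_steps = as.integer(pace_steps), height0 = height0,
                 sigma = sigma, biasfactor = biasfactor,
                 temperature = temperature, grid_min = grid_min,
                 grid_max = grid_max, grid_bins = as.integer(grid_bins),
                 n_walkers = as.integer(n_walkers)),
            class = "metad_config")
}

fes_grid <- function(cfg) {
  seq(cfg$grid_min, cfg$grid_max, length.out = cfg$grid_bins + 1L)
}

#' Well-tempered hill height
#'
#' Height of the next deposited hill given the bias already accumulated at
#' the deposition point: `height0 * exp(-v / (kB * (gamma - 1) * T))`.
#'
#' @param v_bias_at_center accumulated bias at the hill centre, kJ/mol (>= 0).
#' @param cfg a [metad_config()].
#' @return hill height in kJ/mol, in `(0, height0]`.
#' @examples
#' scaled_hill_height(0, metad_config()) # 0.6
#' @export
scaled_hill_height <- function(v_bias_at_center, cfg) {
  stopifnot(inherits(cfg, "metad_config"), v_bias_at_center >= 0)
  if (cfg$biasfactor <= 1) stop("biasfactor must exceed 1")
  cfg$height0 * exp(-v_bias_at_center / (KB * (cfg$biasfactor - 1) * cfg$temperature))
}

#' Ordered log of deposited hills
#'
#' @param time,center,height numeric vectors (ps, nm, kJ/mol); heights are
#'   already well-tempered-scaled at deposition.
#' @param config the [metad_config()] the hills were deposited under; all
#'   hills share its `sigma` and `biasfactor`.
#' @return object of class `hill_log` with a `hills` data.frame and the
#'   config snapshot.
#' @export
hill_log <- function(time = numeric(), center = numeric(),
                     height = numeric(), config = metad_config()) {
  stopifnot(length(time) == length(center), length(center) == length(height),
            !is.unsorted(time), all(height > 0 | length(height) == 0),
            all(height <= config$height0 + 1e-12))
  structure(list(hills = data.frame(time = time, center = center,
                                    sigma = rep(config$sigma, length(time)),
                                    height = height,
                                    biasfactor = rep(config$biasfactor,
                                                     length(time))),
                 config = config),
            class = "hill_log")
}

#' Summed Gaussian bias of a hill log
#'
#' \eqn{V(z) = \sum_i h_i \exp(-(z-c_i)^2 / 2\sigma_i^2)}; the full,
#' untruncated sum. An empty log gives 0.
#'
#' @param hills a [hill_log()].
#' @param z numeric vector of positions (nm).
#' @return numeric vector of bias energies (kJ/mol).
#' @export
bias_from_hills <- function(hills, z) {
  stopifnot(inherits(hills, "hill_log"))
  h <- hills$hills
  if (nrow(h) == 0L) return(rep(0, length(z)))
  # outer() over (z, hills); grids and logs are small enough for full sums
  d <- outer(z, h$center, "-")
  as.numeric(exp(-0.5 * (d / rep(h$sigma, each = length(z)))^2) %*% h$height)
}

#' Run well-tempered metadynamics
#'
#' Synchronous multiple-walker well-tempered metadynamics on the Langevin
#' engine. Every `pace_steps` steps each walker (in fixed index order)
#' deposits one hill at its current position, with [scaled_hill_height()]
#' evaluated on the shared bias accumulated so far (including hills deposited
#' by lower-index walkers in the same round). All walkers feel the shared
#' bias. Walker RNG streams are derived as `seed + walker_index - 1`.
#'
#' @param land an [landscape()].
#' @param cfg a [metad_config()].
#' @param langevin a [langevin_params()].
#' @param walls a [wall_spec()].
#' @param n_steps_per_walker steps per walker (>= `pace_steps`).
#' @param seed integer seed.
#' @param z0 numeric vector of walker start positions (recycled); `NULL`
#'   spreads the walkers evenly over the wall interval.
#' @param stride trajectory recording stride in steps (default
#'   `cfg$pace_steps`).
#' @param probe_z optional probe positions; if given, the result carries a
#'   `probe_bias` matrix with the engine's accumulated bias at each probe
#'   immediately after every deposition round.
#' @return list with `trajectories` (list of `abcg_trajectory`), `hills`
#'   (a [hill_log()]), and optionally `probe_bias`.
#' @export
run_wt_metadynamics <- function(land, cfg = metad_config(),
                                langevin = langevin_params(),
                                walls = wall_spec(), n_steps_per_walker,
                                seed, z0 = NULL, stride = NULL,
                                probe_z = NULL) {
  stopifnot(inherits(land, "abcg_landscape"), inherits(cfg, "metad_config"),
            n_steps_per_walker >= cfg$pace_steps)
  if (is.null(stride)) stride <- cfg$pace_steps
  nw <- cfg$n_walkers
  if (is.null(z0)) {
    span <- c(max(walls$lower_at, land$domain[1]),
              min(walls$upper_at, land$domain[2]))
    z0 <- span[1] + (seq_len(nw) - 0.5) / nw * diff(span)
  }
  z0 <- rep_len(as.numeric(z0), nw)
  raw <- cpp_run_metad(unclass(land), unclass(langevin), unclass(walls),
                       unclass(cfg), as.integer(n_steps_per_walker),
                       as.integer(seed), as.integer(stride),
                       if (is.null(probe_z)) numeric() else as.numeric(probe_z),
                       z0)
  trajs <- lapply(seq_along(raw$trajectories), function(w) {
    tr <- as.data.frame(raw$trajectories[[w]])
    attr(tr, "seed") <- as.integer(seed) + w - 1L
    attr(tr, "stride") <- as.integer(stride)
    class(tr) <- c("abcg_trajectory", "data.frame")
    tr
  })
  out <- list(trajectories = trajs,
              hills = hill_log(raw$hill_time, raw$hill_center,
                               raw$hill_height, cfg))
  if (!is.null(probe_z)) {
    out$probe_bias <- raw$probe_bias
    dimnames(out$probe_bias) <- list(NULL, paste0("z", seq_along(probe_z)))
    attr(out$probe_bias, "probe_z") <- as.numeric(probe_z)
  }
  out
}

new_fes <- function(z_grid, free_energy, sampled, cfg) {
  structure(list(z_grid = z_grid, free_energy = free_energy,
                 region_sampled = sampled, config = cfg),
            class = "abcg_fes")
}

#' Reconstruct the free-energy surface from a hill log
#'
#' Hill summation: \eqn{F(z) = -\gamma/(\gamma-1)\, V(z)} on the
#' configuration grid, shifted so the minimum over the grid is zero.
#' `region_sampled` marks bins within 3 sigma of at least one hill centre.
#'
#' @param hills a [hill_log()].
#' @param cfg a [metad_config()] (defaults to the log's snapshot).
#' @return object of class `abcg_fes` with `z_grid`, `free_energy`,
#'   `region_sampled`.
#' @export
reconstruct_fes <- function(hills, cfg = hills$config) {
  stopifnot(inherits(hills, "hill_log"), inherits(cfg, "metad_config"))
  zg <- fes_grid(cfg)
  if (nrow(hills$hills) == 0L) {
    warning("empty hill log: returning a flat zero FES with empty sampled mask")
    return(new_fes(zg, rep(0, length(zg)), rep(FALSE, length(zg)), cfg))
  }
  v <- bias_from_hills(hills, zg)
  g <- cfg$biasfactor
  f <- -(g / (g - 1)) * v
  f <- f - min(f)
  sampled <- vapply(zg, function(z)
    any(abs(z - hills$hills$center) <= 3 * hills$hills$sigma), logical(1))
  new_fes(zg, f, sampled, cfg)
}

#' @export
print.abcg_fes <- function(x, ...) {
  cat("<abcg_fes>", length(x$z_grid), "grid points,",
      sum(x$region_sampled), "sampled;",
      sprintf("F range [0, %.3f] kJ/mol\n", max(x$free_energy)))
  invisible(x)
}

#' RMS difference between two free-energy surfaces
#'
#' Root-mean-square difference over the grid bins inside `region`, after
#' aligning each surface to mean zero on that region. Bins marked unsampled
#' in either surface are excluded.
#'
#' @param a,b `abcg_fes` objects on identical grids.
#' @param region interval `c(lo, hi)` in nm.
#' @return RMS difference in kJ/mol.
#' @export
fes_rmse <- function(a, b, region) {
  stopifnot(inherits(a, "abcg_fes"), inherits(b, "abcg_fes"),
            length(a$z_grid) == length(b$z_grid),
            max(abs(a$z_grid - b$z_grid)) < 1e-12,
            is.numeric(region), length(region) == 2L)
  sel <- a$z_grid >= region[1] & a$z_grid <= region[2] &
    a$region_sampled & b$region_sampled
  if (!any(sel)) stop("empty comparison region")
  da <- a$free_energy[sel] - mean(a$free_energy[sel])
  db <- b$free_energy[sel] - mean(b$free_energy[sel])
  sqrt(mean((da - db)^2))
}

#' Write / read a HILLS file
#'
#' PLUMED-style whitespace text with header
#' `#! FIELDS time dz sigma_dz height biasf`, one hill per row at full
#' precision. The reader tolerates comment lines starting `#!`.
#'
#' @param hills a [hill_log()].
#' @param path file path.
#' @param config a [metad_config()] for the returned log (the file stores
#'   sigma and biasfactor per row; they must be consistent).
#' @return `read_hills` returns a [hill_log()]; `write_hills` returns `path`
#'   invisibly.
#' @export
write_hills <- function(hills, path) {
  stopifnot(inherits(hills, "hill_log"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time dz sigma_dz height biasf", con)
  h <- hills$hills
  writeLines(sprintf("%.17g %.17g %.17g %.17g %.17g",
                     h$time, h$center, h$sigma, h$height, h$biasfactor), con)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path, config = metad_config()) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (nrow(m) > 0) {
    if (max(abs(m[, 3] - config$sigma)) > 1e-12 ||
        max(abs(m[, 5] - config$biasfactor)) > 1e-12)
      stop("HILLS file sigma/biasfactor disagree with the supplied config")
  }
  hill_log(m[, 1], m[, 2], m[, 4], config)
}

#' Write an FES as TSV
#'
#' Three columns: z (nm), free_energy (kJ/mol), sampled (0/1).
#' @param fes an `abcg_fes`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fes_tsv <- function(fes, path) {
  stopifnot(inherits(fes, "abcg_fes"))
  df <- data.frame(z = fes$z_grid, free_energy = fes$free_energy,
                   sampled = as.integer(fes$region_sampled))
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
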