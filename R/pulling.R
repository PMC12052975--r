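#' Staged moving-restraint schedule
#'
#' Piecewise-linear schedule of a harmonic restraint in step number. Between
#' consecutive stages both the centre and the stiffness interpolate linearly;
#' beyond the last stage both are held constant. A stage omitting `kappa`
#' (`NA`) inherits the previous value.
#'
#' @param step integer vector, strictly increasing, starting at 0.
#' @param at restraint centres (nm).
#' @param kappa stiffnesses (kJ/mol/nm^2), `NA` inherits.
#' @return object of class `restraint_schedule` (a data.frame).
#' @seealso [default_pull_in_schedule()] for the published pull-in stages.
#' @export
restraint_schedule <- function(step, at, kappa) {
  stopifnot(length(step) >= 1, length(at) == length(step),
            length(kappa) == length(step), step[1] == 0,
            !is.unsorted(step, strictly = TRUE))
  for (i in seq_along(kappa))
    if (is.na(kappa[i])) {
      if (i == 1L) stop("first stage must state kappa")
      kappa[i] <- kappa[i - 1L]
    }
  stopifnot(all(kappa >= 0))
  structure(data.frame(step = as.numeric(step), at = as.numeric(at),
                       kappa = as.numeric(kappa)),
            class = c("restraint_schedule", "data.frame"))
}

#' The published pull-in schedule
#'
#' Stages that drag the ligand from its initial coordinate into the binding
#' pocket: (step 0, z_init, kappa 1000), (step 4,500,000, 0.2 nm, 1000),
#' (step 5,000,000, 0.2 nm, 0).
#'
#' @param z_init initial restraint centre (nm).
#' @return a [restraint_schedule()].
#' @export
default_pull_in_schedule <- function(z_init) {
  restraint_schedule(step = c(0, 4.5e6, 5e6),
                     at = c(z_init, 0.2, 0.2),
                     kappa = c(1000, NA, 0))
}

#' Restraint centre and stiffness at a step
#'
#' @param schedule a [restraint_schedule()].
#' @param step step number (>= 0; may be fractional).
#' @return list with `center` (nm) and `kappa` (kJ/mol/nm^2).
#' @examples
#' restraint_state(default_pull_in_schedule(1.5), 4750000) # centre 0.2, kappa 500
#' @export
restraint_state <- function(schedule, step) {
  stopifnot(inherits(schedule, "restraint_schedule"), nrow(schedule) >= 1,
            step >= 0)
  s <- schedule$step
  if (step <= s[1])
    return(list(center = schedule$at[1], kappa = schedule$kappa[1]))
  n <- nrow(schedule)
  if (step >= s[n])
    return(list(center = schedule$at[n], kappa = schedule$kappa[n]))
  i <- findInterval(step, s)
  w <- (step - s[i]) / (s[i + 1] - s[i])
  list(center = schedule$at[i] + w * (schedule$at[i + 1] - schedule$at[i]),
       kappa = schedule$kappa[i] + w * (schedule$kappa[i + 1] - schedule$kappa[i]))
}

#' Constant-velocity pull configuration
#'
#' Defaults are the published umbrella-pull parameters: force constant 500
#' kJ/mol/nm^2 and velocity 0.0005 nm/ns along +z, 25 replicates. `velocity`
#' is stated in nm/ns as printed; desk-scale runs rescale it (the analysis
#' drivers use 10 nm/ns so a full translocation fits in a few hundred ps).
#'
#' @param force_constant kJ/mol/nm^2 (default 500).
#' @param velocity nm/ns (default 0.0005).
#' @param n_replicates default 25.
#' @return object of class `pull_config`.
#' @export
pull_config <- function(force_constant = 500, velocity = 0.0005,
                        n_replicates = 25L) {
  stopifnot(force_constant >= 0, velocity > 0, n_replicates >= 1)
  structure(list(force_constant = force_constant, velocity = velocity,
                 direction = "+z", n_replicates = as.integer(n_replicates)),
            class = "pull_config")
}

#' Residue zones along the translocation coordinate
#'
#' Desk-scale stand-in for 3-D residue contacts: a residue is "in contact"
#' when z lies within `halfwidth` of the zone centre. Zones must lie within
#' the metadynamics grid and carry unique labels.
#'
#' @param residue_label character vector (e.g. `"I585"`).
#' @param center zone centres (nm).
#' @param halfwidth nm (default 0.1, recycled).
#' @return data.frame of class `residue_zones`.
#' @export
residue_zones <- function(residue_label, center, halfwidth = 0.1) {
  stopifnot(length(residue_label) == length(center),
            !anyDuplicated(residue_label),
            all(center >= -1.5), all(center <= 2.4))
  structure(data.frame(residue_label = as.character(residue_label),
                       center = as.numeric(center),
                       halfwidth = rep_len(as.numeric(halfwidth),
                                           length(center))),
            class = c("residue_zones", "data.frame"))
}

new_pull_trajectory <- function(frames, contacts, zones, frame_spacing,
                                meta = list()) {
  structure(list(frames = frames, contacts = contacts, zones = zones,
                 frame_spacing = frame_spacing, metadata = meta),
            class = "abcg_pull_trajectory")
}

#' @export
print.abcg_pull_trajectory <- function(x, ...) {
  cat("<abcg_pull_trajectory>", nrow(x$frames), "frames,",
      ncol(x$contacts), "zones, frame spacing", x$frame_spacing, "ps\n")
  invisible(x)
}

#' Run a constant-velocity pull
#'
#' Steered translocation: a harmonic restraint of stiffness
#' `pull$force_constant` moves at `pull$velocity` along +z from `z_start`,
#' dragging the coordinate through the pathway. The restraint force
#' `kappa * (center - z)` and per-zone contacts are recorded every
#' `frame_spacing` ps.
#'
#' @param land an [landscape()].
#' @param pull a [pull_config()].
#' @param langevin a [langevin_params()].
#' @param walls a [wall_spec()].
#' @param zones a [residue_zones()] table.
#' @param z_start initial position and restraint centre (nm).
#' @param n_steps number of steps.
#' @param seed integer seed.
#' @param frame_spacing ps between analysis frames (default 1).
#' @return an `abcg_pull_trajectory`: `frames` data.frame (`time`, `z`,
#'   `restraint_center`, `pull_force`), logical `contacts` matrix (frames x
#'   zones), the zones, and metadata.
#' @export
run_constant_velocity_pull <- function(land, pull = pull_config(),
                                       langevin = langevin_params(),
                                       walls = wall_spec(), zones,
                                       z_start, n_steps, seed,
                                       frame_spacing = 1) {
  stopifnot(inherits(land, "abcg_landscape"), inherits(pull, "pull_config"),
            inherits(zones, "residue_zones"), n_steps >= 1,
            z_start >= land$domain[1], z_start <= land$domain[2])
  v_nm_per_ps <- pull$velocity / 1000
  z_end <- z_start + v_nm_per_ps * n_steps * langevin$timestep
  sched <- restraint_schedule(step = c(0, n_steps),
                              at = c(z_start, z_end),
                              kappa = rep(pull$force_constant, 2))
  run_scheduled_pull(land, sched, langevin, walls, zones, z_start, n_steps,
                     seed, frame_spacing,
                     meta = list(velocity_nm_ns = pull$velocity,
                                 force_constant = pull$force_constant,
                                 seed = as.integer(seed)))
}

#' Run a pull under an arbitrary restraint schedule
#'
#' Generic staged-restraint propagation (used for the pull-in stage and by
#' [run_constant_velocity_pull()]).
#'
#' @inheritParams run_constant_velocity_pull
#' @param schedule a [restraint_schedule()].
#' @param meta metadata list attached to the result.
#' @return an `abcg_pull_trajectory`.
#' @export
run_scheduled_pull <- function(land, schedule, langevin = langevin_params(),
                               walls = wall_spec(), zones, z_start, n_steps,
                               seed, frame_spacing = 1, meta = list()) {
  stopifnot(inherits(schedule, "restraint_schedule"),
            inherits(zones, "residue_zones"))
  frame_stride <- max(1L, as.integer(round(frame_spacing / langevin$timestep)))
  raw <- cpp_run_restrained(unclass(land), unclass(langevin), unclass(walls),
                            schedule$step, schedule$at, schedule$kappa,
                            as.integer(n_steps), z_start, as.integer(seed),
                            frame_stride)
  frames <- data.frame(time = raw$time, z = raw$z,
                       restraint_center = raw$restraint_center,
                       pull_force = raw$pull_force)
  contacts <- outer(frames$z, seq_len(nrow(zones)), function(zz, j)
    abs(zz - zones$center[j]) <= zones$halfwidth[j])
  colnames(contacts) <- zones$residue_label
  meta$seed <- meta$seed %||% as.integer(seed)
  new_pull_trajectory(frames, contacts, zones,
                      frame_stride * langevin$timestep, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Force-window correction factor
#'
#' A signed balance statistic over a window of the restraint-force series
#' around a frame: with P the sum of positive force samples and N the sum of
#' negative samples in the window,
#' `(P - |N|) / (P + |N|)`, and 0 when the denominator is 0. The window
#' spans `window` ps on each side (default 10) and is truncated at the
#' trajectory ends.
#'
#' @param pull_force numeric force series, one value per frame.
#' @param frame_index 1-based frame index.
#' @param window half-window in ps (default 10).
#' @param frame_spacing ps between frames (default 1).
#' @return correction factor in `[-1, 1]`.
#' @examples
#' correction_factor(c(2, 1, -1), 2, window = 1, frame_spacing = 1) # 0.5
#' @export
correction_factor <- function(pull_force, frame_index, window = 10,
                              frame_spacing = 1) {
  stopifnot(window > 0, frame_index >= 1, frame_index <= length(pull_force))
  if (any(!is.finite(pull_force))) stop("non-finite forces in series")
  hw <- as.integer(floor(window / frame_spacing))
  lo <- max(1L, frame_index - hw)
  hi <- min(length(pull_force), frame_index + hw)
  w <- pull_force[lo:hi]
  pos <- sum(w[w > 0])
  neg <- abs(sum(w[w < 0]))
  if (pos + neg == 0) return(0)
  (pos - neg) / (pos + neg)
}

# all frames at once (same truncation convention), via running sums
correction_factors <- function(pull_force, window = 10, frame_spacing = 1) {
  if (any(!is.finite(pull_force))) stop("non-finite forces in series")
  n <- length(pull_force)
  hw <- as.integer(floor(window / frame_spacing))
  cp <- c(0, cumsum(pmax(pull_force, 0)))
  cn <- c(0, cumsum(pmax(-pull_force, 0)))
  lo <- pmax(1L, seq_len(n) - hw)
  hi <- pmin(n, seq_len(n) + hw)
  pos <- cp[hi + 1L] - cp[lo]
  neg <- cn[hi + 1L] - cn[lo]
  out <- numeric(n)
  nz <- (pos + neg) > 0
  out[nz] <- (pos[nz] - neg[nz]) / (pos[nz] + neg[nz])
  out
}

#' Raw and force-adjusted contact frequencies
#'
#' Per zone j: `raw_frequency = mean_t contacts[t, j]` and
#' `adjusted_frequency = mean_t contacts[t, j] * cf(t)`, with `cf(t)` the
#' [correction_factor()] of the restraint-force window around frame t. The
#' raw frequency is always reported alongside the adjusted one.
#'
#' @param traj an `abcg_pull_trajectory`.
#' @param window half-window in ps (default 10).
#' @return a `contact_frequency_table`: data.frame with `residue`,
#'   `raw_frequency` in `[0, 1]`, `adjusted_frequency` in `[-1, 1]`;
#'   metadata carried as the `metadata` attribute.
#' @export
adjusted_contact_frequencies <- function(traj, window = 10) {
  stopifnot(inherits(traj, "abcg_pull_trajectory"))
  if (nrow(traj$frames) == 0L) stop("zero-length trajectory")
  cf <- correction_factors(traj$frames$pull_force, window, traj$frame_spacing)
  raw <- colMeans(traj$contacts)
  adj <- as.numeric(crossprod(traj$contacts, cf) / nrow(traj$contacts))
  contact_frequency_table(traj$zones$residue_label, raw, adj, traj$metadata)
}

#' Construct a contact-frequency table
#'
#' @param residue residue labels.
#' @param raw_frequency raw contact frequencies in `[0, 1]`.
#' @param adjusted_frequency force-adjusted frequencies in `[-1, 1]`.
#' @param metadata named list (molecule, variant, replicate, seed, ...).
#' @return data.frame of class `contact_frequency_table`.
#' @export
contact_frequency_table <- function(residue, raw_frequency,
                                    adjusted_frequency, metadata = list()) {
  stopifnot(all(raw_frequency >= 0), all(raw_frequency <= 1),
            all(adjusted_frequency >= -1), all(adjusted_frequency <= 1),
            !anyDuplicated(residue))
  structure(data.frame(residue = as.character(residue),
                       raw_frequency = as.numeric(raw_frequency),
                       adjusted_frequency = as.numeric(adjusted_frequency)),
            metadata = metadata,
            class = c("contact_frequency_table", "data.frame"))
}

#' Write / read a pull trajectory as COLVAR-style text
#'
#' Whitespace table with header `#! FIELDS time z center force` followed by
#' one 0/1 column per residue zone; zone definitions are carried as `# zone`
#' comment lines so the round trip is lossless.
#'
#' @param traj an `abcg_pull_trajectory`.
#' @param path file path.
#' @return `read_pull_trajectory` returns the trajectory;
#'   `write_pull_trajectory` returns `path` invisibly.
#' @export
write_pull_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "abcg_pull_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  z <- traj$zones
  writeLines(sprintf("# zone %s %.17g %.17g", z$residue_label, z$center,
                     z$halfwidth), con)
  writeLines(sprintf("# frame_spacing %.17g", traj$frame_spacing), con)
  writeLines(paste("#! FIELDS time z center force",
                   paste(z$residue_label, collapse = " ")), con)
  f <- traj$frames
  body <- sprintf("%.17g %.17g %.17g %.17g", f$time, f$z,
                  f$restraint_center, f$pull_force)
  flags <- apply(traj$contacts, 1, function(r)
    paste(as.integer(r), collapse = " "))
  writeLines(paste(body, flags), con)
  invisible(path)
}

#' @rdname write_pull_trajectory
#' @export
read_pull_trajectory <- function(path) {
  lines <- readLines(path)
  zl <- lines[startsWith(lines, "# zone ")]
  zp <- do.call(rbind, strsplit(sub("^# zone ", "", zl), " "))
  zones <- residue_zones(zp[, 1], as.numeric(zp[, 2]), as.numeric(zp[, 3]))
  spacing <- as.numeric(sub("^# frame_spacing ", "",
                            lines[startsWith(lines, "# frame_spacing")]))
  body <- lines[!startsWith(lines, "#")]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  frames <- data.frame(time = m[, 1], z = m[, 2], restraint_center = m[, 3],
                       pull_force = m[, 4])
  contacts <- m[, 4 + seq_len(nrow(zones)), drop = FALSE] > 0.5
  colnames(contacts) <- zones$residue_label
  new_pull_trajectory(frames, contacts, zones, spacing)
}

#' Write / read a contact-frequency table as TSV
#'
#' Metadata are carried as `# key: value` header lines.
#'
#' @param tab a [contact_frequency_table()].
#' @param path file path.
#' @return `read_contact_table` returns the table; `write_contact_table`
#'   returns `path` invisibly.
#' @export
write_contact_table <- function(tab, path) {
  stopifnot(inherits(tab, "contact_frequency_table"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- attr(tab, "metadata")
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, as.character(meta[[k]])), con)
  writeLines("residue\traw_frequency\tadjusted_frequency", con)
  writeLines(sprintf("%s\t%.17g\t%.17g", tab$residue, tab$raw_frequency,
                     tab$adjusted_frequency), con)
  invisible(path)
}

#' @rdname write_contact_table
#' @export
read_contact_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "# ")]
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^# ", "", ml)
    k <- sub(":.*$", "", kv)
    meta[[k]] <- trimws(sub("^[^:]*:", "", kv))
  }
  body <- lines[!startsWith(lines, "#")]
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  contact_frequency_table(df$residue, df$raw_frequency,
                          df$adjusted_frequency, meta)
}
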