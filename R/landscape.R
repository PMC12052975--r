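#' Free-energy landscape along the translocation coordinate
#'
#' A landscape is the 1-D free-energy profile \eqn{F(z)} along the
#' translocation coordinate z (the z-component of the ligand position within
#' the transmembrane helix bundle), in kJ/mol over nm. Closed-form archetypes
#' cover the shapes seen in transporter translocation profiles; `tabulated`
#' interpolates a user grid linearly.
#'
#' Kinds and their parameters:
#' \describe{
#'   \item{flat}{no parameters, \eqn{F \equiv 0}.}
#'   \item{harmonic}{`k` (kJ/mol/nm^2), `z0` (nm): \eqn{F = k/2 (z-z_0)^2}.}
#'   \item{double_well}{`barrier` (kJ/mol), `minima` (nm):
#'     \eqn{F = h\,(z^2-a^2)^2/a^4}, minima at \eqn{\pm a}, barrier `h` at 0.}
#'   \item{downhill_barriers}{`slope`, `ref`, plus vectors `barrier_heights`,
#'     `barrier_centers`, `barrier_widths`: a linear downhill trend
#'     \eqn{-s (z - z_{ref})} decorated with Gaussian bumps.}
#'   \item{entry_barrier}{as `downhill_barriers`; by convention carries an
#'     additional entry bump (see [make_landscape()]).}
#'   \item{tabulated}{`grid`, `values`: strictly increasing grid with >= 2
#'     nodes, linear interpolation; at interior nodes the derivative is taken
#'     from the segment on the right (last node: left).}
#' }
#'
#' @param kind one of `"flat"`, `"harmonic"`, `"double_well"`,
#'   `"downhill_barriers"`, `"entry_barrier"`, `"tabulated"`.
#' @param params named list of numeric parameters (see Details).
#' @param domain closed interval `c(z_lo, z_hi)` in nm.
#' @param grid,values tabulated nodes (only for `kind = "tabulated"`).
#' @return an object of class `abcg_landscape`.
#' @examples
#' land <- landscape("harmonic", list(k = 2, z0 = 0))
#' evaluate_landscape(land, 1) # energy 1 kJ/mol, force -2 kJ/mol/nm
#' @export
landscape <- function(kind, params = list(), domain = c(-1.5, 2.4),
                      grid = NULL, values = NULL) {
  kinds <- c(flat = 0L, harmonic = 1L, double_well = 2L,
             downhill_barriers = 3L, entry_barrier = 3L, tabulated = 4L)
  if (!is.character(kind) || length(kind) != 1L || !kind %in% names(kinds))
    stop("unknown landscape kind: ", paste(kind, collapse = ", "))
  stopifnot(is.numeric(domain), length(domain) == 2L, domain[1] < domain[2])
  if (kind == "tabulated") {
    if (is.null(grid) || is.null(values))
      stop("tabulated landscape needs 'grid' and 'values'")
    if (length(grid) < 2L || length(grid) != length(values))
      stop("tabulated landscape needs >= 2 nodes with matching values")
    if (any(diff(grid) <= 0))
      stop("tabulated grid must be strictly increasing")
    if (!all(is.finite(grid)) || !all(is.finite(values)))
      stop("tabulated nodes must be finite")
    domain <- c(max(domain[1], grid[1]), min(domain[2], grid[length(grid)]))
  }
  defaults <- switch(kind,
    harmonic = list(k = 2, z0 = 0),
    double_well = list(barrier = 12, minima = 0.8),
    downhill_barriers = list(slope = 3.2, ref = -1.1,
                             barrier_heights = c(4, 5, 3),
                             barrier_centers = c(-0.3, 0.8, 1.5),
                             barrier_widths = c(0.12, 0.12, 0.12)),
    entry_barrier = list(slope = 3.2, ref = -1.1,
                         barrier_heights = c(4, 5, 3),
                         barrier_centers = c(-0.3, 0.8, 1.5),
                         barrier_widths = c(0.12, 0.12, 0.12)),
    list())
  params <- utils::modifyList(defaults, params)
  if (kind %in% c("downhill_barriers", "entry_barrier")) {
    nb <- length(params$barrier_heights)
    stopifnot(length(params$barrier_centers) == nb,
              length(params$barrier_widths) == nb,
              all(params$barrier_widths > 0))
  }
  if (kind == "double_well")
    stopifnot(params$barrier > 0, params$minima > 0)
  structure(list(kind = kind, kind_code = unname(kinds[kind]),
                 params = params, domain = as.numeric(domain),
                 grid = as.numeric(grid), values = as.numeric(values)),
            class = "abcg_landscape")
}

#' Evaluate a landscape
#'
#' Returns the free energy and the force \eqn{-dF/dz} at each `z`. Points
#' outside the domain are clamped to the nearest endpoint and flagged via the
#' `clamped` attribute (with a warning).
#'
#' @param land an [landscape()] object.
#' @param z numeric vector of positions (nm).
#' @return list with numeric vectors `energy` (kJ/mol) and `force`
#'   (kJ/mol/nm), and attribute `clamped` (logical vector).
#' @export
evaluate_landscape <- function(land, z) {
  stopifnot(inherits(land, "abcg_landscape"), is.numeric(z))
  clamped <- z < land$domain[1] | z > land$domain[2]
  if (any(clamped))
    warning(sum(clamped), " position(s) outside the landscape domain were clamped")
  out <- cpp_eval_landscape(unclass(land), as.numeric(z))
  attr(out, "clamped") <- clamped
  out
}

#' @export
print.abcg_landscape <- function(x, ...) {
  cat("<abcg_landscape> kind:", x$kind,
      sprintf(" domain: [%g, %g] nm\n", x$domain[1], x$domain[2]))
  if (length(x$params))
    cat("  params:", paste(names(x$params), vapply(x$params, function(p)
      paste(signif(p, 4), collapse = ","), ""), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Analytic FES of a landscape on a metadynamics grid
#'
#' Tabulates \eqn{F(z)} (optionally plus wall energy) on the grid of a
#' metadynamics configuration and shifts the minimum to zero, giving the
#' ground-truth surface that a converged reconstruction should recover.
#'
#' @param land an [landscape()] object.
#' @param cfg a [metad_config()].
#' @param walls optional [wall_spec()] whose energy is added.
#' @return an `abcg_fes` object (see [reconstruct_fes()]).
#' @export
landscape_fes <- function(land, cfg, walls = NULL) {
  zg <- fes_grid(cfg)
  zc <- pmin(pmax(zg, land$domain[1]), land$domain[2])
  f <- cpp_eval_landscape(unclass(land), zc)$energy
  if (!is.null(walls)) f <- f + cpp_eval_wall(unclass(walls), zg)$energy
  new_fes(zg, f - min(f), rep(TRUE, length(zg)), cfg)
}
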