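#' Simulation parameters for the synthetic prothallus generator
#'
#' The defaults are the study conditions the generator emulates: the
#' centre-group division and growth rates are the published group means for
#' *S. chinensis* gametophytes over a 48-hr interval (45.64% / 15.10% of
#' cells divided, 157.63% / 132.39% relative total area, centre vs outside),
#' the AC divides obliquely essentially every 48-hr round, and the new
#' wedge-shaped daughter takes a minor fraction of the apical-cell area.
#'
#' @param p_div_ac probability that the apical cell divides (obliquely) per
#'   48-hr step.
#' @param p_div_centre per-cell division probability for centre-group cells.
#' @param p_div_outside per-cell division probability outside the centre.
#' @param growth_centre mean 48-hr area multiplier for centre-group cells.
#' @param growth_outside mean 48-hr area multiplier outside the centre.
#' @param growth_cv coefficient of variation of the lognormal per-cell
#'   growth multiplier.
#' @param wedge_fraction fraction of the apical-cell area given to the
#'   apex-containing (new AC) daughter of the oblique division, in (0, 1).
#' @param n_initial_cells number of cells in the seeded tissue (>= 3; the
#'   apical packet accounts for three of them).
#' @param mean_cell_area mean cell area of the seeded tissue (um^2).
#' @param pixel_size rendering pixel size (um/px).
#' @param seed integer RNG seed.
#' @param trichome_rate probability that a marginal cell is flagged as a
#'   trichome (0 disables trichomes, the default).
#' @param centre_ring adjacency rings around the apical packet included in
#'   the centre group / centre region.
#' @return An object of class `fq_params` (a validated named list).
#' @export
simulation_params <- function(p_div_ac = 1.0,
                              p_div_centre = 0.4564,
                              p_div_outside = 0.1510,
                              growth_centre = 1.5763,
                              growth_outside = 1.3239,
                              growth_cv = 0.15,
                              wedge_fraction = 0.4,
                              n_initial_cells = 60L,
                              mean_cell_area = 350,
                              pixel_size = 0.5,
                              seed = 1L,
                              trichome_rate = 0,
                              centre_ring = 1L) {
  p <- list(p_div_ac = as.numeric(p_div_ac),
            p_div_centre = as.numeric(p_div_centre),
            p_div_outside = as.numeric(p_div_outside),
            growth_centre = as.numeric(growth_centre),
            growth_outside = as.numeric(growth_outside),
            growth_cv = as.numeric(growth_cv),
            wedge_fraction = as.numeric(wedge_fraction),
            n_initial_cells = as.integer(n_initial_cells),
            mean_cell_area = as.numeric(mean_cell_area),
            pixel_size = as.numeric(pixel_size),
            seed = as.integer(seed),
            trichome_rate = as.numeric(trichome_rate),
            centre_ring = as.integer(centre_ring))
  class(p) <- "fq_params"
  validate_params(p)
  p
}

#' Validate simulation parameters
#'
#' @param params an `fq_params` object (or plain list with the same fields).
#' @return The validated object, invisibly.
#' @export
validate_params <- function(params) {
  probs <- c("p_div_ac", "p_div_centre", "p_div_outside", "trichome_rate")
  for (f in probs) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("invalid-parameter: ", f, " must be a probability in [0, 1]")
    }
  }
  for (f in c("growth_centre", "growth_outside")) {
    if (params[[f]] < 1) stop("invalid-parameter: ", f, " must be >= 1")
  }
  if (params$growth_cv < 0) stop("invalid-parameter: growth_cv must be >= 0")
  wf <- params$wedge_fraction
  if (wf <= 0 || wf >= 1) {
    stop("invalid-parameter: wedge_fraction must lie strictly in (0, 1)")
  }
  if (params$n_initial_cells < 1) {
    stop("invalid-parameter: n_initial_cells must be positive")
  }
  if (params$pixel_size <= 0) {
    stop("invalid-parameter: pixel_size must be > 0")
  }
  if (params$mean_cell_area <= 0) {
    stop("invalid-parameter: mean_cell_area must be > 0")
  }
  if (params$centre_ring < 0) {
    stop("invalid-parameter: centre_ring must be >= 0")
  }
  invisible(params)
}

#' Write simulation parameters to YAML
#'
#' @param params `fq_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  writeLines(yaml::as.yaml(unclass(params), precision = 15), path)
  invisible(path)
}

#' Read simulation parameters from YAML
#'
#' @param path YAML file written by [write_params()].
#' @return An `fq_params` object.
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("invalid-parameter: unknown parameter field(s): ",
         paste(unknown, collapse = ", "))
  }
  do.call(simulation_params, vals)
}

#' @export
print.fq_params <- function(x, ...) {
  cat("Simulation parameters (fq_params)\n")
  for (f in names(x)) cat(sprintf("  %-16s %s\n", f, format(x[[f]])))
  invisible(x)
}
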