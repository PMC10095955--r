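# One 48-hr round of growth and division, and the full two-timepoint
# simulation. Growth is realized geometrically: per-cell lognormal area
# multipliers define target areas, the domain is rescaled to the new total,
# and a power-diagram weight fit reproduces each cell's target area (the
# generators are the rescaled cell centroids, so cells stay in place and the
# tissue expands outward from its middle).

lognormal_factors <- function(n, mean_mult, cv) {
  if (cv <= 0) return(rep(mean_mult, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean_mult) - sdlog^2 / 2
  rlnorm(n, meanlog, sdlog)
}

grow_tissue <- function(tissue, factors, tol = 0.005, maxit = 600L) {
  areas <- tissue_areas(tissue)
  targets <- areas * factors
  dom_c <- poly_centroid(tissue$domain)
  s <- sqrt(sum(targets) / poly_area(tissue$domain))
  domain <- scale_polygon(tissue$domain, s, dom_c)
  # generators start from the current cell centroids with size-based
  # weights: cells stay in place and the refit realizes the growth targets
  ord <- names(tissue$polygons)
  pts <- scale_polygon(tissue_centroids(tissue), s, dom_c)
  w0 <- (targets - mean(targets)) / pi
  fit <- cpp_fit_power_weights(pts, targets, domain, w0, tol, maxit, 0.5)
  polys <- cpp_power_cells(fit$pts, fit$w, domain)
  if (any(vapply(polys, nrow, integer(1)) < 3)) {
    stop("geometry error: cell lost during growth fit")
  }
  names(polys) <- names(tissue$polygons)
  tissue$polygons <- polys
  tissue$generators <- fit$pts
  rownames(tissue$generators) <- ord
  tissue$weights <- stats::setNames(as.numeric(fit$w), ord)
  tissue$domain <- domain
  tissue$adjacency <- polygon_adjacency(polys)
  # apex follows the similarity transform, snapped back onto the AC boundary
  apx <- scale_point(tissue$apex_point, s, dom_c)
  acp <- polys[[as.character(ac_id(tissue))]]
  vi <- which.min((acp[, 1] - apx[1])^2 + (acp[, 2] - apx[2])^2)
  tissue$apex_point <- acp[vi, ]
  attr(tissue, "growth_fit_err") <- fit$max_rel_err
  tissue
}

#' Advance a tissue by one 48-hr round of growth and division
#'
#' Each cell's area is first multiplied by a lognormal factor whose mean is
#' the region's growth rate (`growth_centre` within the centre region,
#' `growth_outside` elsewhere) and whose coefficient of variation is
#' `growth_cv`. The AC then divides obliquely with probability `p_div_ac`;
#' every other non-trichome cell divides once with its region's
#' probability. Packet trapezoids choose periclinal or anticlinal
#' orientation uniformly; other cells are anticlinal-biased (70%).
#'
#' @param tissue an `fq_tissue` (typically from [seed_tissue()]).
#' @param params an `fq_params` object. Uses the current RNG state.
#' @return List with `tissue` (at +48 hr), `lineage` (data.frame parent_id,
#'   daughter_id, orientation), `events` (division events), and `growth`
#'   (per-parent drawn and realized area multipliers and regions).
#' @export
step_48h <- function(tissue, params) {
  validate_params(params)
  core_ids <- packet_core_ids(tissue)
  tissue$cells$region <- assign_regions(tissue, params$centre_ring)
  tissue <- refresh_packet(tissue)
  cells0 <- tissue$cells
  areas0 <- tissue_areas(tissue)
  ord <- order(cells0$cell_id)

  # draw growth multipliers in cell-id order
  mean_mult <- ifelse(cells0$region == "centre", params$growth_centre,
                      params$growth_outside)
  factors <- numeric(nrow(cells0))
  factors[ord] <- lognormal_factors(nrow(cells0),  1, params$growth_cv) *
    mean_mult[ord]
  grown <- grow_tissue(tissue, factors)
  areas_grown <- tissue_areas(grown)

  # draw divisions in cell-id order
  p_div <- ifelse(cells0$cell_class == "AC_wedge", params$p_div_ac,
           ifelse(cells0$cell_class == "trichome", 0,
           ifelse(cells0$region == "centre", params$p_div_centre,
                  params$p_div_outside)))
  u <- numeric(nrow(cells0))
  u[ord] <- runif(nrow(cells0))
  divides <- u < p_div
  uo <- numeric(nrow(cells0))
  uo[ord] <- runif(nrow(cells0))
  is_packet_trap <- cells0$packet_member & cells0$cell_class == "trapezoid"
  orientation <- ifelse(cells0$cell_class == "AC_wedge", "oblique",
                 ifelse(is_packet_trap,
                        ifelse(uo < 0.5, "periclinal", "anticlinal"),
                        ifelse(uo < 0.7, "anticlinal", "periclinal")))

  events <- list()
  lineage <- list()
  step_idx <- tissue$step_count + 1L
  for (k in order(cells0$cell_id)) {
    pid <- cells0$cell_id[k]
    if (!divides[k]) {
      lineage[[length(lineage) + 1L]] <-
        data.frame(parent_id = pid, daughter_id = pid, orientation = "none",
                   stringsAsFactors = FALSE)
      next
    }
    res <- apply_division(grown, pid, orientation[k], params,
                          step_index = step_idx)
    grown <- res$tissue
    events[[length(events) + 1L]] <- res$event
    lineage[[length(lineage) + 1L]] <-
      data.frame(parent_id = pid,
                 daughter_id = c(res$event$daughter1, res$event$daughter2),
                 orientation = orientation[k], stringsAsFactors = FALSE)
  }

  grown$timepoint_hr <- tissue$timepoint_hr + 48
  grown$step_count <- step_idx
  lineage <- do.call(rbind, lineage)
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(parent_id = integer(), daughter1 = integer(),
               daughter2 = integer(), orientation = character(),
               step_index = integer())
  growth <- data.frame(cell_id = cells0$cell_id,
                       region = cells0$region,
                       cell_class = cells0$cell_class,
                       area0_um2 = areas0,
                       drawn_factor = factors,
                       realized_factor = areas_grown / areas0,
                       divided = divides,
                       stringsAsFactors = FALSE)
  list(tissue = grown, lineage = lineage, events = events, growth = growth,
       core_ids = core_ids)
}

#' Simulate one gametophyte over a 48-hr interval
#'
#' Seeds a tissue and advances it one 48-hr round under `params`, with the
#' RNG seeded from `params$seed` so identical parameters reproduce
#' bit-identical tissues.
#'
#' @param params an `fq_params` object.
#' @param n_steps number of 48-hr rounds (default 1).
#' @return List with `t0`, `t48` tissues, `lineage` (t0 cell to 1-2
#'   daughters), `events`, and the per-cell `growth` ledger. For
#'   `n_steps > 1` the lineage/growth entries describe the final step and
#'   `steps` holds the full history.
#' @export
simulate_gametophyte <- function(params, n_steps = 1L) {
  validate_params(params)
  set.seed(params$seed)
  t0 <- seed_tissue(params)
  tissue <- t0
  steps <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    steps[[s]] <- step_48h(tissue, params)
    tissue <- steps[[s]]$tissue
  }
  last <- steps[[n_steps]]
  # t0 of the final step, with the packet flags and regions that step used
  t0_final <- if (n_steps == 1L) t0 else steps[[n_steps - 1L]]$tissue
  t0_final$cells$packet_member <- t0_final$cells$cell_id %in% last$core_ids
  t0_final$cells$region <- assign_regions(t0_final, params$centre_ring)
  list(t0 = t0_final, t48 = last$tissue, lineage = last$lineage,
       events = last$events, growth = last$growth, steps = steps,
       params = params)
}
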