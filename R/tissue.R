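# The tissue container: a single-layered polygonal prothallus. `cells` is a
# data.frame keyed by cell_id; `polygons` is a parallel named list of convex
# polygon matrices (microns); `adjacency` holds shared-edge neighbour pairs.

new_tissue <- function(cells, polygons, adjacency, apex_point, domain,
                       timepoint_hr = 0, next_id = NULL, oblique_parity = 1L,
                       step_count = 0L, generators = NULL, weights = NULL) {
  stopifnot(is.data.frame(cells), all(as.integer(names(polygons)) == cells$cell_id))
  if (is.null(next_id)) next_id <- max(cells$cell_id) + 1L
  if (is.null(generators)) {
    generators <- t(vapply(polygons, poly_centroid, numeric(2)))
    rownames(generators) <- names(polygons)
  }
  if (is.null(weights)) {
    weights <- stats::setNames(rep(0, length(polygons)), names(polygons))
  }
  structure(list(cells = cells, polygons = polygons, adjacency = adjacency,
                 apex_point = apex_point, domain = domain,
                 timepoint_hr = timepoint_hr, next_id = as.integer(next_id),
                 oblique_parity = oblique_parity, step_count = step_count,
                 generators = generators, weights = weights),
            class = "fq_tissue")
}

# chord endpoints of a split: the two vertices shared by both daughters
split_chord <- function(d1, d2, tol = 1e-7) {
  hits <- NULL
  for (i in seq_len(nrow(d1))) {
    dd <- sqrt((d2[, 1] - d1[i, 1])^2 + (d2[, 2] - d1[i, 2])^2)
    if (min(dd) < tol) hits <- rbind(hits, d1[i, ])
  }
  if (is.null(hits) || nrow(hits) < 2) return(NULL)
  # farthest-apart pair of shared vertices
  best <- c(1, 2); bd <- -1
  for (i in seq_len(nrow(hits) - 1)) for (j in (i + 1):nrow(hits)) {
    d <- sum((hits[i, ] - hits[j, ])^2)
    if (d > bd) { bd <- d; best <- c(i, j) }
  }
  hits[best, , drop = FALSE]
}

# power-diagram state for two daughters of a chord split: both sites sit at
# the parent site offset a little along the chord normal, and a weight
# asymmetry places their radical axis exactly on the chord, so the split is
# represented in the diagram while neighbours' boundaries barely move
split_site_weights <- function(d1, d2, parent_site, parent_weight) {
  a1 <- poly_area(d1); a2 <- poly_area(d2)
  ch <- split_chord(d1, d2)
  if (is.null(ch)) {
    nrm <- unit_vec(poly_centroid(d1) - poly_centroid(d2))
    m_ch <- (poly_centroid(d1) + poly_centroid(d2)) / 2
    chord_len <- sqrt(min(a1, a2))
  } else {
    u <- unit_vec(ch[2, ] - ch[1, ])
    nrm <- c(-u[2], u[1])
    m_ch <- colMeans(ch)
    chord_len <- sqrt(sum((ch[2, ] - ch[1, ])^2))
  }
  s1 <- sign(sum(nrm * (poly_centroid(d1) - m_ch)))
  if (s1 == 0) s1 <- 1
  delta <- max(0.5, min(1.5, 0.35 * a1 / chord_len, 0.35 * a2 / chord_len))
  c_n <- sum(nrm * (m_ch - parent_site))
  list(sites = rbind(parent_site + s1 * delta * nrm,
                     parent_site - s1 * delta * nrm),
       weights = c(parent_weight + 2 * delta * s1 * c_n,
                   parent_weight - 2 * delta * s1 * c_n))
}

#' @export
print.fq_tissue <- function(x, ...) {
  cat(sprintf("fq_tissue: %d cells at %g hr (%d AC, %d packet, %d centre)\n",
              nrow(x$cells), x$timepoint_hr,
              sum(x$cells$cell_class == "AC_wedge"),
              sum(x$cells$packet_member),
              sum(x$cells$region == "centre")))
  invisible(x)
}

tissue_areas <- function(tissue) {
  vapply(tissue$polygons, poly_area, numeric(1))
}

tissue_centroids <- function(tissue) {
  t(vapply(tissue$polygons, poly_centroid, numeric(2)))
}

ac_id <- function(tissue) {
  tissue$cells$cell_id[tissue$cells$cell_class == "AC_wedge"]
}

#' Validate tissue invariants
#'
#' Checks that the cells tile the domain (areas sum to the domain area),
#' that exactly one wedge-shaped AC is present and is a packet member, that
#' polygons have positive area, and that the adjacency table is consistent
#' with shared edges.
#'
#' @param tissue an `fq_tissue` object.
#' @param tol relative tolerance on the tiling-area check.
#' @return The tissue, invisibly; errors on violation.
#' @export
validate_tissue <- function(tissue, tol = 1e-6) {
  areas <- tissue_areas(tissue)
  if (any(areas <= 0)) stop("tissue invariant violated: zero-area cell")
  da <- poly_area(tissue$domain)
  if (abs(sum(areas) - da) / da > tol) {
    stop("tissue invariant violated: cells do not tile the domain")
  }
  n_ac <- sum(tissue$cells$cell_class == "AC_wedge")
  if (n_ac != 1) stop("tissue invariant violated: ", n_ac, " AC_wedge cells")
  if (!all(tissue$cells$packet_member[tissue$cells$cell_class == "AC_wedge"])) {
    stop("tissue invariant violated: AC_wedge must be a packet member")
  }
  if (nrow(tissue$adjacency) > 0) {
    ids <- tissue$cells$cell_id
    if (!all(tissue$adjacency$id1 %in% ids) || !all(tissue$adjacency$id2 %in% ids)) {
      stop("tissue invariant violated: adjacency references missing cells")
    }
  }
  invisible(tissue)
}

# radially graded relative cell size: small at the apex, large distally,
# mirroring the size gradient seen across a prothallus
size_gradient <- function(d, dmax) {
  0.14 + 2.2 * (pmin(d / dmax, 1))^1.4
}

# dart-throwing point sampler with a radius-graded exclusion distance
sample_generator_points <- function(n, domain_centre, radius, apex,
                                    mean_area) {
  pts <- matrix(numeric(0), ncol = 2)
  rmin_base <- 0.60 * sqrt(mean_area / pi)
  relax <- 1
  attempts <- 0L
  while (nrow(pts) < n && attempts < 400L * n) {
    attempts <- attempts + 1L
    u <- runif(2)
    r <- radius * sqrt(u[1])
    th <- 2 * pi * u[2]
    cand <- domain_centre + r * c(cos(th), sin(th))
    d_apex <- sqrt(sum((cand - apex)^2))
    g <- size_gradient(d_apex, 2 * radius)
    rloc <- rmin_base * sqrt(g) * relax
    ok <- TRUE
    if (nrow(pts) > 0) {
      dd <- sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)
      ok <- all(dd > rloc)
    }
    # keep the apex neighbourhood free for the packet parent
    if (sqrt(sum((cand - apex)^2)) < 1.4 * rmin_base) ok <- FALSE
    if (ok) pts <- rbind(pts, cand)
    if (attempts %% (50L * n) == 0L) relax <- relax * 0.9
  }
  if (nrow(pts) < n) stop("geometry error: could not place generator points")
  pts
}

#' Seed a synthetic prothallus with a three-celled apical packet
#'
#' Builds a single-layered polygonal tissue: a wedge-shaped apical cell (AC)
#' flanked/backed by two trapezoid packet progenies at the apex, plus
#' `n_initial_cells - 3` general cells tiling the rest of a roughly circular
#' prothallus with a small-at-the-apex size gradient. Cell polygons come
#' from an area-fitted power (Laguerre) tessellation of sampled generator
#' points; the packet is carved from the apex cell by two oblique chords.
#'
#' @param params an `fq_params` object (uses the RNG state; call
#'   `set.seed()` or use [simulate_gametophyte()] for reproducibility).
#' @return An `fq_tissue` at 0 hr.
#' @export
seed_tissue <- function(params) {
  validate_params(params)
  n <- params$n_initial_cells
  if (n < 3) stop("invalid-parameter: n_initial_cells must be >= 3")
  mu <- params$mean_cell_area
  radius <- sqrt(n * mu / pi)
  centre <- c(0, -radius)
  apex <- c(0, 0)
  domain <- circle_polygon(centre, radius, n = 64L)

  n_hist <- 0L
  if (n == 3L) {
    polys <- list(domain)
    parent_idx <- 1L
  } else {
    npts <- n - 2L - n_hist
    for (attempt in 1:8) {
      p1 <- matrix(c(0, -0.28 * sqrt(mu)), ncol = 2)
      rest <- sample_generator_points(npts - 1L, centre, radius, apex, mu)
      pts <- rbind(p1, rest)
      d_apex <- sqrt(pts[, 1]^2 + pts[, 2]^2)
      g <- size_gradient(d_apex, 2 * radius)
      g[1] <- g[1] * 6.0  # the apex cell hosts the whole three-celled packet
      targets <- g / sum(g) * poly_area(domain)
      w0 <- (targets - mean(targets)) / pi
      fit <- cpp_fit_power_weights(pts, targets, domain, w0, 0.01, 600L, 0.5)
      polys <- cpp_power_cells(fit$pts, fit$w, domain)
      if (all(vapply(polys, nrow, integer(1)) >= 3) &&
          fit$max_rel_err < 0.2) break
      polys <- NULL
    }
    if (is.null(polys)) {
      stop("geometry error: degenerate cell in seeded tessellation")
    }
    parent_idx <- 1L  # the apex-adjacent generator placed first
  }

  # carve the three-celled packet out of the apex cell with two oblique chords
  parent <- polys[[parent_idx]]
  s1 <- split_polygon(parent, c(1, 0.7), 0.62, apex)
  t1 <- s1$other
  s2 <- split_polygon(s1$ref_side, c(1, -0.7), 0.56, apex)
  ac <- s2$ref_side
  t2 <- s2$other

  others <- polys[-parent_idx]
  # power-diagram state of the tessellated cells and the carved packet
  if (n == 3L) {
    gen_pts <- matrix(numeric(0), ncol = 2)
    gen_w <- numeric(0)
    parent_site <- poly_centroid(parent)
    parent_w <- 0
  } else {
    gen_pts <- fit$pts[-parent_idx, , drop = FALSE]
    gen_w <- fit$w[-parent_idx]
    parent_site <- fit$pts[parent_idx, ]
    parent_w <- fit$w[parent_idx]
  }

  # recently divided packet-neighbour cells: split the closest apex
  # neighbours radially into two fresh halves each
  if (n_hist > 0L && length(others) > 0L) {
    shared <- vapply(others, function(pp)
      cpp_shared_edge_length(parent, pp, 1e-6), numeric(1))
    # only cells large enough that their halves (and those halves' later
    # daughters) remain resolvable
    big <- vapply(others, poly_area, numeric(1)) >= 110
    eligible <- which(shared >= 1 & big)
    cand <- eligible[order(-shared[eligible])]
    cand <- cand[seq_len(min(n_hist, length(cand)))]
    pk_ctr <- poly_centroid(parent)
    for (i in cand) {
      ctr <- poly_centroid(others[[i]])
      sp <- split_polygon(others[[i]], unit_vec(ctr - pk_ctr), 0.5, ctr)
      sw <- split_site_weights(sp$ref_side, sp$other,
                               gen_pts[i, ], gen_w[i])
      others[[i]] <- sp$ref_side
      others <- c(others, list(sp$other))
      gen_pts[i, ] <- sw$sites[1, ]
      gen_pts <- rbind(gen_pts, sw$sites[2, ])
      gen_w[i] <- sw$weights[1]
      gen_w <- c(gen_w, sw$weights[2])
    }
  }

  n_gen <- length(others)
  polygons <- c(others, list(ac, t1, t2))
  ids <- seq_len(n_gen + 3L)
  names(polygons) <- ids

  sw1 <- split_site_weights(s1$ref_side, t1, parent_site, parent_w)
  sw2 <- split_site_weights(ac, t2, sw1$sites[1, ], sw1$weights[1])
  generators <- rbind(gen_pts, sw2$sites[1, ], sw1$sites[2, ], sw2$sites[2, ])
  rownames(generators) <- ids
  weights <- stats::setNames(c(gen_w, sw2$weights[1], sw1$weights[2],
                               sw2$weights[2]), ids)
  cls <- c(rep("general", n_gen), "AC_wedge", "trapezoid", "trapezoid")
  packet <- c(rep(FALSE, n_gen), TRUE, TRUE, TRUE)

  cells <- data.frame(cell_id = ids, cell_class = cls, packet_member = packet,
                      region = "unassigned", stringsAsFactors = FALSE)
  adjacency <- polygon_adjacency(polygons)

  # optional trichomes: marginal cells flagged and excluded downstream
  if (params$trichome_rate > 0 && n_gen > 0) {
    bbd <- vapply(polygons[seq_len(n_gen)], function(p) {
      max(sqrt((p[, 1] - centre[1])^2 + (p[, 2] - centre[2])^2))
    }, numeric(1))
    marginal <- which(bbd > 0.96 * radius)
    flag <- marginal[runif(length(marginal)) < params$trichome_rate]
    cells$cell_class[flag] <- "trichome"
  }

  # apex point snapped onto the AC boundary
  acp <- polygons[[as.character(n_gen + 1L)]]
  vi <- which.min((acp[, 1] - apex[1])^2 + (acp[, 2] - apex[2])^2)
  apex_point <- acp[vi, ]

  tissue <- new_tissue(cells, polygons, adjacency, apex_point, domain,
                       timepoint_hr = 0, generators = generators,
                       weights = weights)
  tissue$cells$region <- assign_regions(tissue, params$centre_ring)
  validate_tissue(tissue)
  tissue
}

# the AC plus its most recently created adjacent trapezoid progenies
# (recency by cell id, ids being fresh and increasing). The 3-cell form is
# the division-grammar packet; the wider core (up to 4 progenies, i.e. the
# previous round's five-celled packet) anchors the centre-of-meristem group.
packet_core_ids <- function(tissue, max_progenies = 4L) {
  acid <- ac_id(tissue)
  nbrs <- adjacency_neighbours(tissue$adjacency, acid)
  trap <- tissue$cells$cell_id[tissue$cells$cell_class == "trapezoid" &
                               tissue$cells$cell_id %in% nbrs]
  sort(c(acid, utils::tail(sort(trap), max_progenies)))
}

#' Assign centre/outside regions
#'
#' The centre region is the apical packet core (the AC and its recent
#' packet progenies) plus all cells within `ring` adjacency steps of it;
#' all other non-trichome cells are outside. Trichomes stay `unassigned`
#' (they are excluded from quantification).
#'
#' @param tissue an `fq_tissue`.
#' @param ring number of adjacency rings around the packet (default 1).
#' @return Character vector of regions aligned with `tissue$cells`.
#' @export
assign_regions <- function(tissue, ring = 1L) {
  core <- packet_core_ids(tissue)
  centre_ids <- adjacency_ring(tissue$adjacency, core, ring)
  region <- ifelse(tissue$cells$cell_id %in% centre_ids, "centre", "outside")
  region[tissue$cells$cell_class == "trichome"] <- "unassigned"
  region
}

# refresh the packet definition at the start of a 48-hr round: the AC plus
# its two most recently created adjacent trapezoid progenies
refresh_packet <- function(tissue) {
  keep <- packet_core_ids(tissue, max_progenies = 2L)
  tissue$cells$packet_member <- tissue$cells$cell_id %in% keep
  tissue
}
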