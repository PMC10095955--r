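# Oriented cell divisions. Orientations follow the meristem geometry: the
# radial axis of a cell points from the apex (notch) towards the cell
# centroid; "periclinal" chords run parallel to the local margin
# (perpendicular to that axis), "anticlinal" chords perpendicular to the
# margin (parallel to the axis), and the AC's "oblique" chord is tilted 45
# degrees off the axis, alternating sides between successive rounds.

division_orientations <- c("oblique", "periclinal", "anticlinal")

division_chord <- function(tissue, cell_id, orientation) {
  poly <- tissue$polygons[[as.character(cell_id)]]
  ctr <- poly_centroid(poly)
  axis <- unit_vec(ctr - tissue$apex_point)
  switch(orientation,
         oblique = rotate_vec(axis, tissue$oblique_parity * pi / 4),
         periclinal = c(-axis[2], axis[1]),
         anticlinal = axis,
         stop("unknown division orientation: ", orientation))
}

#' Apply one oriented cell division
#'
#' Replaces the parent cell with two daughters separated by a straight
#' chord. An oblique division is only legal on the wedge-shaped AC (and the
#' AC only ever divides obliquely): the apex-containing daughter becomes the
#' new AC with `wedge_fraction` of the parent area and its sibling becomes a
#' trapezoid packet member. Periclinal and anticlinal divisions split the
#' cell in half. Daughter ids are fresh; adjacency is updated locally; the
#' daughters tile the parent exactly.
#'
#' @param tissue an `fq_tissue`.
#' @param cell_id id of the dividing cell.
#' @param orientation one of `"oblique"`, `"periclinal"`, `"anticlinal"`.
#' @param params an `fq_params` object (supplies `wedge_fraction`).
#' @param step_index integer index recorded in the division event.
#' @return List with the updated `tissue` and the `event` record
#'   (parent_id, daughter_ids, orientation, step_index).
#' @export
apply_division <- function(tissue, cell_id, orientation, params,
                           step_index = tissue$step_count + 1L) {
  key <- as.character(cell_id)
  row <- match(cell_id, tissue$cells$cell_id)
  if (is.na(row)) stop("unknown cell id: ", cell_id)
  orientation <- match.arg(orientation, division_orientations)
  is_ac <- tissue$cells$cell_class[row] == "AC_wedge"
  if (orientation == "oblique" && !is_ac) {
    stop("orientation-violation: oblique division is only legal on the AC")
  }
  if (is_ac && orientation != "oblique") {
    stop("orientation-violation: the AC divides obliquely")
  }

  poly <- tissue$polygons[[key]]
  dirv <- division_chord(tissue, cell_id, orientation)
  frac <- if (orientation == "oblique") params$wedge_fraction else 0.5
  sp <- split_polygon(poly, dirv, frac, tissue$apex_point)
  a1 <- poly_area(sp$ref_side); a2 <- poly_area(sp$other)
  if (min(a1, a2) <= 1e-9) stop("geometry error: degenerate daughter cell")

  d1 <- tissue$next_id; d2 <- tissue$next_id + 1L
  parent_class <- tissue$cells$cell_class[row]
  parent_packet <- tissue$cells$packet_member[row]
  parent_region <- tissue$cells$region[row]
  if (orientation == "oblique") {
    classes <- c("AC_wedge", "trapezoid")
    packet <- c(TRUE, TRUE)
    tissue$oblique_parity <- -tissue$oblique_parity
  } else {
    classes <- rep(parent_class, 2)
    packet <- rep(parent_packet, 2)
  }

  old_nbrs <- adjacency_neighbours(tissue$adjacency, cell_id)
  # drop the parent
  tissue$cells <- tissue$cells[-row, , drop = FALSE]
  tissue$polygons[[key]] <- NULL
  keep <- !(tissue$adjacency$id1 == cell_id | tissue$adjacency$id2 == cell_id)
  tissue$adjacency <- tissue$adjacency[keep, , drop = FALSE]

  tissue$cells <- rbind(tissue$cells,
                        data.frame(cell_id = c(d1, d2),
                                   cell_class = classes,
                                   packet_member = packet,
                                   region = rep(parent_region, 2),
                                   stringsAsFactors = FALSE))
  tissue$polygons[[as.character(d1)]] <- sp$ref_side
  tissue$polygons[[as.character(d2)]] <- sp$other
  # daughters' power-diagram sites: parent site nudged along the chord
  # normal with a weight asymmetry that puts their radical axis on the
  # division chord (see split_site_weights)
  sw <- split_site_weights(sp$ref_side, sp$other,
                           tissue$generators[key, ], tissue$weights[[key]])
  gg <- sw$sites
  w_d <- sw$weights
  # local adjacency update: daughters can only touch each other and the
  # parent's former neighbours
  cand <- rbind(c(d1, d2),
                cbind(rep(c(d1, d2), each = length(old_nbrs)),
                      rep(old_nbrs, 2)))
  add1 <- integer(0); add2 <- integer(0); addl <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    l <- cpp_shared_edge_length(tissue$polygons[[as.character(i)]],
                                tissue$polygons[[as.character(j)]], 1e-6)
    if (l >= 1.0) {
      add1 <- c(add1, min(i, j)); add2 <- c(add2, max(i, j)); addl <- c(addl, l)
    }
  }
  tissue$adjacency <- rbind(tissue$adjacency,
                            data.frame(id1 = add1, id2 = add2, shared_um = addl))
  tissue$next_id <- d2 + 1L

  tissue$generators <- tissue$generators[rownames(tissue$generators) != key, ,
                                         drop = FALSE]
  tissue$generators <- rbind(tissue$generators, gg)
  rownames(tissue$generators)[nrow(tissue$generators) - 1:0] <- c(d1, d2)
  tissue$weights <- tissue$weights[names(tissue$weights) != key]
  tissue$weights[as.character(c(d1, d2))] <- w_d

  if (orientation == "oblique") {
    # apex follows the new AC boundary
    acp <- sp$ref_side
    vi <- which.min((acp[, 1] - tissue$apex_point[1])^2 +
                    (acp[, 2] - tissue$apex_point[2])^2)
    tissue$apex_point <- acp[vi, ]
  }

  event <- data.frame(parent_id = cell_id, daughter1 = d1, daughter2 = d2,
                      orientation = orientation, step_index = step_index,
                      stringsAsFactors = FALSE)
  list(tissue = tissue, event = event)
}
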