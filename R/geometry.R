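# Planar polygon utilities used throughout the simulator. All polygons are
# n x 2 matrices of vertices in counter-clockwise order; units are microns.

#' Polygon area (shoelace formula)
#'
#' @param vertices n x 2 matrix of polygon vertices (ordered).
#' @return Unsigned area.
#' @export
poly_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Polygon centroid
#'
#' @param vertices n x 2 matrix of polygon vertices (ordered).
#' @return Numeric length-2 centroid (x, y).
#' @export
poly_centroid <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

#' Test whether a point lies inside a polygon
#'
#' Ray-casting test; points on the boundary may fall on either side.
#'
#' @param pt length-2 point.
#' @param vertices polygon matrix.
#' @return Logical.
#' @export
point_in_polygon <- function(pt, vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  crosses <- ((y > pt[2]) != (y[j] > pt[2])) &
    (pt[1] < (x[j] - x) * (pt[2] - y) / (y[j] - y) + x)
  sum(crosses, na.rm = TRUE) %% 2 == 1
}

# regular polygon approximating a circle, counter-clockwise
circle_polygon <- function(centre, radius, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(centre[1] + radius * cos(th), centre[2] + radius * sin(th))
}

# similarity transform: scale about a centre point
scale_polygon <- function(vertices, s, centre) {
  sweep(sweep(vertices, 2, centre, "-") * s, 2, centre, "+")
}

scale_point <- function(pt, s, centre) {
  (pt - centre) * s + centre
}

poly_bbox <- function(vertices) {
  c(xmin = min(vertices[, 1]), xmax = max(vertices[, 1]),
    ymin = min(vertices[, 2]), ymax = max(vertices[, 2]))
}

#' Split a convex polygon by an area-calibrated chord
#'
#' Cuts the polygon with a straight chord of the given direction, placed so
#' that the daughter containing (or nearest to) `ref_point` receives the
#' fraction `frac` of the parent area. Daughters tile the parent exactly.
#'
#' @param vertices convex polygon matrix.
#' @param direction length-2 chord direction vector.
#' @param frac area fraction in (0, 1) given to the reference-side daughter.
#' @param ref_point length-2 reference point.
#' @return List with elements `ref_side` and `other`, both polygon matrices.
#' @export
split_polygon <- function(vertices, direction, frac, ref_point) {
  stopifnot(frac > 0, frac < 1)
  cpp_split_polygon_frac(vertices, direction[1], direction[2], frac,
                         ref_point[1], ref_point[2])
}

# adjacency between polygons from shared boundary edges; candidate pairs are
# pre-filtered by bounding-box overlap
#' Shared-edge adjacency of a set of polygons
#'
#' Two cells are adjacent when their boundaries share a collinear segment of
#' length at least `min_shared` microns.
#'
#' @param polygons named list of polygon matrices (names = cell ids).
#' @param min_shared minimum shared edge length (microns).
#' @param tol collinearity tolerance (microns).
#' @return data.frame with columns `id1`, `id2`, `shared_um` (id1 < id2).
#' @export
polygon_adjacency <- function(polygons, min_shared = 1.0, tol = 1e-6) {
  ids <- as.integer(names(polygons))
  n <- length(polygons)
  if (n < 2) {
    return(data.frame(id1 = integer(), id2 = integer(), shared_um = numeric()))
  }
  bb <- t(vapply(polygons, poly_bbox, numeric(4)))
  out1 <- integer(0); out2 <- integer(0); len <- numeric(0)
  eps <- 1e-6
  for (i in seq_len(n - 1L)) {
    js <- which(bb[, "xmin"] <= bb[i, "xmax"] + eps &
                bb[, "xmax"] >= bb[i, "xmin"] - eps &
                bb[, "ymin"] <= bb[i, "ymax"] + eps &
                bb[, "ymax"] >= bb[i, "ymin"] - eps)
    js <- js[js > i]
    for (j in js) {
      l <- cpp_shared_edge_length(polygons[[i]], polygons[[j]], tol)
      if (l >= min_shared) {
        out1 <- c(out1, ids[i]); out2 <- c(out2, ids[j]); len <- c(len, l)
      }
    }
  }
  data.frame(id1 = out1, id2 = out2, shared_um = len)
}

# neighbours of a set of ids in an adjacency table
adjacency_neighbours <- function(adjacency, ids) {
  sel <- adjacency$id1 %in% ids | adjacency$id2 %in% ids
  setdiff(unique(c(adjacency$id1[sel], adjacency$id2[sel])), ids)
}

# ids within `ring` adjacency steps of the seed set (seed included)
adjacency_ring <- function(adjacency, seed_ids, ring) {
  members <- seed_ids
  frontier <- seed_ids
  k <- 0L
  while (k < ring && length(frontier) > 0) {
    frontier <- setdiff(adjacency_neighbours(adjacency, frontier), members)
    members <- c(members, frontier)
    k <- k + 1L
  }
  sort(members)
}

rotate_vec <- function(v, angle) {
  c(cos(angle) * v[1] - sin(angle) * v[2],
    sin(angle) * v[1] + cos(angle) * v[2])
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(c(0, 1))
  v / n
}
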