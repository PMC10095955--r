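# Shared fixtures and independent oracles for the test suite.

# cache simulations so several tests can reuse one realization
.fq_cache <- new.env(parent = emptyenv())

cached_sim <- function(seed = 1, n = 60, n_steps = 1) {
  key <- paste(seed, n, n_steps, sep = "_")
  if (is.null(.fq_cache[[key]])) {
    p <- simulation_params(seed = seed, n_initial_cells = n)
    .fq_cache[[key]] <- list(params = p,
                             sim = simulate_gametophyte(p, n_steps = n_steps))
  }
  .fq_cache[[key]]
}

cached_render <- function(seed = 1, n = 60, n_steps = 1,
                          noise = list(gaussian_sd = 0, poisson_scale = 0)) {
  key <- paste("r", seed, n, n_steps, noise$gaussian_sd, sep = "_")
  if (is.null(.fq_cache[[key]])) {
    cs <- cached_sim(seed, n, n_steps)
    set.seed(seed + 1000)
    .fq_cache[[key]] <- render_image_pair(cs$sim$t0, cs$sim$t48, cs$params,
                                          noise = noise)
  }
  .fq_cache[[key]]
}

# independent oracle: intersection area of two convex polygons by
# Sutherland-Hodgman clipping written directly in the test helper
oracle_convex_intersection_area <- function(a, b) {
  poly <- a
  nb <- nrow(b)
  for (i in seq_len(nb)) {
    if (nrow(poly) < 3) return(0)
    p1 <- b[i, ]; p2 <- b[if (i == nb) 1 else i + 1, ]
    # inside = left of the directed edge p1 -> p2 (b is counter-clockwise)
    side <- function(q) (p2[1] - p1[1]) * (q[2] - p1[2]) -
      (p2[2] - p1[2]) * (q[1] - p1[1])
    out <- NULL
    np <- nrow(poly)
    for (j in seq_len(np)) {
      cur <- poly[j, ]; nxt <- poly[if (j == np) 1 else j + 1, ]
      sc <- side(cur); sn <- side(nxt)
      if (sc >= 0) out <- rbind(out, cur)
      if ((sc > 0 && sn < 0) || (sc < 0 && sn > 0)) {
        t <- sc / (sc - sn)
        out <- rbind(out, cur + t * (nxt - cur))
      }
    }
    poly <- out
    if (is.null(poly)) return(0)
  }
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# independent shoelace area (kept separate from the package's helper)
oracle_shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

# a minimal hand-built tissue containing one general square cell and a
# remote AC, used to probe single divisions with controlled geometry
toy_square_tissue <- function(side = 10, apex = c(side / 2, 3 * side)) {
  sq <- cbind(c(0, side, side, 0), c(0, 0, side, side))
  ac <- cbind(c(0, side, side / 2), c(2 * side, 2 * side, 2.5 * side))
  cells <- data.frame(cell_id = c(1L, 2L),
                      cell_class = c("general", "AC_wedge"),
                      packet_member = c(FALSE, TRUE),
                      region = c("outside", "centre"),
                      stringsAsFactors = FALSE)
  polys <- list(`1` = sq, `2` = ac)
  adj <- data.frame(id1 = integer(), id2 = integer(), shared_um = numeric())
  fernquant:::new_tissue(cells, polys, adj, apex_point = apex,
                         domain = cbind(c(-1, 11, 11, -1), c(-1, -1, 31, 31)))
}

# accuracy of a lineage against the simulator truth
lineage_accuracy <- function(lineage, truth) {
  m <- merge(lineage$assignments[, c("parent_id", "daughter_id")],
             truth[, c("parent_id", "daughter_id")],
             by = "daughter_id", all = TRUE)
  mean(!is.na(m$parent_id.x) & !is.na(m$parent_id.y) &
         m$parent_id.x == m$parent_id.y)
}
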