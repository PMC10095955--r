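# Two-timepoint lineage matching: register the frames by integer
# translation, assign each 48-hr cell to the 0-hr cell with maximal pixel
# overlap, keep at most the two largest-overlap daughters per parent, and
# call a division when a parent retained exactly two daughters.

#' Register two label masks by integer translation
#'
#' Maximizes foreground overlap of the binarized masks by circular
#' cross-correlation (FFT). The shift is the integer (dx, dy) displacement
#' of frame 48 relative to frame 0 in pixel units: applying the negative of
#' this shift to mask48 aligns it onto mask0.
#'
#' @param mask0,mask48 integer label matrices of equal size.
#' @return Integer vector `c(drow, dcol)`.
#' @export
register_frames <- function(mask0, mask48) {
  stopifnot(all(dim(mask0) == dim(mask48)))
  a <- (mask0 > 0) * 1
  b <- (mask48 > 0) * 1
  if (sum(a) == 0 || sum(b) == 0) {
    stop("registration error: empty foreground")
  }
  # overlap(s) = sum_x a(x) b(x - s), all shifts at once via FFT
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / length(a)
  pk <- which.max(cc)
  H <- nrow(a); W <- ncol(a)
  # the peak k satisfies mask0 ~ roll(mask48, k); the displacement of
  # frame 48 relative to frame 0 is its negative
  dr <- (pk - 1L) %% H
  dc <- (pk - 1L) %/% H
  if (dr > H / 2) dr <- dr - H
  if (dc > W / 2) dc <- dc - W
  best <- max(cc)
  if (best / min(sum(a), sum(b)) < 0.3) {
    warning("registration is weak: best overlap below 30% of the foreground")
  }
  c(drow = -as.integer(dr), dcol = -as.integer(dc))
}

#' Similarity registration of two label masks
#'
#' A tissue whose every cell expands by 30-60% over 48 hr dilates about its
#' middle, so distal cells move by more than a cell diameter and no
#' translation can align the frames. This estimates the isotropic scale
#' from the foreground areas, maps the 48-hr mask back onto the 0-hr frame
#' about the foreground centroids (nearest-neighbour warp), and refines
#' with an integer translation.
#'
#' @param mask0,mask48 integer label matrices of equal size.
#' @return List with `scale`, `shift` (residual integer translation of the
#'   warped mask), and `warped` (mask48 resampled onto the 0-hr frame).
#' @export
register_similarity <- function(mask0, mask48) {
  stopifnot(all(dim(mask0) == dim(mask48)))
  f0 <- mask0 > 0; f48 <- mask48 > 0
  if (sum(f0) == 0 || sum(f48) == 0) {
    stop("registration error: empty foreground")
  }
  s <- sqrt(sum(f48) / sum(f0))
  idx0 <- which(f0, arr.ind = TRUE)
  idx48 <- which(f48, arr.ind = TRUE)
  c0 <- colMeans(idx0); c48 <- colMeans(idx48)
  H <- nrow(mask0); W <- ncol(mask0)
  # inverse mapping: target (0-hr frame) pixel -> source pixel in mask48
  src_r <- round(c48[1] + s * (seq_len(H) - c0[1]))
  src_c <- round(c48[2] + s * (seq_len(W) - c0[2]))
  ok_r <- src_r >= 1 & src_r <= H
  ok_c <- src_c >= 1 & src_c <= W
  warped <- matrix(0L, H, W)
  warped[ok_r, ok_c] <- mask48[src_r[ok_r], src_c[ok_c]]
  shift <- register_frames(mask0, warped)
  if (any(shift != 0L)) {
    warped <- shift_matrix(warped, -shift[1], -shift[2])
  }
  list(scale = s, shift = shift, warped = warped)
}

# integer-roll a matrix with zero fill
shift_matrix <- function(m, drow, dcol) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  src_r <- seq_len(H) - drow
  src_c <- seq_len(W) - dcol
  ok_r <- src_r >= 1 & src_r <= H
  ok_c <- src_c >= 1 & src_c <= W
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# label centroids (row, col) of an integer mask
label_centroids_px <- function(mask) {
  idx <- which(mask > 0)
  lab <- mask[idx]
  H <- nrow(mask)
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  cbind(r = as.vector(tapply(rows, lab, mean)),
        c = as.vector(tapply(cols, lab, mean)),
        id = as.integer(names(tapply(rows, lab, mean))))
}

# all daughter/parent overlap candidates between two aligned masks, scored
# by the Dice coefficient (robust against a large neighbour grazing a small
# displaced cell)
overlap_candidates <- function(mask0, m48) {
  sel <- mask0 > 0 & m48 > 0
  if (!any(sel)) return(NULL)
  tab <- table(parent = mask0[sel], daughter = m48[sel])
  d_ids <- as.integer(colnames(tab))
  p_ids <- as.integer(rownames(tab))
  area0 <- tabulate(mask0[mask0 > 0])
  a48 <- tabulate(m48[m48 > 0])
  dice <- 2 * unclass(tab) / outer(area0[p_ids], a48[d_ids], "+")
  nz <- which(unclass(tab) > 0, arr.ind = TRUE)
  data.frame(daughter_id = d_ids[nz[, 2]],
             parent_id = p_ids[nz[, 1]],
             overlap_px = as.integer(tab[nz]),
             dice = as.numeric(dice[nz]))
}

# capacity-constrained greedy assignment: best Dice first, at most two
# daughters per parent; a daughter displaced off its best candidate falls
# back to its next one
greedy_capacity_assign <- function(cand) {
  cand <- cand[order(-cand$dice, cand$daughter_id), , drop = FALSE]
  n_assigned <- integer(max(cand$parent_id))
  taken <- logical(max(cand$daughter_id))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    d <- cand$daughter_id[i]; p <- cand$parent_id[i]
    if (taken[d] || n_assigned[p] >= 2L) next
    taken[d] <- TRUE
    n_assigned[p] <- n_assigned[p] + 1L
    keep[i] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$parent_id, out$daughter_id), , drop = FALSE]
}

# residual drift samples from the current assignment: 1:1 matches give
# daughter-minus-parent centroid displacements; divided parents give the
# displacement of the daughters' combined (area-weighted) centroid, which
# covers the actively dividing regions
drift_anchors <- function(asg, c0, c48, m48) {
  if (nrow(asg) == 0) return(NULL)
  a48 <- tabulate(m48[m48 > 0])
  out <- lapply(split(seq_len(nrow(asg)), asg$parent_id), function(i) {
    p <- asg$parent_id[i[1]]
    ds <- asg$daughter_id[i]
    p_row <- match(p, c0[, "id"])
    d_rows <- match(ds, c48[, "id"])
    if (is.na(p_row) || anyNA(d_rows)) return(NULL)
    wt <- a48[ds]
    pos <- c(sum(c48[d_rows, "r"] * wt), sum(c48[d_rows, "c"] * wt)) / sum(wt)
    data.frame(r = unname(pos[1]), c = unname(pos[2]),
               ur = unname(pos[1] - c0[p_row, "r"]),
               uc = unname(pos[2] - c0[p_row, "c"]),
               daughters = I(list(ds)), row.names = NULL)
  })
  anc <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(anc) || nrow(anc) < 4) return(anc)
  # median-trim: a mis-assignment produces a drift sample inconsistent with
  # its neighbourhood; replace such samples by the local median
  for (k in seq_len(nrow(anc))) {
    dd <- sqrt((anc$r - anc$r[k])^2 + (anc$c - anc$c[k])^2)
    dd[k] <- Inf
    near <- order(dd)[seq_len(min(8L, nrow(anc) - 1L))]
    mr <- stats::median(anc$ur[near]); mc <- stats::median(anc$uc[near])
    if (abs(anc$ur[k] - mr) > 4 || abs(anc$uc[k] - mc) > 4) {
      anc$ur[k] <- mr; anc$uc[k] <- mc
    }
  }
  anc
}

# recompute each daughter's overlap candidates after subtracting the local
# drift (inverse-distance-weighted over the nearest anchors, excluding
# anchors the daughter itself contributes to)
drift_candidates <- function(mask0, m48, c48, anchors, area0_all) {
  H <- nrow(mask0); W <- ncol(mask0)
  res <- vector("list", nrow(c48))
  for (k in seq_len(nrow(c48))) {
    d <- c48[k, "id"]
    dd <- sqrt((anchors$r - c48[k, "r"])^2 + (anchors$c - c48[k, "c"])^2)
    dd[vapply(anchors$daughters, function(z) d %in% z, logical(1))] <- Inf
    near <- order(dd)[seq_len(min(6L, sum(is.finite(dd))))]
    if (!length(near)) next
    wgt <- 1 / (dd[near]^2 + 25)
    ur <- round(sum(anchors$ur[near] * wgt) / sum(wgt))
    uc <- round(sum(anchors$uc[near] * wgt) / sum(wgt))
    idx <- which(m48 == d)
    rows <- (idx - 1L) %% H + 1L - ur
    cols <- (idx - 1L) %/% H + 1L - uc
    okpx <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
    if (!any(okpx)) next
    ov <- mask0[cbind(rows[okpx], cols[okpx])]
    ov <- ov[ov > 0]
    if (!length(ov)) next
    tb <- table(ov)
    p_ids <- as.integer(names(tb))
    res[[k]] <- data.frame(daughter_id = d, parent_id = p_ids,
                           overlap_px = as.integer(tb),
                           dice = 2 * as.integer(tb) /
                             (area0_all[p_ids] + length(idx)))
  }
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}

# growth-consistency repair: cells roughly conserve area through division
# and grow by a bounded factor, so a parent whose assigned daughters imply
# a strong shrinkage is probably missing a daughter that a neighbouring
# parent (with implausibly large implied growth) captured by overlap alone
repair_by_growth <- function(asg, cand, mask0, m48) {
  if (nrow(asg) < 2) return(asg)
  a0 <- tabulate(mask0[mask0 > 0])
  a48 <- tabulate(m48[m48 > 0])
  implied <- function(a) {
    tot <- tapply(a48[a$daughter_id], a$parent_id, sum)
    tot / a0[as.integer(names(tot))]
  }
  for (pass in 1:3) {
    g <- implied(asg)
    deficit <- as.integer(names(g))[g < 0.8]
    # a thief parent either shows implausible implied growth, or presents
    # as "divided" while one daughter is a near-whole-cell (Dice >= 0.7)
    # match: true division daughters cannot exceed ~2/3
    two_d <- names(which(table(asg$parent_id) == 2))
    fake_div <- vapply(as.integer(two_d), function(q) {
      max(asg$dice[asg$parent_id == q]) >= 0.7
    }, logical(1))
    surplus <- union(as.integer(names(g))[g > 1.4],
                     as.integer(two_d)[fake_div])
    if (!length(deficit) || !length(surplus)) break
    moved <- FALSE
    for (p in deficit) {
      if (sum(asg$parent_id == p) >= 2) next
      # daughters of surplus parents that also overlap p
      opts <- cand[cand$parent_id == p &
                   cand$daughter_id %in%
                     asg$daughter_id[asg$parent_id %in% surplus], ,
                   drop = FALSE]
      if (!nrow(opts)) next
      opts <- opts[order(-opts$overlap_px), , drop = FALSE]
      for (i in seq_len(nrow(opts))) {
        d <- opts$daughter_id[i]
        q <- asg$parent_id[asg$daughter_id == d]
        if (sum(asg$parent_id == q) < 2) next  # do not orphan q
        old_dev <- abs(g[[as.character(p)]] - 1.1) +
          abs(g[[as.character(q)]] - 1.1)
        gp_new <- (sum(a48[asg$daughter_id[asg$parent_id == p]]) + a48[d]) / a0[p]
        gq_new <- (sum(a48[asg$daughter_id[asg$parent_id == q]]) - a48[d]) / a0[q]
        if (abs(gp_new - 1.1) + abs(gq_new - 1.1) < old_dev - 0.1) {
          asg$parent_id[asg$daughter_id == d] <- p
          asg$overlap_px[asg$daughter_id == d] <- opts$overlap_px[i]
          moved <- TRUE
          break
        }
      }
      if (moved) break
    }
    if (!moved) break
  }
  asg[order(asg$parent_id, asg$daughter_id), , drop = FALSE]
}

# attach below-threshold daughters to parents whose assigned daughters
# leave an implausible area deficit (implied 48/0 ratio < 0.8); the move
# must bring the parent's implied growth into a plausible range
rescue_unmatched <- function(assign, unmatched, cand, mask0, m48) {
  if (!length(unmatched)) return(assign)
  a0 <- tabulate(mask0[mask0 > 0])
  a48 <- tabulate(m48[m48 > 0])
  for (d in unmatched) {
    opts <- cand[cand$daughter_id == d, , drop = FALSE]
    if (!nrow(opts)) next
    opts <- opts[order(-opts$overlap_px), , drop = FALSE]
    for (i in seq_len(nrow(opts))) {
      p <- opts$parent_id[i]
      nd <- sum(assign$parent_id == p)
      if (nd >= 2L) next
      g_now <- sum(a48[assign$daughter_id[assign$parent_id == p]]) / a0[p]
      g_new <- g_now + a48[d] / a0[p]
      if (g_now < 0.8 && g_new < 1.6 &&
          abs(g_new - 1.1) < abs(g_now - 1.1)) {
        assign <- rbind(assign,
                        data.frame(parent_id = p, daughter_id = d,
                                   overlap_px = opts$overlap_px[i]))
        break
      }
    }
  }
  assign
}

#' Match cells between 0 hr and 48 hr by maximal label overlap
#'
#' After registration, each 48-hr label is assigned to the 0-hr label with
#' which it shares the most pixels (ties and near-ties resolved by the Dice
#' coefficient). With `refine = TRUE` a second pass estimates a local
#' residual drift for every 48-hr cell from its confidently matched
#' neighbours (inverse-distance-weighted centroid displacements) and
#' re-scores the overlaps after subtracting that drift, which recovers
#' small cells in regions growing faster than the frame average.
#' Assignments whose overlap is below `min_overlap_frac` of the 48-hr cell
#' area are reported unmatched, and at most the two largest-overlap
#' daughters are retained per parent (extras are flagged and moved to the
#' unmatched list).
#'
#' @param mask0,mask48 integer label matrices of equal size.
#' @param min_overlap_frac minimum overlap as a fraction of the t48 area.
#' @param shift integer registration shift `c(drow, dcol)` of frame 48
#'   relative to frame 0 (e.g. from [register_frames()]).
#' @param refine run the local drift-refinement pass.
#' @return An `fq_lineage`: list with `assignments` (parent_id,
#'   daughter_id, overlap_px), `unmatched_t48`, `extra_daughters`,
#'   `registration_shift`.
#' @export
match_overlap <- function(mask0, mask48, min_overlap_frac = 0.2,
                          shift = c(0L, 0L), refine = TRUE) {
  stopifnot(all(dim(mask0) == dim(mask48)))
  m48 <- if (any(shift != 0L)) shift_matrix(mask48, -shift[1], -shift[2]) else mask48
  area48 <- tabulate(mask48[mask48 > 0])
  unmatched <- integer(0)
  assign <- data.frame(parent_id = integer(), daughter_id = integer(),
                       overlap_px = integer())
  extras <- integer(0)
  cand <- overlap_candidates(mask0, m48)
  if (!is.null(cand)) {
    cand_raw <- cand
    asg_raw <- greedy_capacity_assign(cand_raw)
    asg <- asg_raw
    if (refine) {
      c0 <- label_centroids_px(mask0)
      c48 <- label_centroids_px(m48)
      area0_all <- tabulate(mask0[mask0 > 0])
      for (iter in 1:3) {
        anchors <- drift_anchors(asg, c0, c48, m48)
        if (is.null(anchors) || nrow(anchors) < 4) break
        cand2 <- drift_candidates(mask0, m48, c48, anchors, area0_all)
        # the drift-corrected view supersedes the raw one wherever the
        # correction is nonzero (daughters without correction keep their
        # raw candidates)
        cand_new <- rbind(
          cand[!(cand$daughter_id %in% cand2$daughter_id), , drop = FALSE],
          cand2)
        asg2 <- greedy_capacity_assign(cand_new)
        if (identical(asg2, asg)) { cand <- cand_new; break }
        asg <- asg2
        cand <- cand_new
      }
    }
    asg <- repair_by_growth(asg, cand, mask0, m48)
    ok <- asg$overlap_px >= min_overlap_frac * area48[asg$daughter_id]
    unmatched <- asg$daughter_id[!ok]
    assign <- asg[ok, c("parent_id", "daughter_id", "overlap_px"),
                  drop = FALSE]
    # rescue: a small daughter displaced beyond its own diameter fails the
    # overlap threshold, but a parent left with an implausible area deficit
    # can reclaim it (area is conserved through division)
    assign <- rescue_unmatched(assign, unmatched, cand, mask0, m48)
    unmatched <- setdiff(unmatched, assign$daughter_id)
    extras <- sort(setdiff(unique(cand$daughter_id), assign$daughter_id))
    assign <- assign[order(assign$parent_id, -assign$overlap_px), ]
    rownames(assign) <- NULL
  }
  all48 <- sort(unique(mask48[mask48 > 0]))
  unmatched <- sort(unique(c(unmatched, setdiff(all48, assign$daughter_id))))
  structure(list(assignments = assign, unmatched_t48 = unmatched,
                 extra_daughters = extras,
                 registration_shift = as.integer(shift)),
            class = "fq_lineage")
}

#' @export
print.fq_lineage <- function(x, ...) {
  cat(sprintf("fq_lineage: %d assignments, %d parents, %d unmatched t48 cells\n",
              nrow(x$assignments), length(unique(x$assignments$parent_id)),
              length(x$unmatched_t48)))
  invisible(x)
}

#' Register and match a 0/48-hr mask pair
#'
#' Convenience wrapper: similarity registration (default) or integer
#' translation only, followed by maximal-overlap matching.
#'
#' @param mask0,mask48 integer label matrices of equal size.
#' @param min_overlap_frac minimum overlap fraction for [match_overlap()].
#' @param scale_registration register scale + translation (TRUE) or
#'   translation only (FALSE).
#' @return An `fq_lineage` with `registration_scale` set.
#' @export
track_pair <- function(mask0, mask48, min_overlap_frac = 0.2,
                       scale_registration = TRUE) {
  if (scale_registration) {
    reg <- register_similarity(mask0, mask48)
    lin <- match_overlap(mask0, reg$warped, min_overlap_frac, c(0L, 0L))
    lin$registration_shift <- reg$shift
    lin$registration_scale <- reg$scale
  } else {
    shift <- register_frames(mask0, mask48)
    lin <- match_overlap(mask0, mask48, min_overlap_frac, shift)
    lin$registration_scale <- 1
  }
  lin
}

#' Call divisions from a lineage map
#'
#' A 0-hr cell divided if and only if it retained exactly two daughters.
#'
#' @param lineage an `fq_lineage` (or data.frame with parent_id,
#'   daughter_id).
#' @param parent_ids optional ids to report on (parents absent from the
#'   lineage are returned as NA, flagged lost).
#' @return Named logical vector over parent ids.
#' @export
classify_divided <- function(lineage, parent_ids = NULL) {
  asg <- if (inherits(lineage, "fq_lineage")) lineage$assignments else lineage
  nd <- table(asg$parent_id)
  present <- as.integer(names(nd))
  if (is.null(parent_ids)) parent_ids <- present
  out <- stats::setNames(rep(NA, length(parent_ids)), parent_ids)
  hit <- parent_ids %in% present
  out[hit] <- as.integer(nd[as.character(parent_ids[hit])]) == 2L
  out
}

#' Red/green division overlay
#'
#' Paints the 0-hr mask with divided cells in red (255, 0, 0), non-divided
#' cells in green (0, 200, 0) and background black; cells without a flag are
#' grey and a warning is emitted.
#'
#' @param mask0 integer label matrix at 0 hr.
#' @param divided named logical vector from [classify_divided()].
#' @return H x W x 3 array in 0-1.
#' @export
division_overlay <- function(mask0, divided) {
  ids <- sort(unique(mask0[mask0 > 0]))
  known <- as.integer(names(divided))
  missing <- setdiff(ids, known[!is.na(divided)])
  if (length(missing)) {
    warning("cells without division flag rendered grey: ",
            paste(missing, collapse = ", "))
  }
  H <- nrow(mask0); W <- ncol(mask0)
  r <- matrix(0, H, W); g <- matrix(0, H, W); b <- matrix(0, H, W)
  for (id in ids) {
    px <- mask0 == id
    if (id %in% missing) {
      r[px] <- 0.5; g[px] <- 0.5; b[px] <- 0.5
    } else if (isTRUE(divided[[as.character(id)]])) {
      r[px] <- 1
    } else {
      g[px] <- 200 / 255
    }
  }
  array(c(r, g, b), dim = c(H, W, 3))
}
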