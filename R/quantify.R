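# Centre-of-meristem quantification: group definition and propagation,
# percentage of cells divided, relative total cell area, per-cell relative
# growth, colour-coded value maps and the Student two-tailed t-test.

#' Define the centre-of-meristem group at 0 hr
#'
#' The centre group is the wedge-shaped AC, its packet progenies and all
#' cells within `ring` adjacency steps of the packet; every other
#' non-trichome cell is outside. Trichomes belong to neither group.
#'
#' @param all_ids integer ids of all 0-hr cells.
#' @param ac_id id of the AC.
#' @param adjacency adjacency data.frame (`id1`, `id2`), e.g. from
#'   [polygon_adjacency()] or [label_adjacency()].
#' @param ring adjacency rings around the packet (default 1).
#' @param packet_ids ids of the apical packet (default: just `ac_id`).
#' @param trichome_ids ids excluded as trichomes.
#' @param sample_id optional sample identifier.
#' @return An `fq_group`: list with `centre_ids_t0`, `outside_ids_t0`,
#'   `excluded_ids`, later filled `centre_ids_t48`, `outside_ids_t48`.
#' @export
define_centre_group <- function(all_ids, ac_id, adjacency, ring = 1L,
                                packet_ids = NULL, trichome_ids = integer(0),
                                sample_id = NA) {
  if (!ac_id %in% all_ids) stop("ac_id ", ac_id, " is not a known cell id")
  if (is.null(packet_ids)) packet_ids <- ac_id
  if (!all(packet_ids %in% all_ids)) stop("packet ids outside the cell set")
  centre <- adjacency_ring(adjacency, unique(c(ac_id, packet_ids)), ring)
  centre <- setdiff(centre, trichome_ids)
  outside <- setdiff(all_ids, c(centre, trichome_ids))
  structure(list(sample_id = sample_id,
                 centre_ids_t0 = sort(centre),
                 outside_ids_t0 = sort(outside),
                 excluded_ids = sort(trichome_ids),
                 centre_ids_t48 = NULL, outside_ids_t48 = NULL),
            class = "fq_group")
}

#' Propagate a group assignment to 48 hr through the lineage
#'
#' The 48-hr sets are exactly the daughters of the 0-hr sets. Cells with no
#' lineage are dropped with a warning.
#'
#' @param group an `fq_group`.
#' @param lineage an `fq_lineage` (or assignments data.frame).
#' @return The group with `centre_ids_t48` / `outside_ids_t48` filled.
#' @export
propagate_group <- function(group, lineage) {
  asg <- if (inherits(lineage, "fq_lineage")) lineage$assignments else lineage
  daughters_of <- function(ids) {
    miss <- setdiff(ids, asg$parent_id)
    if (length(miss)) {
      warning("no lineage for cell(s) ", paste(miss, collapse = ", "),
              "; dropped from the propagated group")
    }
    sort(asg$daughter_id[asg$parent_id %in% ids])
  }
  group$centre_ids_t48 <- daughters_of(group$centre_ids_t0)
  group$outside_ids_t48 <- daughters_of(group$outside_ids_t0)
  group
}

#' Percentage of cells that divided over 48 hr
#'
#' Number of group cells that divided divided by the number of group cells
#' at 0 hr, times 100.
#'
#' @param ids group cell ids at 0 hr.
#' @param divided named logical vector from [classify_divided()].
#' @return Percentage on the 0-100 scale; NA (with a warning) for an empty
#'   group.
#' @export
pct_divided <- function(ids, divided) {
  if (length(ids) == 0) {
    warning("empty group: percentage divided is undefined")
    return(NA_real_)
  }
  flags <- divided[as.character(ids)]
  if (anyNA(flags)) {
    warning("cells without division flag excluded from the percentage")
    ids <- ids[!is.na(flags)]
    flags <- flags[!is.na(flags)]
    if (length(ids) == 0) return(NA_real_)
  }
  sum(flags) / length(ids) * 100
}

#' Relative total cell area (48/0 hr) of a group
#'
#' Total area of the group's cells (daughters included) at 48 hr over the
#' total area of the group at 0 hr, times 100.
#'
#' @param group a propagated `fq_group`.
#' @param meas0,meas48 measurement tables (cell_id, area_um2) at 0 / 48 hr.
#' @param side `"centre"` or `"outside"`.
#' @return Percentage (100 = no net growth).
#' @export
relative_total_area <- function(group, meas0, meas48, side = c("centre", "outside")) {
  side <- match.arg(side)
  ids0 <- group[[paste0(side, "_ids_t0")]]
  ids48 <- group[[paste0(side, "_ids_t48")]]
  if (is.null(ids48)) stop("group has not been propagated to 48 hr")
  a0 <- sum(meas0$area_um2[meas0$cell_id %in% ids0])
  if (a0 <= 0) stop("zero total area at 0 hr: relative area undefined")
  a48 <- sum(meas48$area_um2[meas48$cell_id %in% ids48])
  a48 / a0 * 100
}

#' Per-cell relative growth
#'
#' (area at 48 hr, daughters summed, minus area at 0 hr) / area at 0 hr.
#'
#' @param cell_ids 0-hr cell ids.
#' @param lineage an `fq_lineage` (or assignments data.frame).
#' @param meas0,meas48 measurement tables (cell_id, area_um2).
#' @return Named numeric vector; NA (flagged by a warning) where the cell
#'   has no lineage.
#' @export
relative_cell_growth <- function(cell_ids, lineage, meas0, meas48) {
  asg <- if (inherits(lineage, "fq_lineage")) lineage$assignments else lineage
  a0 <- stats::setNames(meas0$area_um2, meas0$cell_id)
  a48 <- stats::setNames(meas48$area_um2, meas48$cell_id)
  out <- stats::setNames(rep(NA_real_, length(cell_ids)), cell_ids)
  miss <- character(0)
  for (id in cell_ids) {
    ds <- asg$daughter_id[asg$parent_id == id]
    if (length(ds) == 0) { miss <- c(miss, id); next }
    out[as.character(id)] <-
      (sum(a48[as.character(ds)]) - a0[[as.character(id)]]) / a0[[as.character(id)]]
  }
  if (length(miss)) {
    warning("no lineage for cell(s) ", paste(miss, collapse = ", "),
            ": relative growth unset")
  }
  out
}

#' Student's two-tailed t-test
#'
#' Pooled-variance Student t with n_x + n_y - 2 degrees of freedom
#' (`welch = TRUE` switches to the Welch approximation).
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param welch use Welch's unequal-variance form instead.
#' @return List with `t`, `p`, `df`.
#' @export
student_t_two_tailed <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 values")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, p = 1, df = length(x) + length(y) - 2))
    }
    warning("zero variance with unequal means: t is infinite")
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0,
                df = length(x) + length(y) - 2))
  }
  tt <- t.test(x, y, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Blue-to-red palette lookup
#'
#' Linear interpolation from pure blue at 0 to pure red at 1 (channels
#' rounded to 8 bit): r = round(255 t)/255, g = 0, b = round(255 (1-t))/255.
#'
#' @param t values in 0-1 (clipped).
#' @return matrix with columns r, g, b in 0-1.
#' @export
value_palette <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  cbind(r = round(255 * t) / 255, g = 0, b = round(255 * (1 - t)) / 255)
}

#' Render a colour-coded per-cell value map
#'
#' Linear blue (vmin) to red (>= vmax) fill per cell, as used for the cell
#' size maps (scale maxima 700-3200 um^2 depending on figure) and the
#' relative growth maps (blue 0 to red >= 1). Cells without a value are
#' grey and flagged with a warning.
#'
#' @param mask integer label matrix.
#' @param values named numeric vector of per-cell values.
#' @param vmin,vmax colour scale bounds (vmin < vmax).
#' @return H x W x 3 array in 0-1.
#' @export
render_value_map <- function(mask, values, vmin, vmax) {
  if (vmin >= vmax) stop("invalid-parameter: vmin must be < vmax")
  ids <- sort(unique(mask[mask > 0]))
  have <- as.integer(names(values))[!is.na(values)]
  missing <- setdiff(ids, have)
  if (length(missing)) {
    warning("cells without value rendered grey: ",
            paste(missing, collapse = ", "))
  }
  H <- nrow(mask); W <- ncol(mask)
  r <- matrix(0, H, W); g <- matrix(0, H, W); b <- matrix(0, H, W)
  for (id in ids) {
    px <- mask == id
    if (id %in% missing) {
      r[px] <- 0.5; g[px] <- 0.5; b[px] <- 0.5
    } else {
      tt <- (values[[as.character(id)]] - vmin) / (vmax - vmin)
      col <- value_palette(tt)
      r[px] <- col[1, "r"]; g[px] <- col[1, "g"]; b[px] <- col[1, "b"]
    }
  }
  array(c(r, g, b), dim = c(H, W, 3))
}

#' Per-sample centre-vs-outside statistics
#'
#' @param group a propagated `fq_group`.
#' @param meas0,meas48 measurement tables.
#' @param divided named logical division flags for the 0-hr cells.
#' @return One-row data.frame with mean areas, percentage divided, and
#'   relative total areas for both groups.
#' @export
group_stats <- function(group, meas0, meas48, divided) {
  a0 <- stats::setNames(meas0$area_um2, meas0$cell_id)
  a48 <- stats::setNames(meas48$area_um2, meas48$cell_id)
  data.frame(
    sample_id = group$sample_id,
    n_centre = length(group$centre_ids_t0),
    n_outside = length(group$outside_ids_t0),
    mean_area_centre_0 = mean(a0[as.character(group$centre_ids_t0)]),
    mean_area_outside_0 = mean(a0[as.character(group$outside_ids_t0)]),
    mean_area_centre_48 = mean(a48[as.character(group$centre_ids_t48)]),
    mean_area_outside_48 = mean(a48[as.character(group$outside_ids_t48)]),
    pct_div_centre = pct_divided(group$centre_ids_t0, divided),
    pct_div_outside = pct_divided(group$outside_ids_t0, divided),
    rel_area_centre = relative_total_area(group, meas0, meas48, "centre"),
    rel_area_outside = relative_total_area(group, meas0, meas48, "outside"),
    stringsAsFactors = FALSE)
}

#' Across-sample summary with Student t-tests
#'
#' Aggregates per-sample group statistics (one summary value per
#' gametophyte) and compares centre vs outside by the pooled two-tailed
#' t-test, as in the across-sample panels of the study design.
#'
#' @param samples data.frame of [group_stats()] rows (one per sample).
#' @return List with `summary` (mean, SE, n per statistic) and `tests`
#'   (t, p for percentage divided and relative area).
#' @export
summarize_samples <- function(samples) {
  se <- function(v) sd(v) / sqrt(length(v))
  stats_cols <- c("mean_area_centre_0", "mean_area_outside_0",
                  "pct_div_centre", "pct_div_outside",
                  "rel_area_centre", "rel_area_outside")
  summary <- data.frame(
    statistic = stats_cols,
    mean = vapply(stats_cols, function(cn) mean(samples[[cn]]), numeric(1)),
    se = vapply(stats_cols, function(cn) se(samples[[cn]]), numeric(1)),
    n = nrow(samples), row.names = NULL, stringsAsFactors = FALSE)
  tests <- list(
    pct_divided = student_t_two_tailed(samples$pct_div_centre,
                                       samples$pct_div_outside),
    rel_area = student_t_two_tailed(samples$rel_area_centre,
                                    samples$rel_area_outside),
    mean_area_0 = student_t_two_tailed(samples$mean_area_centre_0,
                                       samples$mean_area_outside_0))
  list(summary = summary, tests = tests,
       low_power = nrow(samples) < 4)
}
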