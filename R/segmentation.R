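# Marker-based watershed segmentation of membrane-stain images. Cell
# interiors are dark basins between bright wall ridges: markers are the
# regional minima that survive h-minima suppression, and basins are flooded
# from the markers with EBImage::propagate restricted to the tissue
# foreground. Defaults: sigma = 1 px smoothing, h = 10% of the dynamic
# range, minimum region 25 px.

#' Gaussian pre-smoothing
#'
#' @param image 2D intensity matrix.
#' @param sigma Gaussian sigma in pixels; 0 returns the input unchanged.
#' @return Smoothed matrix of the same size.
#' @export
preprocess_smooth <- function(image, sigma = 2) {
  if (length(dim(image)) != 2) stop("shape error: image must be 2D")
  if (sigma < 0) stop("invalid-parameter: sigma must be >= 0")
  if (sigma == 0) return(image)
  as.matrix(EBImage::gblur(image, sigma = sigma))
}

#' Tissue foreground mask
#'
#' Otsu threshold followed by hole filling: the bright wall network (or the
#' whole tissue, depending on where the threshold falls) encloses the cell
#' interiors, so filling holes recovers the full tissue footprint.
#'
#' @param image smoothed intensity matrix in 0-1.
#' @return Logical matrix (TRUE = tissue).
#' @export
foreground_mask <- function(image) {
  rng <- range(image)
  if (diff(rng) < 1e-6) {
    warning("degenerate image: no foreground found")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  th <- EBImage::otsu(EBImage::Image(image), range = rng)
  mask <- EBImage::fillHull(EBImage::Image(image > th)) > 0
  matrix(as.logical(mask), nrow(image), ncol(image))
}

#' Extract watershed markers by h-minima suppression
#'
#' Suppresses intensity minima shallower than `h` (grayscale reconstruction
#' by erosion of image + h over the image) and labels the regional minima
#' that survive: one marker per basin deeper than `h`.
#'
#' @param image smoothed intensity matrix.
#' @param h minimum basin depth on the intensity scale (> 0).
#' @param mask optional logical foreground mask (default
#'   [foreground_mask()]).
#' @return Integer matrix of disjoint marker labels (0 elsewhere).
#' @export
extract_markers <- function(image, h, mask = NULL) {
  if (h <= 0) stop("invalid-parameter: h must be > 0")
  if (is.null(mask)) mask <- foreground_mask(image)
  empty <- matrix(0L, nrow(image), ncol(image))
  if (!any(mask)) {
    warning("no markers: empty foreground")
    return(empty)
  }
  rng <- range(image[mask])
  if (h >= diff(rng)) {
    warning("no markers: h exceeds the image dynamic range")
    return(empty)
  }
  f <- image
  f[!mask] <- rng[2]  # background treated as a ridge
  # quantize so that plateaus filled to their pour level merge exactly and
  # the regional-minima test is robust to floating-point slopes
  q <- h / 10
  f <- round(f / q) * q
  hmin <- cpp_reconstruct_erosion(f + h, f)
  rec2 <- cpp_reconstruct_erosion(hmin + q, hmin)
  core <- EBImage::erode(mask * 1, EBImage::makeBrush(3, "box")) > 0
  minima <- (rec2 - hmin) > q / 2 & core
  lab <- matrix(as.integer(EBImage::bwlabel(minima * 1)),
                nrow(image), ncol(image))
  if (max(lab) > 0) {
    # a genuine basin floor is dim (a cell interior); bright shallow minima
    # are partial-volume artefacts along the mask border
    floor_lvl <- vapply(split(f[lab > 0], lab[lab > 0]), min, numeric(1))
    cap <- rng[1] + 0.4 * diff(rng)
    bad <- as.integer(names(floor_lvl))[floor_lvl > cap]
    counts <- tabulate(lab[lab > 0])
    bad <- union(bad, which(counts < 3))
    if (length(bad)) {
      lab[lab %in% bad] <- 0L
      keep <- sort(unique(lab[lab > 0]))
      remap <- match(lab, keep)
      lab <- matrix(ifelse(is.na(remap), 0L, remap), nrow(lab), ncol(lab))
    }
  }
  if (max(lab) == 0) warning("no markers survived h-minima suppression")
  lab
}

#' Marker-based watershed segmentation
#'
#' Floods the intensity landscape from the markers so that every foreground
#' pixel is assigned to exactly one marker (seeded region growing on the
#' intensity image); watershed-line pixels are absorbed into the adjacent
#' regions so the labels tile the foreground. Regions smaller than
#' `min_region` pixels are merged into their largest neighbour.
#'
#' @param image smoothed intensity matrix.
#' @param markers integer marker matrix from [extract_markers()].
#' @param pixel_size microns per pixel.
#' @param mask optional logical foreground mask.
#' @param min_region minimum region size in pixels.
#' @return An `fq_labelmap`: list with `labels`, `pixel_size`,
#'   `label_areas` (pixel counts named by label).
#' @export
watershed_segment <- function(image, markers, pixel_size = 1, mask = NULL,
                              min_region = 25) {
  if (max(markers) == 0) stop("segmentation error: empty markers")
  if (is.null(mask)) mask <- foreground_mask(image)
  lab <- EBImage::propagate(EBImage::Image(image),
                            seeds = EBImage::Image(markers),
                            mask = EBImage::Image(mask * 1) > 0,
                            lambda = 1e-4)
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  lab <- merge_small_regions(lab, min_region)
  segmentation_labelmap(lab, pixel_size)
}

#' Construct a segmentation label map
#'
#' @param labels integer label matrix (0 = background).
#' @param pixel_size microns per pixel.
#' @return An `fq_labelmap` object.
#' @export
segmentation_labelmap <- function(labels, pixel_size) {
  stopifnot(pixel_size > 0)
  counts <- tabulate(labels[labels > 0])
  present <- which(counts > 0)
  structure(list(labels = labels, pixel_size = pixel_size,
                 label_areas = stats::setNames(counts[present], present)),
            class = "fq_labelmap")
}

# merge labelled regions smaller than min_px into their largest neighbour
merge_small_regions <- function(labels, min_px) {
  repeat {
    counts <- tabulate(labels[labels > 0])
    small <- which(counts > 0 & counts < min_px)
    if (length(small) == 0) break
    adj <- label_adjacency(labels, min_contact = 1L)
    changed <- FALSE
    for (s in small) {
      nb <- c(adj$id2[adj$id1 == s], adj$id1[adj$id2 == s])
      nb <- nb[nb != s]
      if (length(nb) == 0) next
      target <- nb[which.max(counts[nb])]
      labels[labels == s] <- target
      changed <- TRUE
    }
    if (!changed) break
  }
  labels
}

#' Adjacency between labelled regions of a label image
#'
#' Two labels are adjacent when at least `min_contact` 4-neighbour pixel
#' pairs straddle their common boundary.
#'
#' @param labels integer label matrix.
#' @param min_contact minimum number of touching pixel pairs.
#' @return data.frame with columns `id1`, `id2`, `contacts` (id1 < id2).
#' @export
label_adjacency <- function(labels, min_contact = 2L) {
  H <- nrow(labels); W <- ncol(labels)
  a <- c(labels[-H, ], labels[, -W])
  b <- c(labels[-1, ], labels[, -1])
  sel <- a != b & a > 0 & b > 0
  if (!any(sel)) {
    return(data.frame(id1 = integer(), id2 = integer(), contacts = integer()))
  }
  p1 <- pmin(a[sel], b[sel]); p2 <- pmax(a[sel], b[sel])
  tab <- table(paste(p1, p2))
  keep <- tab >= min_contact
  if (!any(keep)) {
    return(data.frame(id1 = integer(), id2 = integer(), contacts = integer()))
  }
  parts <- do.call(rbind, strsplit(names(tab)[keep], " "))
  data.frame(id1 = as.integer(parts[, 1]), id2 = as.integer(parts[, 2]),
             contacts = as.integer(tab[keep]))
}

#' Measure segmented cells
#'
#' One record per label: area in square microns (pixel count times
#' pixel_size^2) and centroid in image coordinates (microns; x along
#' columns, y up from the bottom of the frame).
#'
#' @param labelmap an `fq_labelmap`.
#' @param trichome_ids optional integer ids flagged as trichomes.
#' @return data.frame (cell_id, area_um2, centroid_x, centroid_y,
#'   is_trichome).
#' @export
measure_cells <- function(labelmap, trichome_ids = NULL) {
  labels <- labelmap$labels
  px <- labelmap$pixel_size
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) {
    warning("no labels to measure")
    return(data.frame(cell_id = integer(), area_um2 = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      is_trichome = logical()))
  }
  H <- nrow(labels); W <- ncol(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  x <- (cols - 0.5) * px
  y <- (H - rows + 0.5) * px
  npix <- as.vector(tapply(rep(1, length(lab)), lab, sum))
  cx <- as.vector(tapply(x, lab, mean))
  cy <- as.vector(tapply(y, lab, mean))
  out <- data.frame(cell_id = as.integer(names(tapply(x, lab, mean))),
                    area_um2 = npix * px^2,
                    centroid_x = cx, centroid_y = cy)
  out$is_trichome <- out$cell_id %in% trichome_ids
  out[order(out$cell_id), , drop = FALSE]
}

#' Per-cell intersection-over-union against a reference partition
#'
#' Each reference label is matched to the test label with maximal pixel
#' overlap; IoU is computed for that match.
#'
#' @param test integer label matrix to evaluate.
#' @param reference ground-truth integer label matrix.
#' @return data.frame (reference_id, matched_id, iou).
#' @export
label_iou <- function(test, reference) {
  stopifnot(all(dim(test) == dim(reference)))
  sel <- reference > 0
  tab <- table(ref = reference[sel], test = test[sel])
  ref_ids <- as.integer(rownames(tab))
  test_sizes <- tabulate(test[test > 0])
  ref_sizes <- tabulate(reference[reference > 0])
  best <- apply(tab, 1, which.max)
  matched <- as.integer(colnames(tab))[best]
  inter <- tab[cbind(seq_along(ref_ids), best)]
  t_sz <- ifelse(matched > 0 & matched <= length(test_sizes),
                 test_sizes[pmax(matched, 1)], 0)
  union <- ref_sizes[ref_ids] + t_sz - inter
  data.frame(reference_id = ref_ids, matched_id = matched,
             iou = as.numeric(inter / union))
}

#' Segment one membrane-stain image end to end
#'
#' Convenience wrapper: smooth, mask, extract h-minima markers, flood.
#'
#' @param image raw intensity matrix in 0-1.
#' @param pixel_size microns per pixel.
#' @param sigma smoothing sigma (px).
#' @param h_frac h as a fraction of the image dynamic range.
#' @param min_region minimum region size (px).
#' @return An `fq_labelmap`.
#' @export
segment_image <- function(image, pixel_size, sigma = 1, h_frac = 0.10,
                          min_region = 25) {
  sm <- preprocess_smooth(image, sigma)
  mask <- foreground_mask(sm)
  if (!any(mask)) stop("segmentation error: empty foreground")
  h <- h_frac * diff(range(sm[mask]))
  markers <- extract_markers(sm, h, mask)
  watershed_segment(sm, markers, pixel_size, mask, min_region)
}
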