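# Rendering: turn tissues into membrane-stain-like grayscale images (bright
# cell-wall ridges, dim interiors) plus ground-truth label masks. Both
# timepoints share one field of view and coordinate origin so that overlap
# tracking works exactly as on registered micrographs.

default_noise <- function() {
  list(gaussian_sd = 0.02, poisson_scale = 0)
}

render_field <- function(t0, t48, pixel_size, margin = 8) {
  bb0 <- poly_bbox(t0$domain)
  bb1 <- poly_bbox(t48$domain)
  ox <- min(bb0["xmin"], bb1["xmin"]) - margin
  oy <- min(bb0["ymin"], bb1["ymin"]) - margin
  xmax <- max(bb0["xmax"], bb1["xmax"]) + margin
  ymax <- max(bb0["ymax"], bb1["ymax"]) + margin
  W <- as.integer(ceiling((xmax - ox) / pixel_size))
  H <- as.integer(ceiling((ymax - oy) / pixel_size))
  list(ox = unname(ox), oy = unname(oy), W = W, H = H)
}

rasterize_tissue <- function(tissue, field, pixel_size) {
  ids <- tissue$cells$cell_id
  cpp_rasterize(tissue$polygons[as.character(ids)], as.integer(ids),
                field$W, field$H, pixel_size, field$ox, field$oy)
}

# wall mask: pixels whose 4-neighbourhood crosses a label boundary (including
# the tissue/background rim), thickened to the requested width
wall_mask <- function(labels, width_px = 2) {
  H <- nrow(labels); W <- ncol(labels)
  wm <- matrix(FALSE, H, W)
  d <- labels[-H, ] != labels[-1, ]
  wm[-H, ][d] <- TRUE; wm[-1, ][d] <- TRUE
  d <- labels[, -W] != labels[, -1]
  wm[, -W][d] <- TRUE; wm[, -1][d] <- TRUE
  wm[labels == 0] <- FALSE
  if (width_px > 1) {
    brush <- EBImage::makeBrush(2L * (width_px %/% 2L) + 1L, shape = "disc")
    wm <- EBImage::dilate(wm * 1, brush) > 0
    wm[labels == 0] <- FALSE
  }
  wm
}

#' Render a two-timepoint synthetic membrane-stain image pair
#'
#' Produces, per timepoint, a grayscale intensity image in which cell
#' boundaries are bright ridges and interiors are dim, together with a
#' ground-truth label mask (pixel value = cell id, 0 = background). Both
#' frames share one field of view.
#'
#' @param t0,t48 tissues from [simulate_gametophyte()].
#' @param params `fq_params` (supplies `pixel_size`).
#' @param noise list with `gaussian_sd` (additive Gaussian noise sd on the
#'   0-1 intensity scale) and `poisson_scale` (photons per intensity unit;
#'   0 disables shot noise).
#' @param wall_width_px wall ridge width in pixels.
#' @param levels intensity levels: background, cell interior, wall ridge.
#' @param fov optional fixed field of view `c(width_um, height_um)`; errors
#'   if the tissues do not fit.
#' @return List of class `fq_render` with `image0`, `image48` (matrices in
#'   0-1), `labels0`, `labels48` (integer matrices), `pixel_size`, `origin`.
#' @export
render_image_pair <- function(t0, t48, params, noise = default_noise(),
                              wall_width_px = 2,
                              levels = c(bg = 0.03, interior = 0.30, wall = 0.95),
                              fov = NULL) {
  px <- params$pixel_size
  field <- render_field(t0, t48, px)
  if (!is.null(fov)) {
    if (field$W * px > fov[1] || field$H * px > fov[2]) {
      stop("render error: field of view too small for the tissue pair")
    }
    field$W <- as.integer(ceiling(fov[1] / px))
    field$H <- as.integer(ceiling(fov[2] / px))
  }
  one <- function(tissue) {
    lab <- rasterize_tissue(tissue, field, px)
    wm <- wall_mask(lab, wall_width_px)
    img <- matrix(levels[["bg"]], field$H, field$W)
    img[lab > 0] <- levels[["interior"]]
    img[wm] <- levels[["wall"]]
    img <- as.matrix(EBImage::gblur(img, sigma = 0.6))
    if (noise$poisson_scale > 0) {
      img <- matrix(rpois(length(img), pmax(img, 0) * noise$poisson_scale) /
                      noise$poisson_scale, nrow(img), ncol(img))
    }
    if (noise$gaussian_sd > 0) {
      img <- img + rnorm(length(img), 0, noise$gaussian_sd)
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    list(image = img, labels = lab)
  }
  r0 <- one(t0)
  r48 <- one(t48)
  structure(list(image0 = r0$image, image48 = r48$image,
                 labels0 = r0$labels, labels48 = r48$labels,
                 pixel_size = px, origin = c(field$ox, field$oy)),
            class = "fq_render")
}

# --- TIFF helpers -----------------------------------------------------------

#' Write a grayscale intensity image as 16-bit TIFF
#' @param image matrix with values in 0-1.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intensity_tiff <- function(image, path) {
  tiff::writeTIFF(image, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a grayscale TIFF as a 0-1 matrix
#' @param path TIFF path.
#' @return Numeric matrix.
#' @export
read_intensity_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Write an integer label mask as 16-bit TIFF (0 = background)
#' @param labels integer matrix of labels (< 65535).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) >= 65535) stop("label ids exceed 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a 16-bit label TIFF back to integer labels
#' @param path TIFF path written by [write_label_tiff()].
#' @return Integer matrix.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

# per-tissue ground-truth table (cell_id, class, region, area, centroid)
tissue_truth_table <- function(tissue) {
  ctr <- tissue_centroids(tissue)
  data.frame(cell_id = tissue$cells$cell_id,
             cell_class = tissue$cells$cell_class,
             region = tissue$cells$region,
             area_um2 = unname(tissue_areas(tissue)),
             centroid_x = ctr[, 1], centroid_y = ctr[, 2],
             stringsAsFactors = FALSE)
}

#' Write all simulator outputs for one gametophyte pair
#'
#' Writes `t0.tif`/`t48.tif` (16-bit grayscale), `t0_labels.tif`/
#' `t48_labels.tif` (16-bit label masks), `lineage_truth.csv`,
#' `tissue_t0.csv`/`tissue_t48.csv` and `params.yaml` under `dir`.
#'
#' @param sim result of [simulate_gametophyte()].
#' @param render result of [render_image_pair()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation_outputs <- function(sim, render, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_intensity_tiff(render$image0, file.path(dir, "t0.tif"))
  write_intensity_tiff(render$image48, file.path(dir, "t48.tif"))
  write_label_tiff(render$labels0, file.path(dir, "t0_labels.tif"))
  write_label_tiff(render$labels48, file.path(dir, "t48_labels.tif"))
  write.csv(sim$lineage, file.path(dir, "lineage_truth.csv"), row.names = FALSE)
  write.csv(tissue_truth_table(sim$t0), file.path(dir, "tissue_t0.csv"),
            row.names = FALSE)
  write.csv(tissue_truth_table(sim$t48), file.path(dir, "tissue_t48.csv"),
            row.names = FALSE)
  write_params(sim$params, file.path(dir, "params.yaml"))
  invisible(dir)
}
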