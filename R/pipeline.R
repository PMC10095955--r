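# End-to-end orchestration: configuration handling, the
# simulate -> segment -> track -> quantify pipeline, and the
# parameter-recovery experiment.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    simulate = list(enabled = TRUE, use_truth_masks = FALSE, n_steps = 1L,
                    params = unclass(simulation_params())),
    inputs = list(image0 = NULL, image48 = NULL, labels0 = NULL,
                  labels48 = NULL, pixel_size = NULL,
                  ac_point = NULL, packet_points = NULL,
                  trichome_ids = NULL),
    noise = default_noise(),
    segmentation = list(sigma = 1, h_frac = 0.10, min_region = 25),
    tracking = list(min_overlap_frac = 0.2, scale_registration = TRUE),
    quantification = list(ring = 1L, size_scale_max = 700,
                          growth_scale_max = 1.0))
}

merge_validate <- function(defaults, values, path = "") {
  unknown <- setdiff(names(values), names(defaults))
  if (length(unknown)) {
    stop("config error: unknown key(s) ",
         paste0(path, unknown, collapse = ", "))
  }
  for (nm in names(values)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_validate(defaults[[nm]],
                                       as.list(values[[nm]]),
                                       paste0(path, nm, "."))
    } else {
      # NULL-safe: assigning NULL via [[<- would delete the key
      defaults[nm] <- list(values[[nm]])
    }
  }
  defaults
}

#' Build (and validate) a pipeline configuration
#'
#' Unknown keys are rejected; omitted keys take their defaults. The
#' configuration round-trips losslessly through YAML.
#'
#' @param values named list of overrides (possibly nested).
#' @param file optional YAML file to read overrides from.
#' @return An `fq_config` list.
#' @export
pipeline_config <- function(values = list(), file = NULL) {
  if (!is.null(file)) values <- yaml::read_yaml(file)
  cfg <- merge_validate(default_pipeline_config(), values)
  do.call(simulation_params, cfg$simulate$params)  # validates
  structure(cfg, class = "fq_config")
}

#' Write a pipeline configuration to YAML
#' @param config `fq_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config), precision = 15), path)
  invisible(path)
}

# nearest nonzero label around a pixel position
label_at_point <- function(labels, point_um, pixel_size, radius = 4L) {
  H <- nrow(labels); W <- ncol(labels)
  col <- round(point_um[1] / pixel_size + 0.5)
  row <- round(H - point_um[2] / pixel_size + 0.5)
  for (r in 0:radius) {
    rows <- max(1, row - r):min(H, row + r)
    cols <- max(1, col - r):min(W, col + r)
    patch <- labels[rows, cols, drop = FALSE]
    nz <- patch[patch > 0]
    if (length(nz)) return(as.integer(names(which.max(table(nz)))))
  }
  NA_integer_
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> segment -> track -> quantify and,
#' when `config$out_dir` is set, writes all stage outputs plus a
#' machine-readable run manifest. Stage failures abort with a
#' stage-tagged error message.
#'
#' @param config an `fq_config` from [pipeline_config()].
#' @return List with the simulation (if any), segmentations, lineage,
#'   division flags, group assignment, per-sample statistics and paths of
#'   written artifacts.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "fq_config")) config <- pipeline_config(config)

  stage1 <- if (isTRUE(config$simulate$enabled)) {
    run_stage("simulate", {
      prm <- do.call(simulation_params, config$simulate$params)
      sim <- simulate_gametophyte(prm, n_steps = config$simulate$n_steps)
      render <- render_image_pair(sim$t0, sim$t48, prm, noise = config$noise)
      tt <- tissue_truth_table(sim$t0)
      org <- render$origin
      acr <- tt[tt$cell_class == "AC_wedge", ]
      pk <- tt[tt$cell_id %in%
               sim$t0$cells$cell_id[sim$t0$cells$packet_member], ]
      list(sim = sim, render = render, px = prm$pixel_size,
           img0 = render$image0, img48 = render$image48,
           ac_pt = c(acr$centroid_x - org[1], acr$centroid_y - org[2]),
           packet_pts = cbind(pk$centroid_x - org[1],
                              pk$centroid_y - org[2]),
           trichome_ids = tt$cell_id[tt$cell_class == "trichome"])
    })
  } else {
    run_stage("load-inputs", {
      ins <- config$inputs
      if (is.null(ins$image0) || is.null(ins$image48)) {
        stop("image0/image48 inputs are required when simulation is disabled")
      }
      if (!file.exists(ins$image0)) stop("missing input file: ", ins$image0)
      if (!file.exists(ins$image48)) stop("missing input file: ", ins$image48)
      if (is.null(ins$pixel_size)) stop("pixel_size input is required")
      list(sim = NULL, render = NULL, px = ins$pixel_size,
           img0 = read_intensity_tiff(ins$image0),
           img48 = read_intensity_tiff(ins$image48),
           ac_pt = if (!is.null(ins$ac_point)) as.numeric(ins$ac_point),
           packet_pts = if (!is.null(ins$packet_points))
             matrix(unlist(ins$packet_points), ncol = 2, byrow = TRUE),
           trichome_ids = if (!is.null(ins$trichome_ids))
             as.integer(ins$trichome_ids) else integer(0))
    })
  }
  sim <- stage1$sim; render <- stage1$render; px <- stage1$px
  img0 <- stage1$img0; img48 <- stage1$img48
  ac_pt <- stage1$ac_pt; packet_pts <- stage1$packet_pts
  trichome_ids <- stage1$trichome_ids

  use_truth <- isTRUE(config$simulate$use_truth_masks) && !is.null(render)
  seg <- run_stage("segment", {
    sg <- config$segmentation
    if (use_truth) {
      list(seg0 = segmentation_labelmap(render$labels0, px),
           seg48 = segmentation_labelmap(render$labels48, px))
    } else {
      list(seg0 = segment_image(img0, px, sg$sigma, sg$h_frac, sg$min_region),
           seg48 = segment_image(img48, px, sg$sigma, sg$h_frac, sg$min_region))
    }
  })

  track <- run_stage("track", {
    lineage <- track_pair(seg$seg0$labels, seg$seg48$labels,
                          config$tracking$min_overlap_frac,
                          config$tracking$scale_registration)
    all0 <- sort(unique(seg$seg0$labels[seg$seg0$labels > 0]))
    divided <- classify_divided(lineage, all0)
    list(lineage = lineage, divided = divided, all0 = all0)
  })

  quant <- run_stage("quantify", {
    q <- config$quantification
    meas0 <- measure_cells(seg$seg0, trichome_ids)
    meas48 <- measure_cells(seg$seg48)
    if (is.null(ac_pt)) stop("an AC annotation point is required")
    acid <- label_at_point(seg$seg0$labels, ac_pt, px)
    if (is.na(acid)) stop("AC annotation does not hit a segmented cell")
    pk_ids <- acid
    if (!is.null(packet_pts)) {
      pk_ids <- unique(stats::na.omit(apply(packet_pts, 1, label_at_point,
                                            labels = seg$seg0$labels,
                                            pixel_size = px)))
    }
    # pixel-contact threshold for the adjacency ring: ~1.5 um of shared
    # boundary (a 1-um edge spans ~2/px pixels, with up to twice as many
    # 4-neighbour contacts on diagonal staircases); erring towards
    # exclusion keeps the centre group's per-cell rates undiluted
    adj <- label_adjacency(seg$seg0$labels,
                           min_contact = max(2L, as.integer(round(3 / px))))
    group <- define_centre_group(track$all0, acid, adj, ring = q$ring,
                                 packet_ids = pk_ids,
                                 trichome_ids = trichome_ids)
    group <- propagate_group(group, track$lineage)
    stats_row <- group_stats(group, meas0, meas48, track$divided)
    growth <- relative_cell_growth(track$all0, track$lineage, meas0, meas48)
    list(meas0 = meas0, meas48 = meas48, group = group,
         stats = stats_row, growth = growth, ac_id = acid)
  })

  out <- list(sim = sim, render = render, seg0 = seg$seg0, seg48 = seg$seg48,
              lineage = track$lineage, divided = track$divided,
              meas0 = quant$meas0, meas48 = quant$meas48,
              group = quant$group, stats = quant$stats,
              growth = quant$growth, config = config)

  if (!is.null(config$out_dir)) {
    run_stage("write-outputs", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_pipeline_outputs(out, config$out_dir)
    })
  }
  out
}

write_pipeline_outputs <- function(out, dir) {
  if (!is.null(out$sim)) write_simulation_outputs(out$sim, out$render, dir)
  write.csv(out$meas0, file.path(dir, "cells_t0.csv"), row.names = FALSE)
  write.csv(out$meas48, file.path(dir, "cells_t48.csv"), row.names = FALSE)
  write.csv(out$lineage$assignments, file.path(dir, "lineage.csv"),
            row.names = FALSE)
  write.csv(data.frame(cell_id = as.integer(names(out$divided)),
                       divided = unname(out$divided)),
            file.path(dir, "divided.csv"), row.names = FALSE)
  write.csv(out$stats, file.path(dir, "group_stats.csv"), row.names = FALSE)
  q <- out$config$quantification
  sizes <- stats::setNames(out$meas0$area_um2, out$meas0$cell_id)
  png::writePNG(render_value_map(out$seg0$labels, sizes, 0, q$size_scale_max),
                file.path(dir, "size_map.png"))
  png::writePNG(division_overlay(out$seg0$labels, out$divided),
                file.path(dir, "division_map.png"))
  suppressWarnings(
    png::writePNG(render_value_map(out$seg0$labels, out$growth, 0,
                                   q$growth_scale_max),
                  file.path(dir, "growth_map.png")))
  manifest <- list(
    package = "fernquant",
    version = as.character(packageVersion("fernquant")),
    r_version = as.character(getRversion()),
    seed = out$config$seed,
    config = unclass(out$config),
    scale_bounds = list(size = c(0, q$size_scale_max),
                        growth = c(0, q$growth_scale_max)),
    files = as.list(tools::md5sum(list.files(dir, full.names = TRUE,
                                             pattern = "\\.(csv|tif|yaml)$"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

# analyze one simulated gametophyte, either through the image pipeline or
# on the simulator's ground truth (the oracle path)
analyze_sample <- function(params, use_segmentation = TRUE,
                           noise = default_noise(),
                           segmentation = list(sigma = 1, h_frac = 0.10,
                                               min_region = 25),
                           min_overlap_frac = 0.2, ring = 1L, n_steps = 1L) {
  if (use_segmentation) {
    cfg <- pipeline_config(list(
      seed = params$seed,
      simulate = list(enabled = TRUE, n_steps = n_steps,
                      params = unclass(params)),
      noise = noise, segmentation = segmentation,
      tracking = list(min_overlap_frac = min_overlap_frac),
      quantification = list(ring = ring)))
    res <- run_pipeline(cfg)
    return(res$stats)
  }
  sim <- simulate_gametophyte(params, n_steps = n_steps)
  meas0 <- tissue_truth_table(sim$t0)
  meas48 <- tissue_truth_table(sim$t48)
  lin <- sim$lineage
  divided <- classify_divided(lin, meas0$cell_id)
  tri <- meas0$cell_id[meas0$cell_class == "trichome"]
  group <- define_centre_group(
    meas0$cell_id, meas0$cell_id[meas0$cell_class == "AC_wedge"],
    sim$t0$adjacency, ring = ring,
    packet_ids = sim$t0$cells$cell_id[sim$t0$cells$packet_member],
    trichome_ids = tri)
  group <- propagate_group(group, lin)
  group_stats(group, meas0, meas48, divided)
}

#' Run the parameter-recovery experiment
#'
#' Simulates `n_samples` gametophyte pairs spanning the study's range of
#' tissue sizes, runs the full pipeline on each (render -> segment ->
#' track -> quantify, or the ground-truth oracle path), and aggregates the
#' four group statistics with across-sample Student t-tests.
#'
#' @param params base `fq_params`; per-sample seeds and sizes are derived
#'   from it.
#' @param n_samples number of gametophytes (default 8).
#' @param seed experiment seed (combined with per-sample indices).
#' @param sizes integer vector of `n_initial_cells` per sample (recycled).
#' @param use_segmentation run the image pipeline (TRUE) or the
#'   ground-truth oracle path (FALSE).
#' @param calibrate_ac give the AC the centre division rate so that the
#'   group-level generating rate equals `p_div_centre` (used when comparing
#'   recovered rates against the generating parameters).
#' @return An `fq_recovery` list: `samples`, `summary`, `tests`,
#'   `generating`, `low_power`.
#' @export
run_recovery_experiment <- function(params = simulation_params(),
                                    n_samples = 8L, seed = 1L,
                                    sizes = c(50L, 52L, 62L, 75L, 85L,
                                              95L, 105L, 120L),
                                    use_segmentation = TRUE,
                                    calibrate_ac = TRUE, n_steps = 2L) {
  sizes <- rep_len(sizes, n_samples)
  rows <- vector("list", n_samples)
  for (k in seq_len(n_samples)) {
    p <- params
    p$n_initial_cells <- sizes[k]
    p$seed <- as.integer((seed * 1009L + k * 7919L) %% .Machine$integer.max)
    if (calibrate_ac) p$p_div_ac <- p$p_div_centre
    rows[[k]] <- analyze_sample(p, use_segmentation = use_segmentation,
                                n_steps = n_steps)
    rows[[k]]$sample_id <- k
  }
  samples <- do.call(rbind, rows)
  agg <- summarize_samples(samples)
  generating <- list(pct_div_centre = params$p_div_centre * 100,
                     pct_div_outside = params$p_div_outside * 100,
                     rel_area_centre = params$growth_centre * 100,
                     rel_area_outside = params$growth_outside * 100)
  structure(list(samples = samples, summary = agg$summary,
                 tests = agg$tests, generating = generating,
                 n_samples = n_samples, low_power = agg$low_power),
            class = "fq_recovery")
}

#' @export
print.fq_recovery <- function(x, ...) {
  cat(sprintf("fq_recovery: %d samples%s\n", x$n_samples,
              if (x$low_power) " (low power)" else ""))
  print(x$summary, digits = 4)
  cat(sprintf("t-tests: %% divided p = %.3g, relative area p = %.3g\n",
              x$tests$pct_divided$p, x$tests$rel_area$p))
  invisible(x)
}

#' Draw one sample's group statistics from the generator's distributional layer
#'
#' Bypasses geometry and imaging: division flags are Bernoulli draws with
#' the region rates and per-cell areas grow by lognormal multipliers, fed
#' through the same quantification functions as the pipeline. Used for
#' statistical calibration (null rejection rate, power) where thousands of
#' replicates are needed.
#'
#' @param params `fq_params`.
#' @param n_centre,n_outside group sizes at 0 hr.
#' @return One-row data.frame as from [group_stats()].
#' @export
simulate_group_stats <- function(params, n_centre = 12L, n_outside = 90L) {
  n <- n_centre + n_outside
  ids <- seq_len(n)
  centre_ids <- seq_len(n_centre)
  outside_ids <- setdiff(ids, centre_ids)
  a0 <- c(rlnorm(n_centre, log(140), 0.35), rlnorm(n_outside, log(420), 0.5))
  p <- c(params$p_div_ac, rep(params$p_div_centre, n_centre - 1L),
         rep(params$p_div_outside, n_outside))
  div <- runif(n) < p
  gmean <- c(rep(params$growth_centre, n_centre),
             rep(params$growth_outside, n_outside))
  g <- lognormal_factors(n, 1, params$growth_cv) * gmean
  a48_tot <- a0 * g
  # build the lineage: undivided keep their id, divided get two fresh ids
  ndiv <- sum(div)
  div_ids <- ids[div]
  d1 <- n + seq_len(ndiv) * 2L - 1L
  d2 <- d1 + 1L
  f <- runif(ndiv, 0.35, 0.65)
  lin <- data.frame(
    parent_id = c(ids[!div], rep(div_ids, each = 2L)),
    daughter_id = c(ids[!div], as.integer(rbind(d1, d2))))
  d_id <- lin$daughter_id
  d_area <- c(a48_tot[!div],
              as.numeric(rbind(a48_tot[div] * f, a48_tot[div] * (1 - f))))
  meas0 <- data.frame(cell_id = ids, area_um2 = a0)
  meas48 <- data.frame(cell_id = d_id, area_um2 = d_area)
  group <- structure(list(sample_id = NA, centre_ids_t0 = centre_ids,
                          outside_ids_t0 = outside_ids,
                          excluded_ids = integer(0),
                          centre_ids_t48 = NULL, outside_ids_t48 = NULL),
                     class = "fq_group")
  group <- propagate_group(group, lin)
  divided <- classify_divided(lin, ids)
  group_stats(group, meas0, meas48, divided)
}
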