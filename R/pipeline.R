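# -- presets, cohorts and the end-to-end pipeline -----------------------------

#' Default pipeline configuration
#'
#' All analysis constants in one declarative list. Defaults: synchronisation
#' threshold 0.01 pp/min; Myosin normalisation percentiles 5 and 98.5 with
#' reference grey 200 and 255 ceiling; vertex exclusion radius 2 px; 30-s
#' time bins smoothed over 3 bins for display; mixed-effects alpha 0.01;
#' 100-um central AP window; rates over +/- 2 frames.
#'
#' @param ... overrides of any default.
#' @return Named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sync_threshold_pp_min = 0.01,
    sync_sustain_min = 2,
    background_percentile = 5,
    reference_percentile = 98.5,
    reference_grey = 200,
    ceiling_grey = 255,
    vertex_exclusion_px = 2,
    bin_min = 0.5,
    smooth_bins = 3L,
    alpha = 0.01,
    central_width_um = 100,
    rate_window_frames = 2L,
    dv_threshold_deg = 45,
    n_embryos = 4L,
    n_cells = 180L,
    n_swaps = 20L,
    mesoderm_half_width_cells = 0L,
    frame_interval_min = 0.5,
    t_start_min = -15,
    t_end_min = 30,
    pixel_size_um = 0.5,
    seed = 1L)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Generate one synthetic embryo movie
#'
#' Presets emulate the two genotypes of the emulated study. "wildtype"
#' combines a ventral (DV) pull active from about -13 to +7 minutes
#' (mesoderm invagination) with a posterior (AP) pull from 0 to 20 minutes
#' (endoderm invagination and axis extension); "twist" lacks the DV pull.
#' Each embryo gets a random onset shift (so synchronisation is exercised)
#' and a random flow-magnitude factor (between-embryo variability).
#' Scripted T1 swaps on DV-oriented interfaces run throughout extension.
#'
#' @param preset "wildtype", "twist", or "custom" (supply `flow`).
#' @param seed integer seed (drives tessellation, scheduling and noise).
#' @param id movie id.
#' @param n_cells,n_swaps scene size.
#' @param times_min frame times; default -15..+30 min in 30-s steps.
#' @param dv_rate,ap_rate peak strain rates of the two pulls (pp/min).
#' @param onset_jitter_min onset shift drawn uniformly in +/- this value.
#' @param magnitude_cv coefficient of variation of the per-embryo flow
#'   magnitude factor.
#' @param track_noise_um tracking jitter SD passed to [simulate_movie()].
#' @param flow optional `flow_spec` for preset "custom".
#' @param swaps optional swap schedule (otherwise scheduled internally).
#' @return An `epi_movie`; `ground_truth$onset_min` records the scripted
#'   GBE onset in raw movie time.
#' @export
synth_embryo <- function(preset = c("wildtype", "twist", "custom"),
                         seed = 1L, id = NULL,
                         n_cells = 180L, n_swaps = 20L,
                         times_min = seq(-15, 30, by = 0.5),
                         dv_rate = 0.02, ap_rate = 0.025,
                         onset_jitter_min = 2, magnitude_cv = 0.1,
                         track_noise_um = 0.1,
                         flow = NULL, swaps = NULL) {
  preset <- match.arg(preset)
  set.seed(seed)
  if (is.null(id)) id <- sprintf("%s_%03d", preset, seed %% 1000L)
  mesh <- generate_tessellation(n_cells, mean_diameter_um = 12, jitter = 0.15)
  onset <- stats::runif(1, -onset_jitter_min, onset_jitter_min)
  mag <- max(stats::rnorm(1, 1, magnitude_cv), 0.5)
  x_ref <- max(mesh$vertices[, 1])
  if (preset == "custom") {
    if (is.null(flow)) flow <- flow_none()
  } else {
    ap <- flow_ap_pull(rate = ap_rate * mag, decay_um = 120, x_ref = x_ref,
                       t_on = onset, t_off = onset + 20, ramp_min = 1)
    flow <- if (preset == "wildtype")
      flow_sum(flow_dv_pull(rate = dv_rate * mag, decay_um = 50,
                            t_on = onset - 13, t_off = onset + 7,
                            ramp_min = 2), ap)
    else ap
  }
  # swap times from +6 min: with the 5-min scripted shrinkage, junctions
  # start shrinking only after the onset of extension, as in polarised
  # intercalation
  if (is.null(swaps) && n_swaps > 0)
    swaps <- schedule_swaps(mesh, n_swaps, t_range = onset + c(6, 20))
  mv <- simulate_movie(mesh, times_min, flow = flow, swaps = swaps,
                       id = id, genotype = preset,
                       track_noise_um = track_noise_um)
  mv$ground_truth$onset_min <- onset
  mv$ground_truth$magnitude <- mag
  mv
}

#' Generate a cohort of synthetic embryos
#'
#' @param preset genotype preset for [synth_embryo()].
#' @param n_embryos cohort size (the emulated study used 4 wild-type
#'   movies).
#' @param seed base seed; embryo k uses seed + k.
#' @param ... forwarded to [synth_embryo()].
#' @return List of `epi_movie`.
#' @export
synth_cohort <- function(preset, n_embryos = 4L, seed = 1L, ...) {
  lapply(seq_len(n_embryos), function(k)
    synth_embryo(preset, seed = seed + k,
                 id = sprintf("%s_%02d", preset, k), ...))
}

# per-movie mean AP tissue strain-rate series over ectodermal cells
movie_ap_series <- function(movie, tissue) {
  keep <- if (is.null(movie$cell_types)) rep(TRUE, nrow(tissue)) else
    tissue$cell_id %in% names(movie$cell_types)[
      movie$cell_types == "ectoderm"]
  d <- tissue[keep & !is.na(tissue$txx), ]
  agg <- stats::aggregate(txx ~ frame + time_min, data = d, FUN = mean)
  tibble::tibble(time_min = agg$time_min, value = agg$txx)
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' Generates a wild-type-like and a twist-like cohort, computes strain
#' rates and their decomposition per movie, detects neighbour exchanges,
#' synchronises each genotype to the onset of extension, bins the requested
#' metrics into 30-s bins of synchronised time and compares genotypes per
#' bin with the mixed-effects test. Deterministic given the config seed.
#'
#' @param config list from [pipeline_config()].
#' @param metrics named list mapping metric names to strain-table columns
#'   (from the decomposition table).
#' @param out_dir optional directory: tables and a provenance manifest are
#'   written as delimited text.
#' @return List with per-movie tables, synchronisation, binned series,
#'   ribbon summaries and per-bin comparisons for each metric.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         metrics = list(dv_cell_shape = "cyy",
                                        ap_cell_shape = "cxx",
                                        dv_tissue = "tyy",
                                        ap_intercalation = "ixx"),
                         out_dir = NULL) {
  times <- seq(config$t_start_min, config$t_end_min,
               by = config$frame_interval_min)
  cohorts <- list(
    wildtype = synth_cohort("wildtype", config$n_embryos, config$seed,
                            n_cells = config$n_cells,
                            n_swaps = config$n_swaps, times_min = times),
    twist = synth_cohort("twist", config$n_embryos, config$seed + 1000L,
                         n_cells = config$n_cells,
                         n_swaps = config$n_swaps, times_min = times))
  axes <- axes_frame(0)

  per_movie <- list(); series <- list(); events_all <- list()
  log_lines <- character(0)
  for (gt in names(cohorts)) for (mv in cohorts[[gt]]) {
    mv <- classify_cells(mv, axes, config$mesoderm_half_width_cells)
    tis <- tissue_strain_rates(mv, config$rate_window_frames)
    shp <- cell_shape_strain_rates(mv, config$rate_window_frames)
    dec <- strain_decomposition(tis, shp)
    dec$movie <- mv$id; dec$genotype <- gt
    dec$type <- mv$cell_types[dec$cell_id]
    per_movie[[mv$id]] <- dec
    s <- movie_ap_series(mv, tis)
    s$movie <- mv$id; s$genotype <- gt
    series[[mv$id]] <- s
    ev <- detect_t1(mv)
    if (nrow(ev)) { ev$movie <- mv$id; ev$genotype <- gt }
    events_all[[mv$id]] <- ev
    log_lines <- c(log_lines, sprintf(
      "%s: %d cells tracked, %d T1 events",
      mv$id, length(mv$cell_types), nrow(ev)))
  }

  sync <- synchronise(dplyr::bind_rows(series),
                      threshold = config$sync_threshold_pp_min,
                      sustain_min = config$sync_sustain_min,
                      grid_step_min = config$bin_min)

  dec_all <- dplyr::bind_rows(per_movie)
  dec_all <- dec_all[dec_all$type == "ectoderm", ]
  off <- stats::setNames(sync$offset_min, sync$movie)
  dec_all$sync_time_min <- dec_all$time_min - off[dec_all$movie]
  edges <- seq(floor(min(dec_all$sync_time_min, na.rm = TRUE)),
               ceiling(max(dec_all$sync_time_min, na.rm = TRUE)),
               by = config$bin_min)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  dec_all$bin <- mids[pmin(pmax(
    findInterval(dec_all$sync_time_min, edges, rightmost.closed = TRUE),
    1L), length(mids))]

  results <- list()
  for (mname in names(metrics)) {
    col <- metrics[[mname]]
    d <- tibble::tibble(bin = dec_all$bin, embryo = dec_all$movie,
                        genotype = dec_all$genotype,
                        value = dec_all[[col]])
    cmp <- genotype_compare(d, alpha = config$alpha)
    ribbons <- lapply(split(d, d$genotype), ribbon_summary,
                      smooth_bins = config$smooth_bins)
    results[[mname]] <- list(binned = d, comparison = cmp, ribbons = ribbons)
  }

  out <- list(config = config, sync = sync,
              decomposition = dec_all,
              events = dplyr::bind_rows(events_all),
              metrics = results, log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$decomposition,
                     file.path(out_dir, "strain_decomposition.csv"),
                     row.names = FALSE)
    utils::write.csv(out$sync, file.path(out_dir, "synchronisation.csv"),
                     row.names = FALSE)
    utils::write.csv(out$events, file.path(out_dir, "t1_events.csv"),
                     row.names = FALSE)
    for (mname in names(results))
      utils::write.csv(results[[mname]]$comparison,
                       file.path(out_dir, sprintf("compare_%s.csv", mname)),
                       row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("epimorph")),
      r_version = R.version.string,
      seed = config$seed,
      config = config[order(names(config))],
      log = log_lines)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
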