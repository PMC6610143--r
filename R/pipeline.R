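#' Run a configured analysis pipeline end to end
#'
#' Executes the stages named in `config` in their canonical order —
#' `simulate` -> `localize` -> `track` -> `msd`, plus the independent
#' `frap`, `spr` and `runoff` stages — writing every intermediate table as
#' CSV under `out_dir` and a machine-readable JSON run report
#' (`report.json`) holding the parameters, the seed and the headline fitted
#' numbers. All randomness flows from `config$seed`; running the same
#' config twice produces identical outputs.
#'
#' Config blocks (all optional except `seed`):
#' * `simulate`: `kind`, `D`, `jitter_sd`, `n_tracks`, `n_frames`, `dt`,
#'   `loc_noise_um` — ground-truth tracks (plus localization noise).
#' * `localize`: `render = TRUE` renders the simulated tracks to a movie and
#'   re-localizes it (optics fields may be overridden); otherwise the stage
#'   is skipped in favour of the ground-truth table.
#' * `track`: `max_disp_um`, `min_length_frames`, `max_jump_nm` (filter
#'   applied only when both are present).
#' * `msd`: `max_lag_frames`, `n_points` — ensemble MSD + diffusion fit.
#' * `frap`: generator parameters of [make_frap_trace()] -> normalize + fit.
#' * `spr`: `k_on`, `k_off`, `R_max`, `concentrations_M`, `noise_sd` ->
#'   global one-to-one fit.
#' * `runoff`: [runoff_scene()] fields + `n_frames` -> normalized curve.
#'
#' @param config a named list, or a path to a JSON/YAML config file.
#' @param out_dir output directory (created if missing); defaults to
#'   `config$out_dir`.
#' @return the run report, invisibly (a list, also written as JSON).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a config file path.")
  if (is.null(config$seed)) abort("`config$seed` is required.")
  out_dir <- out_dir %||% config$out_dir %||% abort("`out_dir` is required.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  report <- list(package = "spottrackr",
                 version = as.character(utils::packageVersion("spottrackr")),
                 seed = seed, config = config, results = list())

  tracks <- NULL
  dt <- config$simulate$dt %||% 1
  if (!is.null(config$simulate)) {
    s <- config$simulate
    model <- motion_model(kind = s$kind %||% "brownian", D = s$D %||% 0.1,
                          jitter_sd = s$jitter_sd %||% 0.03)
    tracks <- make_tracks(model, n_tracks = s$n_tracks %||% 100,
                          n_frames = s$n_frames %||% 30, dt = dt,
                          seed = seed)
    noise <- s$loc_noise_um %||% 0
    if (noise > 0) {
      set.seed(seed + 1L)
      tracks$x_um <- tracks$x_um + rnorm(nrow(tracks), 0, noise)
      tracks$y_um <- tracks$y_um + rnorm(nrow(tracks), 0, noise)
    }
    write_tracks(tracks, file.path(out_dir, "ground_truth_tracks.csv"))
    report$results$n_ground_truth_tracks <- length(unique(tracks$track_id))
  }

  locs <- NULL
  if (!is.null(config$localize) && isTRUE(config$localize$render)) {
    if (is.null(tracks)) abort("localize stage needs a simulate stage.")
    opt <- do.call(optics, c(config$localize$optics %||% list(),
                             list(frame_interval_s = dt)))
    mv <- render_movie(tracks, opt, seed = seed + 2L)
    write_movie(mv, file.path(out_dir, "movie.tif"))
    locs <- localize_movie(mv)
    write_localizations(locs, file.path(out_dir, "localizations.csv"))
    report$results$n_localizations <- nrow(locs)
  } else if (!is.null(tracks)) {
    locs <- mutate(tracks, channel = 1L)
  }

  linked <- NULL
  if (!is.null(config$track)) {
    if (is.null(locs)) abort("track stage needs localizations.")
    tk <- config$track
    linked <- link_nearest_neighbor(select(locs, -dplyr::any_of("track_id")),
                                    max_disp = tk$max_disp_um %||% 1.5)
    if (!is.null(tk$min_length_frames) && !is.null(tk$max_jump_nm)) {
      linked <- filter_bound(linked, tk$min_length_frames, tk$max_jump_nm)
    }
    write_tracks(linked, file.path(out_dir, "tracks.csv"))
    write.csv(track_jump_stats(linked), file.path(out_dir, "track_summary.csv"),
              row.names = FALSE)
    report$results$n_tracks <- length(unique(linked$track_id))
  }

  if (!is.null(config$msd)) {
    src <- linked %||% tracks
    if (is.null(src)) abort("msd stage needs tracks.")
    msd <- ensemble_msd(src, max_lag_frames = config$msd$max_lag_frames %||% 10,
                        frame_interval_s = dt)
    dfit <- fit_diffusion(msd, n_points = config$msd$n_points %||% 5)
    write.csv(as_tibble(msd), file.path(out_dir, "msd.csv"), row.names = FALSE)
    report$results$D_um2_s <- dfit$D
    report$results$D_ci95_um2_s <- dfit$ci95
  }

  if (!is.null(config$frap)) {
    fp <- config$frap
    trace <- make_frap_trace(k = fp$k %||% log(2) / 141,
                             mobile_fraction = fp$mobile_fraction %||% 1,
                             bleach_depth = fp$bleach_depth %||% 0.6,
                             noise_sd = fp$noise_sd %||% 0,
                             pre_frames = fp$pre_frames %||% 10,
                             post_frames = fp$post_frames %||% 400,
                             dt = fp$dt %||% 1, seed = seed + 3L)
    curve <- normalize_frap(trace)
    ffit <- fit_frap(curve)
    write.csv(as_tibble(curve), file.path(out_dir, "frap_curve.csv"), row.names = FALSE)
    report$results$frap_t_half_s <- ffit$t_half
    report$results$frap_mobile_fraction <- ffit$mobile_fraction
  }

  if (!is.null(config$spr)) {
    sp <- config$spr
    concs <- sp$concentrations_M %||% c(100e-9, 30e-9)
    sgs <- map(seq_along(concs), function(i) {
      make_sensorgram(sp$k_on %||% 1e5, sp$k_off %||% 1.47e-3,
                      sp$R_max %||% 100, concs[i],
                      noise_sd = sp$noise_sd %||% 0, seed = seed + 10L + i)
    })
    bfit <- fit_binding(sgs)
    write.csv(bind_rows(sgs), file.path(out_dir, "sensorgrams.csv"), row.names = FALSE)
    report$results$spr_K_D_nM <- bfit$K_D * 1e9
    report$results$spr_k_on <- bfit$k_on
    report$results$spr_k_off <- bfit$k_off
  }

  if (!is.null(config$runoff)) {
    ro <- config$runoff
    scene <- runoff_scene(n_cells = ro$n_cells %||% 3,
                          spots_per_cell = ro$spots_per_cell %||% 16,
                          drug_time_s = ro$drug_time_s %||% 100,
                          runoff_rate = ro$runoff_rate %||% 0.02)
    opt <- optics(frame_interval_s = ro$dt %||% 10)
    sim <- make_runoff_scene(scene, opt, n_frames = ro$n_frames %||% 40,
                             seed = seed + 20L)
    curve <- runoff_curve(sim$counts, scene$drug_time_s)
    write.csv(curve, file.path(out_dir, "runoff_curve.csv"), row.names = FALSE)
    final <- filter(curve, .data$channel == 1) %>% tail(1)
    report$results$runoff_final_fraction <- final$mean_norm
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

#' Read a pipeline config from JSON or YAML
#'
#' @param path config file path (`.json`, `.yml` or `.yaml`).
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) abort("yaml package not available.")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
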