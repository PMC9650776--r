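#' Run the simulate -> localize -> pair -> (classify | fret) pipeline
#'
#' Executes the stages listed in `config$stages` in order, writing each
#' stage's artifact into `out_dir` (`frames.tif`, `localizations.csv`,
#' `pairs.csv`, `classified.csv` or `fret_states.json`). All randomness
#' derives from the root seed, split deterministically per stage, so a rerun
#' with the same config and seed reproduces every output bit-identically.
#' `classify` and `fret` are mutually exclusive in one run. Inputs on disk
#' are never modified. Stage failures abort with the stage name in the
#' message.
#'
#' @param config A `pipeline_config` (see [read_config()]) or a path to a
#'   JSON config file.
#' @param out_dir Output directory (created if needed); overrides
#'   `config$out_dir`.
#' @param seed Root integer seed; overrides `config$seed`.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  stages <- unlist(config$stages)
  if (is.null(stages)) stages <- c("simulate", "localize", "pair")
  if (all(c("classify", "fret") %in% stages))
    stop("stages 'classify' and 'fret' are mutually exclusive in one run")
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- seed %||% config$seed %||% 1L
  stage_seed <- function(stage)
    (seed + 1000L * match(stage,
                          c("simulate", "localize", "pair", "classify",
                            "fret"))) %% .Machine$integer.max
  cal <- config$calibration
  cfg_opt <- config$optics
  artifacts <- list()
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    sim <- config$simulate
    set.seed(stage_seed("simulate"))
    fov <- sim$fov_px %||% c(96, 96)
    n_frames <- sim$n_frames %||% 10
    n_emitters <- sim$n_emitters %||% 8
    dye <- sim$dye %||% "CF660"
    photons <- sim$photons %||% 2000
    spec <- dye_spectrum(dye)
    px <- cfg_opt$pixel_size_nm
    ems <- lapply(seq_len(n_emitters), function(i)
      emitter(stats::runif(1, 0.1, 0.55) * fov[1] * px,
              stats::runif(1, 0.1, 0.9) * fov[2] * px,
              spec, photons = photons))
    noise <- do.call(noise_model, c(as.list(config$noise),
                                    list(seed = stage_seed("simulate"))))
    sim_out <- simulate_frames(ems, cfg_opt, cal, noise, fov_px = fov,
                               n_frames = n_frames)
    write_frames(sim_out$stack, file.path(out_dir, "frames.tif"))
    write_table_with_header(sim_out$truth,
                            file.path(out_dir, "ground_truth.csv"),
                            seed = seed)
    artifacts$frames <<- file.path(out_dir, "frames.tif")
    artifacts$ground_truth <<- file.path(out_dir, "ground_truth.csv")
  })

  if ("localize" %in% stages) run_stage("localize", function() {
    stack <- read_frames(artifacts$frames %||%
                           file.path(out_dir, "frames.tif"))
    locs <- localize_stack(stack, cfg_opt, as.list(config$localize))
    write_localizations(locs, file.path(out_dir, "localizations.csv"),
                        seed = seed)
    artifacts$localizations <<- file.path(out_dir, "localizations.csv")
  })

  if ("pair" %in% stages) run_stage("pair", function() {
    locs <- read_localizations(artifacts$localizations %||%
                                 file.path(out_dir, "localizations.csv"))
    p <- as.list(config$pair)
    linked <- link_orders(locs, cal,
                          d_window = p$d_window %||% c(2200, 3600),
                          lateral_tol_nm = p$lateral_tol_nm %||% 150)
    write_pairs(linked$pairs, file.path(out_dir, "pairs.csv"), seed = seed)
    artifacts$pairs <<- file.path(out_dir, "pairs.csv")
  })

  if ("classify" %in% stages) run_stage("classify", function() {
    pairs <- read_pairs(artifacts$pairs %||% file.path(out_dir, "pairs.csv"))
    cl <- as.list(config$classify)
    if (!is.null(cl$cutoff_nm)) {
      pairs <- assign_species(pairs, "threshold", cutoff_nm = cl$cutoff_nm)
    } else {
      hist <- pair_distance_histogram(pairs, bin_nm = cl$bin_nm %||% 5)
      model <- fit_distance_histogram(hist, cl$n_components %||% 2)
      pairs <- assign_species(pairs, "max_likelihood", model = model)
    }
    write_pairs(pairs, file.path(out_dir, "classified.csv"), seed = seed)
    artifacts$classified <<- file.path(out_dir, "classified.csv")
  })

  if ("fret" %in% stages) run_stage("fret", function() {
    pairs <- read_pairs(artifacts$pairs %||% file.path(out_dir, "pairs.csv"))
    states <- fit_dsigma_histogram(pairs, reference_fret_states(),
                                   bin_nm = config$fret$bin_nm %||% c(10, 10))
    out <- lapply(states, function(s)
      list(name = s$name, mean = s$mean,
           covariance = as.numeric(s$covariance), weight = s$weight))
    jsonlite::write_json(out, file.path(out_dir, "fret_states.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts$fret_states <<- file.path(out_dir, "fret_states.json")
  })

  invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
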