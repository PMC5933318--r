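#' Pipeline run configuration
#'
#' Collects every setting of the full analysis — prepare (read, speed-filter,
#' gap-split), broad-scale fit (model 1, 48 h grid, all tracks), fine-scale
#' fit (model 2, 6 h grid, a configured subset), behavioral classification
#' and movement descriptors, and dive statistics — into one validated list.
#' Accepts a YAML file path or a named list.
#'
#' @param config list or path to a YAML file. Recognised keys (defaults in
#'   parentheses): `argos` (input CSV, required), `depth` (depth CSV,
#'   optional), `out_dir` (required), `max_speed` (30 km/h),
#'   `max_fraction_removed` (0.04), `gap_days` (28), `model1_step` (48),
#'   `model2_step` (6), `model2_tracks` (character vector of track ids;
#'   default none), `dive_threshold` (10 m), and an `mcmc` sub-list
#'   (`n_chains` 2, `n_iter` 120000, `n_burnin` 100000, `thin` 20, `seed` 1).
#' @return A list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  def <- list(depth = NULL, max_speed = 30, max_fraction_removed = 0.04,
              gap_days = 28, model1_step = 48, model2_step = 6,
              model2_tracks = character(0), dive_threshold = 10,
              mcmc = list())
  for (k in names(def)) if (is.null(config[[k]])) config[[k]] <- def[[k]]
  if (is.null(config$argos)) stop("config must name an `argos` input file")
  if (is.null(config$out_dir)) stop("config must name an `out_dir`")
  md <- list(n_chains = 2, n_iter = 120000, n_burnin = 100000, thin = 20,
             seed = 1)
  for (k in names(md)) if (is.null(config$mcmc[[k]])) config$mcmc[[k]] <- md[[k]]
  config$mcmc <- do.call(mcmc_config, config$mcmc)
  structure(config, class = "run_config")
}

#' Run the full track-analysis pipeline
#'
#' Executes prepare, model-1 fit, descriptors, optional model-2 fit on a
#' track subset, and optional dive analysis, writing versioned outputs and a
#' JSON manifest (inputs, settings, seed, per-stage status, R-hat summary)
#' under `config$out_dir`. A stage failure is recorded in the manifest
#' (partial completion) rather than aborting the run; non-convergence is
#' flagged, not fatal. Reruns with the same config and seed are
#' deterministic.
#'
#' @param config a [run_config()] (or list/YAML path coercible to one).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(settings = list(
    argos = config$argos, depth = config$depth,
    max_speed = config$max_speed, gap_days = config$gap_days,
    model1_step = config$model1_step, model2_step = config$model2_step,
    seed = config$mcmc$seed,
    mcmc = unclass(config$mcmc)), stages = list())
  stage <- function(name, fun) {
    r <- tryCatch(list(status = "ok", value = fun()),
                  error = function(e) list(status = "failed",
                                           error = conditionMessage(e)))
    manifest$stages[[name]] <<- r[setdiff(names(r), "value")]
    r$value
  }

  tracks <- stage("prepare", function() {
    raw <- read_argos(config$argos)
    if (!length(raw)) stop("no tracks in ", config$argos)
    prepped <- list()
    removed <- numeric(0)
    for (tr in raw) {
      flt <- filter_implausible(tr, config$max_speed,
                                config$max_fraction_removed)
      removed[tr$track_id] <- attr(flt, "removed_fraction")
      prepped <- c(prepped, split_on_gap(flt, config$gap_days))
    }
    names(prepped) <- vapply(prepped, function(x) x$track_id, "")
    write_tracks_csv(prepped, file.path(out, "tracks_clean.csv"))
    manifest$stages$prepare$removed_fraction <<- mean(removed)
    prepped
  })
  if (is.null(tracks)) {
    manifest$complete <- FALSE
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = 8, pretty = TRUE)
    return(invisible(manifest))
  }

  fit1 <- stage("fit_model1", function() {
    f <- fit_dcrws(tracks, config$model1_step, config$mcmc)
    write_fit(f, file.path(out, "model1"))
    manifest$stages$fit_model1$max_rhat <<- max(f$param_summary$rhat,
                                                na.rm = TRUE)
    manifest$stages$fit_model1$converged <<- f$converged
    f
  })

  if (!is.null(fit1)) stage("summarize", function() {
    desc <- summarize_fit(fit1)
    utils::write.csv(format_descriptors(desc),
                     file.path(out, "descriptors.csv"), row.names = FALSE)
    utils::write.csv(desc, file.path(out, "descriptors_full.csv"),
                     row.names = FALSE)
    TRUE
  })

  fit2 <- NULL
  if (length(config$model2_tracks)) fit2 <- stage("fit_model2", function() {
    sub <- tracks[intersect(config$model2_tracks, names(tracks))]
    if (!length(sub)) stop("model2_tracks matches no prepared track")
    mc2 <- config$mcmc
    mc2$seed <- config$mcmc$seed + 1000L
    f <- fit_dcrws(sub, config$model2_step, mc2)
    write_fit(f, file.path(out, "model2"))
    manifest$stages$fit_model2$converged <<- f$converged
    f
  })

  if (!is.null(config$depth) && !is.null(fit1)) stage("dives", function() {
    bouts <- read_depth_series(config$depth)
    if (!length(bouts)) stop("no depth bouts in ", config$depth)
    dives <- do.call(rbind, lapply(bouts, detect_dives,
                                   threshold = config$dive_threshold))
    by_tag <- split(dives, dives$tag_id)
    tagged <- list()
    for (tag in names(by_tag)) {
      src <- if (!is.null(fit2) && tag %in% names(fit2$tracks)) fit2 else fit1
      id <- grep(paste0("^", tag), names(src$tracks), value = TRUE)[1L]
      if (is.na(id)) next
      tagged[[tag]] <- add_diel(by_tag[[tag]], src$tracks[[id]]$summary)
    }
    dives <- do.call(rbind, tagged)
    write_dives_csv(dives, file.path(out, "dives.csv"))
    utils::write.csv(summarize_dives(dives),
                     file.path(out, "dive_summary_by_tag.csv"),
                     row.names = FALSE)
    for (tag in names(tagged)) {
      src <- if (!is.null(fit2) && tag %in% names(fit2$tracks)) fit2 else fit1
      id <- grep(paste0("^", tag), names(src$tracks), value = TRUE)[1L]
      binned <- bin_dive_stats(tagged[[tag]], src$tracks[[id]]$grid)
      utils::write.csv(binned,
                       file.path(out, paste0("dive_bins_", tag, ".csv")),
                       row.names = FALSE)
    }
    TRUE
  })

  manifest$complete <- all(vapply(manifest$stages,
                                  function(s) identical(s$status, "ok"),
                                  TRUE))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)
  invisible(manifest)
}
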