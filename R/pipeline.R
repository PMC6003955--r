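#' Default pipeline configuration
#'
#' Collects every analysis constant in one overridable list: geometry, the
#' synthetic population mixture and gains, seeds, discretizations (5 cm
#' maps, 0.4 m information grid, 45 degree angle bins, 0.1 m / 90 degree
#' consistency bins), permutation counts and decision thresholds (FDR 0.05,
#' tuning-depth F-test p < 0.005, strict-median highly-tuned rule, 70%
#' cross-session stability rule).
#'
#' @param ... named overrides of the defaults.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    geometry = room_geometry(),
    population = list(n_position = 8, n_orientation = 8, n_mixed = 0,
                      n_untuned = 8, position_gain = 1.5, alpha_gain = 1.2,
                      reach_fraction = 0.3, reach_gain = 2),
    n_sessions = 1,
    n_trials = 20,
    seed = 1,
    mi = list(n_perm = 200, alpha = 0.05),
    model = list(k_pos = c(5, 5), k_angle = 6, interactions = FALSE),
    thresholds = list(td_p = 0.005, stable_fraction = 0.7),
    decoding = list(run = TRUE, folds = 5, restarts = 2, chance_n = 10),
    reach = list(run = TRUE, n_trees = 100, folds = 5),
    consistency = list(n_perm = 200)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `read_pipeline_config` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$geometry <- list(room_size = x$geometry$room_size,
                     drivable_size = x$geometry$drivable_size,
                     dispenser_xy = x$geometry$dispenser_xy,
                     start_xy = x$geometry$start_xy,
                     docking_radius = x$geometry$docking_radius,
                     reach_radius = x$geometry$reach_radius)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- x$geometry
  x$geometry <- room_geometry(room_size = g$room_size,
                              drivable_size = g$drivable_size,
                              dispenser_xy = g$dispenser_xy,
                              start_xy = matrix(g$start_xy, ncol = 2),
                              docking_radius = g$docking_radius,
                              reach_radius = g$reach_radius)
  do.call(pipeline_config, x)
}

#' Run the full analysis pipeline on synthetic sessions
#'
#' Generates the configured synthetic sessions, then runs the stages in
#' order: mutual-information screening, additive-model tuning depths and
#' preference classification, population place-field and
#' preferred-direction summaries, cross-session consistency (when more
#' than one session), position decoding with chance levels, and the
#' reach-state classifier. Stage outputs are written as CSV/JSON under
#' `out_dir` with a manifest listing every file with an MD5 checksum; a
#' stage failure leaves a partial manifest naming the failing stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return the report list (stage summaries), invisibly also on disk.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  manifest <- list(seed = config$seed, started = format(t0), files = list())
  report <- list()
  record <- function(path) {
    manifest$files[[basename(path)]] <<-
      unname(tools::md5sum(path))
  }
  fail <- function(stage, e) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  stage <- "synthesize"
  tryCatch({
    gt <- do.call(make_population,
                  c(config$population,
                    list(geometry = config$geometry, seed = config$seed)))
    sessions <- generate_multi_session(gt, config$n_sessions,
                                       n_trials = config$n_trials,
                                       geometry = config$geometry)
    for (s in seq_along(sessions)) {
      p <- write_session(sessions[[s]],
                         file.path(out_dir, sprintf("session%02d", s)))
      for (pp in p) record(pp)
    }
    report$n_sessions <- length(sessions)
    report$n_neurons <- length(gt$neurons)
  }, error = function(e) fail(stage, e))

  stage <- "mi_screen"
  tryCatch({
    mi <- mi_screen(sessions[[1]], n_perm = config$mi$n_perm,
                    seed = config$seed, alpha = config$mi$alpha)
    path <- file.path(out_dir, "mi_screen.csv")
    utils::write.csv(mi, path, row.names = FALSE)
    record(path)
    report$mi_significant <- sum(mi$significant)
    sig_neurons <- unique(mi$neuron[mi$significant])
  }, error = function(e) fail(stage, e))

  stage <- "tuning_model"
  tryCatch({
    spec <- tuning_model_spec(k_pos = config$model$k_pos,
                              k_angle = config$model$k_angle,
                              interactions = config$model$interactions)
    idx <- match(sig_neurons, rownames(sessions[[1]]$spikes))
    if (!length(idx)) idx <- seq_len(min(5, nrow(sessions[[1]]$spikes)))
    assess <- assess_tuning(sessions[[1]], idx, spec, keep_fits = TRUE)
    path <- file.path(out_dir, "tuning_depths.csv")
    utils::write.csv(assess$table, path, row.names = FALSE)
    record(path)
    report$n_assessed <- sum(!is.na(assess$table$preference))
    report$n_highly_tuned <- sum(assess$table$highly_tuned)
  }, error = function(e) fail(stage, e))

  stage <- "population_summaries"
  tryCatch({
    pos_idx <- which(!is.na(assess$table$preference) &
                       assess$table$preference == "position")
    if (length(pos_idx)) {
      fields <- lapply(assess$fits[pos_idx], function(f) {
        extract_place_field(extract_position_surface(f), config$geometry)
      })
      hm <- ensemble_place_field_heatmap(list(fields))
      path <- file.path(out_dir, "place_field_heatmap.csv")
      utils::write.table(hm$heatmap, path, sep = ",", row.names = FALSE,
                         col.names = FALSE)
      record(path)
      report$place_field_ks_p <- hm$ks_p
    }
    ori_idx <- which(!is.na(assess$table$preference) &
                       assess$table$preference == "orientation")
    if (length(ori_idx)) {
      dirs <- vapply(assess$fits[ori_idx], function(f) {
        preferred_direction(extract_angle_curve(f, "alpha"))$direction
      }, 0)
      dh <- direction_histogram(list(dirs))
      path <- file.path(out_dir, "preferred_direction_histogram.csv")
      utils::write.csv(data.frame(bin_lo = dh$edges[-9], bin_hi = dh$edges[-1],
                                  proportion = dh$proportion),
                       path, row.names = FALSE)
      record(path)
      report$direction_ks_p <- dh$ks_p
    }
  }, error = function(e) fail(stage, e))

  if (config$n_sessions >= 2) {
    stage <- "consistency"
    tryCatch({
      cp <- consistency_permutation(sessions,
                                    n_perm = config$consistency$n_perm,
                                    seed = config$seed)
      path <- file.path(out_dir, "consistency.csv")
      utils::write.csv(cp$between, path, row.names = FALSE)
      record(path)
      report$consistency_between <- mean(cp$between$index)
      report$consistency_ranksum_p <- cp$ranksum_p
    }, error = function(e) fail(stage, e))
  }

  if (isTRUE(config$decoding$run)) {
    stage <- "decoding"
    tryCatch({
      dspec <- decoder_spec(folds = config$decoding$folds,
                            restarts = config$decoding$restarts)
      dec <- crossvalidated_decode(sessions[[1]], "position",
                                   spec = dspec, seed = config$seed)
      ch <- chance_distribution(sessions[[1]], "position", spec = dspec,
                                n = config$decoding$chance_n,
                                seed = config$seed,
                                actual = dec$session_metric)
      path <- file.path(out_dir, "decoding.json")
      jsonlite::write_json(list(mpe = dec$session_metric,
                                fold_mpe = dec$fold_metric,
                                chance_ci = ch$ci, p = ch$p),
                           path, digits = NA, auto_unbox = TRUE)
      record(path)
      report$decode_mpe <- dec$session_metric
      report$decode_chance_ci <- ch$ci
    }, error = function(e) fail(stage, e))
  }

  if (isTRUE(config$reach$run)) {
    stage <- "reach"
    tryCatch({
      rc <- train_reach_classifier(sessions[[1]],
                                   n_trees = config$reach$n_trees,
                                   folds = config$reach$folds,
                                   seed = config$seed)
      path <- file.path(out_dir, "reach_kappa.json")
      jsonlite::write_json(list(fold_kappa = rc$fold_kappa,
                                mean_kappa = rc$mean_kappa,
                                imbalance = rc$imbalance),
                           path, digits = NA, auto_unbox = TRUE)
      record(path)
      report$reach_kappa <- rc$mean_kappa
    }, error = function(e) fail(stage, e))
  }

  manifest$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$report <- report
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(report)
}
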