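# End-to-end orchestration: descriptive then predictive runs with manifests.

#' Run configuration
#'
#' Declarative configuration for [run_descriptive()] / [run_predictive()],
#' mirroring the two analysis stages: input file pairs per participant,
#' output directory, geometry and cleaning settings, zero or more window
#' strategies (none selected = one summative record per participant), AOI
#' analysis switch, and the predictive settings.
#'
#' @param participants Named list; each element `list(gaze = <path>,
#'   fixations = <path>)`. The gaze path may be `NULL` if only fixation
#'   measures are needed.
#' @param out_dir Output directory.
#' @param geometry A [screen_geometry()].
#' @param cleaning A [cleaning_config()].
#' @param windows List of [window_spec()]s (possibly empty).
#' @param aoi Run AOI analytics when labels are present.
#' @param group_mode Group aggregation for batches: `"pooled"`,
#'   `"mean_of_persons"`, or `NULL` to skip the group record.
#' @param predictive List with `task`, `models`, `folds`, `seed`,
#'   `labels_file` (CSV `participant,label`), `cv`.
#' @return A `run_config` list.
#' @export
run_config <- function(participants, out_dir, geometry = screen_geometry(),
                       cleaning = cleaning_config(), windows = list(),
                       aoi = TRUE, group_mode = "pooled",
                       predictive = NULL) {
  if (!length(participants)) stop("run_config: no participants given")
  if (is.null(names(participants)) || any(names(participants) == "")) {
    stop("run_config: participants must be a named list")
  }
  structure(list(participants = participants, out_dir = out_dir,
                 geometry = geometry, cleaning = cleaning,
                 windows = windows, aoi = isTRUE(aoi),
                 group_mode = group_mode, predictive = predictive),
            class = "run_config")
}

.load_participant <- function(id, paths, geometry, cleaning) {
  fx <- read_fixations(paths$fixations, geometry)
  sm <- NULL
  clean_stats <- NULL
  if (!is.null(paths$gaze)) {
    raw <- read_all_gaze(paths$gaze, geometry)
    dn <- denoise(raw, cleaning)
    sm <- dn$samples
    clean_stats <- c(rows_in = nrow(raw), rows_kept = nrow(dn$samples),
                     dn$counts)
  }
  list(id = id, fixations = fx, samples = sm, clean_stats = clean_stats)
}

#' Run the descriptive-analytics stage
#'
#' Loads and de-noises every participant, emits one DGM CSV per participant
#' per selected window strategy (or a single summative file when no window
#' is selected), a group record in batch mode, AOI tables when labels are
#' present, and a manifest listing every output with its scope and row
#' count. A participant that fails to load is logged in the manifest and
#' the batch continues.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest data.frame (also written as CSV and JSON
#'   under `out_dir`).
#' @export
run_descriptive <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  loaded <- list()
  note <- function(file, scope, kind, rows, status = "ok") {
    manifest[[length(manifest) + 1]] <<- data.frame(
      file = file, scope = scope, kind = kind, rows = rows,
      status = status, stringsAsFactors = FALSE)
  }
  for (id in names(config$participants)) {
    res <- try(.load_participant(id, config$participants[[id]],
                                 config$geometry, config$cleaning),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("participant ", id, " failed: ", attr(res, "condition")$message)
      note(NA_character_, id, "load_failure", 0, "failed")
      next
    }
    loaded[[id]] <- res
    if (!is.null(res$clean_stats)) {
      message("cleaning [", id, "]: ",
              paste(names(res$clean_stats), res$clean_stats,
                    sep = "=", collapse = " "))
    }
    if (!length(config$windows)) {
      rec <- summative_dgms(res$fixations, res$samples, config$geometry,
                            include_aoi = config$aoi, scope = id)
      path <- file.path(config$out_dir, paste0(id, "_summative_dgms.csv"))
      utils::write.csv(as.data.frame(rec), path, row.names = FALSE, na = "")
      note(path, id, "summative", nrow(rec))
    } else {
      for (w in config$windows) {
        recs <- windowed_dgms(res$fixations, res$samples, w,
                              config$geometry, scope = id,
                              include_aoi = config$aoi)
        path <- file.path(config$out_dir,
                          paste0(id, "_", w$kind, "_dgms.csv"))
        utils::write.csv(as.data.frame(recs), path, row.names = FALSE,
                         na = "")
        note(path, id, w$kind, nrow(recs))
        slices <- attr(recs, "slices")
        if (!is.null(slices) && nrow(slices)) {
          mpath <- file.path(config$out_dir,
                             paste0(id, "_", w$kind, "_windows.csv"))
          utils::write.csv(slices, mpath, row.names = FALSE, na = "")
          note(mpath, id, paste0(w$kind, "_manifest"), nrow(slices))
        }
      }
    }
  }
  if (length(loaded) > 1 && !is.null(config$group_mode)) {
    grp <- group_dgms(lapply(loaded, function(p) {
      list(fixations = p$fixations, samples = p$samples)
    }), mode = config$group_mode, geometry = config$geometry,
    include_aoi = config$aoi)
    path <- file.path(config$out_dir, "group_summative_dgms.csv")
    utils::write.csv(as.data.frame(grp), path, row.names = FALSE, na = "")
    note(path, paste0("group:", config$group_mode), "group_summative",
         nrow(grp))
  }
  if (config$aoi) {
    fx_by_p <- lapply(loaded, function(p) p$fixations)
    if (length(fx_by_p) &&
        any(vapply(fx_by_p, function(f) any(!is.na(f$aoi_label)),
                   logical(1)))) {
      paths <- write_aoi_tables(fx_by_p, config$out_dir)
      for (p in paths) note(p, "group", "aoi_table", NA)
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, na = "null")
  invisible(manifest)
}

#' Run the predictive-analytics stage
#'
#' Reads windowed DGM files produced by [run_descriptive()] (one per
#' participant), joins them with participant outcome labels and evaluates
#' the selected models once per window stage, so prediction quality can be
#' tracked over interaction time. With summative input a single stage is
#' evaluated.
#'
#' @param dgm_files Named character vector (participant -> DGM CSV path),
#'   or a pre-assembled `dgm_record` data.frame.
#' @param labels Named vector, data.frame (`participant`, `label`) or a CSV
#'   path with those columns.
#' @param task `"classification"` or `"regression"`.
#' @param models Registry names or `"all"`.
#' @param folds,seed,cv Passed to [evaluate_models()].
#' @param out_dir Optional directory for per-stage report CSVs.
#' @return A list of `evaluation_report`s, one per window stage, named by
#'   stage.
#' @export
run_predictive <- function(dgm_files, labels,
                           task = c("classification", "regression"),
                           models = "all", folds = 10, seed = 1,
                           cv = c("stratified", "grouped"), out_dir = NULL) {
  task <- match.arg(task)
  cv <- match.arg(cv)
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    labels <- utils::read.csv(labels, stringsAsFactors = FALSE)
  }
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$label, labels$participant)
  }
  records <- if (is.data.frame(dgm_files)) {
    dgm_files
  } else {
    rows <- lapply(names(dgm_files), function(id) {
      d <- utils::read.csv(dgm_files[[id]], stringsAsFactors = FALSE,
                           check.names = FALSE)
      d$participant <- id
      d
    })
    all_names <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(r) {
      for (nm in setdiff(all_names, names(r))) r[[nm]] <- NA
      r[all_names]
    })
    do.call(rbind, rows)
  }
  missing <- setdiff(unique(records$participant), names(labels))
  if (length(missing)) {
    stop("run_predictive: no label for participant(s): ",
         paste(missing, collapse = ", "))
  }
  stages <- if ("window_index" %in% names(records) &&
                any(!is.na(records$window_index))) {
    sort(unique(records$window_index))
  } else NA
  reports <- list()
  for (st in stages) {
    sub <- if (is.na(st[1])) records
           else records[records$window_index == st, , drop = FALSE]
    if ("empty" %in% names(sub)) {
      sub <- sub[!(sub$empty %in% TRUE), , drop = FALSE]
    }
    if (!nrow(sub)) next
    feats <- assemble_features(sub, labels, task)
    rep <- try(evaluate_models(feats, models, folds, seed, cv),
               silent = TRUE)
    if (inherits(rep, "try-error")) {
      warning("stage ", st, " skipped: ", attr(rep, "condition")$message)
      next
    }
    stage_name <- if (is.na(st[1])) "summative" else paste0("stage_", st)
    reports[[stage_name]] <- rep
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(rep$report,
                       file.path(out_dir, paste0(stage_name, "_report.csv")),
                       row.names = FALSE)
      utils::write.csv(rep$summary,
                       file.path(out_dir, paste0(stage_name, "_summary.csv")),
                       row.names = FALSE)
    }
  }
  reports
}
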