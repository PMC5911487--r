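#' Write / read a FOV recording as a CSV + JSON container
#'
#' The on-disk layout of one session is a flat, text-only container under
#' `dir`: `<prefix>_traces.csv` (cells x frames, full 17-digit precision so
#' round trips are bit exact), `<prefix>_schedule.csv` (columns `onset_s`,
#' `offset_s`), and `<prefix>_meta.json` (frame rate, condition label,
#' patched cell, optional positions/flags, and the synthetic ground truth).
#' Times are stored in seconds; cell indices are 1-based row numbers of the
#' trace matrix.
#'
#' `readFovRecording()` validates the layout: missing files raise a schema
#' error naming the file, and schedules with inter-trial gaps below 2.5 s
#' load with a loud warning rather than silently.
#'
#' @param rec a [FovRecording-class].
#' @param dir directory (created if needed).
#' @param prefix file-name prefix.
#' @return `writeFovRecording()` returns `dir` invisibly;
#'   `readFovRecording()` returns a [FovRecording-class].
#' @export
writeFovRecording <- function(rec, dir, prefix = "fov") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    tr <- traces(rec)
    lines <- vapply(seq_len(nrow(tr)), function(i)
        paste(c(rownames(tr)[i], sprintf("%.17g", tr[i, ])), collapse = ","),
        character(1))
    writeLines(c(paste(c("cell", sprintf("f%d", seq_len(ncol(tr)) - 1L)),
                       collapse = ","), lines),
               file.path(dir, paste0(prefix, "_traces.csv")))
    sched <- stimSchedule(rec)
    write.csv(data.frame(onset_s = sprintf("%.17g", onsets(sched)),
                         offset_s = sprintf("%.17g", offsets(sched))),
              file.path(dir, paste0(prefix, "_schedule.csv")),
              row.names = FALSE, quote = FALSE)
    rd <- rowData(rec)
    meta <- list(frame_rate = frameRate(rec),
                 condition_label = conditionLabel(rec),
                 patched_cell = if (is.na(patchedCell(rec))) NULL
                                else patchedCell(rec),
                 ground_truth = list(efficacy = as.numeric(rd$efficacy),
                                     spikes_per_trial =
                                         as.integer(rd$spikes_per_trial)))
    pos <- cellPositions(rec)
    if (!is.null(pos))
        meta$positions <- list(x_um = as.numeric(pos[, 1]),
                               y_um = as.numeric(pos[, 2]))
    if ("interneuron" %in% names(rd))
        meta$interneuron <- as.logical(rd$interneuron)
    jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_meta.json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
    invisible(dir)
}

#' @rdname writeFovRecording
#' @export
readFovRecording <- function(dir, prefix = "fov") {
    paths <- file.path(dir, paste0(prefix, c("_traces.csv", "_schedule.csv",
                                             "_meta.json")))
    for (p in paths)
        if (!file.exists(p))
            stop("schema error: missing container file '", basename(p), "'")
    trDf <- read.csv(paths[1], check.names = FALSE)
    if (ncol(trDf) < 2 || names(trDf)[1] != "cell")
        stop("schema error: '", basename(paths[1]),
             "' must have a 'cell' column followed by frame columns")
    tr <- as.matrix(trDf[, -1, drop = FALSE])
    if (!is.numeric(tr) || anyNA(tr))
        stop("schema error: non-numeric or missing values in '",
             basename(paths[1]), "'")
    rownames(tr) <- trDf$cell
    schedDf <- read.csv(paths[2])
    if (!all(c("onset_s", "offset_s") %in% names(schedDf)))
        stop("schema error: '", basename(paths[2]),
             "' must have columns onset_s, offset_s")
    sched <- StimSchedule(schedDf$onset_s, schedDf$offset_s)
    meta <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
    for (field in c("frame_rate", "condition_label"))
        if (is.null(meta[[field]]))
            stop("schema error: missing field '", field, "' in '",
                 basename(paths[3]), "'")
    pos <- NULL
    if (!is.null(meta$positions))
        pos <- cbind(meta$positions$x_um, meta$positions$y_um)
    gt <- meta$ground_truth
    FovRecording(tr, frameRate = meta$frame_rate, schedule = sched,
                 patchedCell = if (is.null(meta$patched_cell)) NA_integer_
                               else meta$patched_cell,
                 cellPositions = pos, interneuron = meta$interneuron,
                 conditionLabel = meta$condition_label,
                 efficacy = gt$efficacy, spikesPerTrial = gt$spikes_per_trial)
}

#' Write follower-detection results
#'
#' Saves the per-cell table as TSV (`cell_id`, `mean_z`, `label`, plus any
#' comparator columns, `n_trials`, threshold values) and a JSON run-metadata
#' sidecar (`<path>.meta.json`) echoing the configuration, seed, package
#' version and a config checksum, so every results artifact is reproducible
#' from inputs + config + seed.
#'
#' @param results a [FollowerResults-class].
#' @param path output TSV path.
#' @param nTrials trials per cell (recorded in the table).
#' @param extra named list merged into the metadata sidecar.
#' @return `path`, invisibly.
#' @export
writeFollowerResults <- function(results, path, nTrials = NA_integer_,
                                 extra = list()) {
    tab <- results@table
    out <- data.frame(cell_id = tab$cell, mean_z = tab$mean_z,
                      label = tab$label)
    for (cn in setdiff(names(tab), c("cell", "mean_z", "label")))
        out[[cn]] <- tab[[cn]]
    out$n_trials <- nTrials
    out$threshold_upper <- results@thresholds@upper
    out$threshold_lower <- results@thresholds@lower
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- c(list(method = results@method,
                   n_iter = results@nIter, seed = results@seed,
                   condition_label = results@conditionLabel,
                   threshold_provenance = results@thresholds@provenance,
                   threshold_upper = results@thresholds@upper,
                   threshold_lower = results@thresholds@lower,
                   package_version =
                       as.character(packageVersion("FollowerScan"))),
              extra)
    js <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
    meta$config_checksum <- sum(utf8ToInt(js)) %% 1e9
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read an analysis configuration from YAML
#'
#' Loads analysis parameters (windows, iteration count, exclusion zone,
#' threshold mode and values, efficacy grid, seed) from a YAML file and
#' merges them over the package defaults. All durations must be positive.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return named list of parameters.
#' @export
readAnalysisConfig <- function(path = NULL) {
    cfg <- list(window_response = 0.4, window_baseline = 0.6,
                n_iter = 5000L, exclusion = 1.0,
                threshold_mode = "default",
                threshold_upper = 2.1, threshold_lower = -2.3,
                efficacy_levels = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.8, 1.0),
                n_cells = 56L, n_trials = 190L, frame_rate = 10,
                seed = 1L)
    if (!is.null(path)) {
        if (!file.exists(path)) stop("config file not found: ", path)
        user <- yaml::read_yaml(path)
        unknown <- setdiff(names(user), names(cfg))
        if (length(unknown))
            stop("unknown config field(s): ", paste(unknown, collapse = ", "))
        cfg <- modifyList(cfg, user)
    }
    for (f in c("window_response", "window_baseline", "exclusion"))
        if (cfg[[f]] <= 0) stop("config field '", f, "' must be positive")
    if (!cfg$threshold_mode %in% c("default", "recalibrate"))
        stop("threshold_mode must be 'default' or 'recalibrate'")
    cfg
}
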