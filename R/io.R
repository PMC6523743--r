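# File formats: BIDS-style events TSV, time-series/motion TSV, NIfTI
# volumes and masks, study layouts, YAML configuration.

#' Write an event table as BIDS-style events.tsv
#'
#' Tab-separated with header `onset`, `duration`, `trial_type`, `correct`;
#' onsets in seconds, 0-based; missing values written as `.`.
#'
#' @param events An `event_table`.
#' @param path Output path.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  df <- data.frame(onset = events$onset, duration = events$duration,
                   trial_type = events$condition,
                   correct = as.integer(events$correct))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a BIDS-style events.tsv
#'
#' Enforces the tab-separated dialect and the event-table invariants;
#' parse errors report the offending line.
#'
#' @param path Path to an events.tsv.
#' @param run_length Optional run length (s) checked against the events.
#' @param conditions Optional declared condition set.
#' @return An `event_table`.
#' @export
read_events <- function(path, run_length = NULL, conditions = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop_config("empty events file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3L) {
    if (grepl(",", lines[1], fixed = TRUE))
      stop_config("line 1: comma-separated file; events must be ",
                  "tab-separated")
    stop_config("line 1: malformed header (expected tab-separated ",
                "onset/duration/trial_type)")
  }
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% header))
    stop_config("line 1: header must contain ",
                paste(need, collapse = ", "))
  df <- utils::read.delim(path, sep = "\t", na.strings = ".",
                          stringsAsFactors = FALSE, check.names = FALSE)
  bad <- which(!is.finite(df$onset) | df$onset < 0)
  if (length(bad))
    stop_config("line ", bad[1] + 1L, ": onset missing or negative")
  if (any(diff(df$onset) <= 0)) {
    ln <- which(diff(df$onset) <= 0)[1] + 2L
    stop_config("line ", ln, ": onsets must be strictly increasing")
  }
  correct <- if ("correct" %in% names(df)) as.logical(df$correct)
  else rep(TRUE, nrow(df))
  ev <- new_event_table(df$onset, df$duration, df$trial_type, correct)
  if (!is.null(run_length)) attr(ev, "run_length") <- run_length
  if (!is.null(conditions)) attr(ev, "conditions") <- conditions
  validate_events(ev)
  ev
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a small volume or mask as NIfTI
#'
#' Synthetic volumes are written with an identity affine. Masks are 0/1
#' volumes on the data grid.
#'
#' @param data 3-D or 4-D numeric array (or 0/1 mask array).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume_nifti <- function(data, path) {
  img <- RNifti::asNifti(data)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume or mask
#'
#' @param path Path to a NIfTI file.
#' @param mask Optional mask array or path; its grid must match the data
#'   grid (an error names both shapes otherwise).
#' @return The data array; with `mask`, a list with `data`, `mask` and
#'   `series` (timepoints x in-mask voxels matrix for 4-D data).
#' @export
read_volume_nifti <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (is.null(mask)) return(arr)
  m <- if (is.character(mask)) as.array(RNifti::readNifti(mask)) else mask
  grid <- dim(arr)[1:3]
  if (!identical(as.integer(dim(m)), as.integer(grid)))
    stop_config("mask grid (", paste(dim(m), collapse = "x"),
                ") does not match data grid (",
                paste(grid, collapse = "x"), ")")
  vox <- which(m != 0)
  series <- if (length(dim(arr)) == 4L) {
    t(apply(arr, 4, function(v) v[vox]))
  } else NULL
  list(data = arr, mask = m, series = series)
}

#' Write a simulated study to disk
#'
#' Layout: `sub-XX/ses-Y/run-Z/task-NAME_{bold.tsv,events.tsv,motion.tsv}`
#' plus `truth.csv` and `config.yaml` at the root. The bold TSV carries one
#' `seed_<region>` and one `target_<region>` column per seed-region
#' channel (a single channel writes plain `target`).
#'
#' @param study A `ppi_study`.
#' @param dir Output directory (created).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config
  single <- length(cfg$seed_regions) == 1L
  grid <- expand.grid(run = seq_len(cfg$n_runs), day = seq_len(cfg$n_days),
                      subject = seq_len(cfg$n_subjects),
                      task = cfg$tasks, stringsAsFactors = FALSE)
  for (g in seq_len(nrow(grid))) {
    i <- grid$subject[g]; d <- grid$day[g]; rn <- grid$run[g]
    tk <- grid$task[g]
    cell_dir <- file.path(dir, sprintf("sub-%02d", i), sprintf("ses-%d", d),
                          sprintf("run-%d", rn))
    dir.create(cell_dir, recursive = TRUE, showWarnings = FALSE)
    bold <- NULL
    for (sr in cfg$seed_regions) {
      rec <- study$recordings[[study_cell_key(i, d, rn, tk, sr)]]
      cols <- stats::setNames(
        list(rec$seed, rec$target),
        c(paste0("seed_", sr),
          if (single) "target" else paste0("target_", sr)))
      bold <- if (is.null(bold)) as.data.frame(cols)
      else cbind(bold, as.data.frame(cols))
    }
    rec1 <- study$recordings[[study_cell_key(i, d, rn, tk,
                                             cfg$seed_regions[1])]]
    write_tsv(bold, file.path(cell_dir, paste0("task-", tk, "_bold.tsv")))
    write_events(rec1$events,
                 file.path(cell_dir, paste0("task-", tk, "_events.tsv")))
    write_tsv(as.data.frame(rec1$motion),
              file.path(cell_dir, paste0("task-", tk, "_motion.tsv")))
  }
  utils::write.csv(study$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  write_study_config(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a study layout from disk
#'
#' Inverse of [write_study()]. Motion files may carry named
#' (`trans_x ... rot_z`) or unnamed 6-column layouts. If a shared `target`
#' column is present it serves every seed region.
#'
#' @param dir Study directory.
#' @return A `ppi_study`.
#' @export
read_study <- function(dir) {
  cfg <- read_study_config(file.path(dir, "config.yaml"))
  truth <- utils::read.csv(file.path(dir, "truth.csv"),
                           stringsAsFactors = FALSE)
  specs <- lapply(stats::setNames(cfg$tasks, cfg$tasks), task_spec)
  acqs <- lapply(specs, acq_for_task, tr = cfg$tr)
  recordings <- list()
  grid <- expand.grid(run = seq_len(cfg$n_runs), day = seq_len(cfg$n_days),
                      subject = seq_len(cfg$n_subjects),
                      task = cfg$tasks, stringsAsFactors = FALSE)
  for (g in seq_len(nrow(grid))) {
    i <- grid$subject[g]; d <- grid$day[g]; rn <- grid$run[g]
    tk <- grid$task[g]
    cell_dir <- file.path(dir, sprintf("sub-%02d", i), sprintf("ses-%d", d),
                          sprintf("run-%d", rn))
    bold <- read_tsv(file.path(cell_dir, paste0("task-", tk, "_bold.tsv")))
    events <- read_events(
      file.path(cell_dir, paste0("task-", tk, "_events.tsv")),
      run_length = specs[[tk]]$run_length,
      conditions = specs[[tk]]$conditions)
    motion <- as.matrix(read_tsv(
      file.path(cell_dir, paste0("task-", tk, "_motion.tsv"))))
    if (ncol(motion) != 6L)
      stop_config("motion file must have exactly 6 columns")
    for (sr in cfg$seed_regions) {
      target_col <- if (paste0("target_", sr) %in% names(bold))
        paste0("target_", sr) else "target"
      recordings[[study_cell_key(i, d, rn, tk, sr)]] <- structure(
        list(seed = bold[[paste0("seed_", sr)]],
             target = bold[[target_col]],
             motion = motion, events = events, acq = acqs[[tk]],
             spec = specs[[tk]],
             meta = list(subject = i, day = d, run = rn, task = tk,
                         seed_region = sr)),
        class = "recording")
    }
  }
  structure(list(recordings = recordings, truth = truth, config = cfg,
                 master_seed = cfg$master_seed),
            class = "ppi_study")
}

#' Serialise a study configuration to YAML
#' @param config A [study_config()].
#' @param path Output path.
#' @export
write_study_config <- function(config, path) {
  lst <- unclass(config)
  lst$vc <- unclass(lst$vc)
  lst$accuracy <- as.list(lst$accuracy)
  if (!is.null(lst$exclusions)) lst$exclusions <- as.list(lst$exclusions)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a study configuration from YAML
#' @param path Path to a config.yaml.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  lst <- yaml::read_yaml(path)
  vc <- do.call(variance_components, lst$vc)
  excl <- if (!is.null(lst$exclusions))
    as.data.frame(lst$exclusions, stringsAsFactors = FALSE) else NULL
  study_config(n_subjects = lst$n_subjects, n_days = lst$n_days,
               n_runs = lst$n_runs, tasks = unlist(lst$tasks),
               seed_regions = unlist(lst$seed_regions), mu = lst$mu,
               vc = vc, noise = lst$noise %||% list(),
               accuracy = unlist(lst$accuracy), tr = lst$tr,
               exclusions = excl, non_responder = lst$non_responder,
               master_seed = lst$master_seed %||% 1L)
}
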