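# Task designs, event tables, HRF convolution and drift bases.

#' Task design specification
#'
#' Encodes the design of one of the three emotional face-processing tasks:
#' event-related emotion identification (`"EI"`, 60 face trials judged
#' happy/fearful/neutral over a 4:03 run), blocked face matching (`"FM"`,
#' five 30-s blocks -- three shape-matching, two face-matching -- over 5:55),
#' and blocked gender classification (`"GC"`, twelve 8-stimulus blocks over
#' 6:24). Any field can be overridden through `...` to define task variants;
#' overridden specs are re-validated for internal consistency.
#'
#' @param name One of `"EI"`, `"FM"`, `"GC"`.
#' @param ... Named overrides of spec fields (e.g. `run_length`,
#'   `stim_duration`, `iti_range`).
#' @return An object of class `task_spec`: a list with fields `name`,
#'   `design` (`"event-related"` or `"blocked"`), `run_length` (s),
#'   `conditions`, `contrast` (see [contrast_code()]), and design-specific
#'   timing fields.
#' @examples
#' sp <- task_spec("GC")
#' sp$n_blocks * sp$stimuli_per_block  # 96 stimulus events
#' @export
task_spec <- function(name = c("EI", "FM", "GC"), ...) {
  name <- match.arg(name)
  sp <- switch(name,
    EI = list(
      name = "EI", design = "event-related",
      run_length = 4 * 60 + 3,
      conditions = c("happy", "fearful", "neutral"),
      n_trials = 60L, stim_duration = 2,
      iti_range = c(0.5, 3.5),
      contrast = list(type = "faces_gt_fixation",
                      faces = c("happy", "fearful", "neutral"))),
    FM = list(
      name = "FM", design = "blocked",
      run_length = 5 * 60 + 55,
      conditions = c("faces", "shapes"),
      block_order = c("shapes", "faces", "shapes", "faces", "shapes"),
      trials_per_block = 6L, stim_duration = 5,
      contrast = list(type = "faces_gt_shapes",
                      faces = "faces", shapes = "shapes")),
    GC = list(
      name = "GC", design = "blocked",
      run_length = 6 * 60 + 24,
      conditions = c("happy", "fearful", "neutral"),
      n_blocks = 12L, stimuli_per_block = 8L, stim_duration = 2,
      contrast = list(type = "faces_gt_fixation",
                      faces = c("happy", "fearful", "neutral")))
  )
  dots <- list(...)
  for (nm in names(dots)) sp[[nm]] <- dots[[nm]]
  sp <- structure(sp, class = "task_spec")
  validate_task_spec(sp)
  sp
}

validate_task_spec <- function(sp) {
  stopifnot(inherits(sp, "task_spec"))
  if (sp$run_length <= 0) stop_config("run_length must be positive")
  stim_total <- switch(sp$name,
    EI = sp$n_trials * sp$stim_duration,
    FM = length(sp$block_order) * sp$trials_per_block * sp$stim_duration,
    GC = sp$n_blocks * sp$stimuli_per_block * sp$stim_duration,
    0)
  if (stim_total > sp$run_length) {
    stop_config("task '", sp$name, "': total stimulus time (", stim_total,
                " s) exceeds run length (", sp$run_length, " s)")
  }
  if (sp$name == "EI" && sp$design != "event-related")
    stop_config("EI must be event-related")
  if (sp$name == "FM") {
    tab <- table(sp$block_order)
    if (length(sp$block_order) != 5L || tab[["shapes"]] != 3L ||
        tab[["faces"]] != 2L)
      stop_config("FM must have 5 blocks: 3 shapes, 2 faces")
  }
  if (sp$name == "GC" && (sp$n_blocks != 12L || sp$stimuli_per_block != 8L))
    stop_config("GC must have 12 blocks of 8 stimuli")
  invisible(sp)
}

#' Acquisition parameters
#'
#' @param tr Repetition time in seconds (default 3.132 s).
#' @param scans Number of volumes; if missing, computed as
#'   `ceiling(run_length / tr)`.
#' @param dt Microtime resolution in seconds; must divide `tr` to within
#'   rounding. Defaults to `tr / 16`.
#' @param run_length Run length in seconds (used to derive `scans` and
#'   checked against `scans * tr`).
#' @return Object of class `acq_spec` with fields `tr`, `dt`, `scans`,
#'   `nbin` (microtime bins per scan) and `run_length`.
#' @export
acq_spec <- function(tr = 3.132, scans = NULL, dt = tr / 16,
                     run_length = NULL) {
  if (tr <= 0) stop_config("tr must be positive")
  if (dt <= 0) stop_config("dt must be positive")
  nbin <- round(tr / dt)
  if (abs(nbin * dt - tr) > 1e-6 * tr)
    stop_config("dt must divide tr to within rounding")
  if (is.null(scans)) {
    if (is.null(run_length)) stop_config("supply scans or run_length")
    scans <- as.integer(ceiling(run_length / tr))
  }
  scans <- as.integer(scans)
  if (!is.null(run_length) && scans * tr < run_length - 1e-9)
    stop_config("scans * tr must cover the run length")
  structure(list(tr = tr, dt = dt, scans = scans, nbin = as.integer(nbin),
                 run_length = run_length %||% (scans * tr)),
            class = "acq_spec")
}

#' Acquisition spec matched to a task
#'
#' Convenience constructor: number of scans is the smallest count covering
#' the task's run length at the given TR.
#' @param spec A [task_spec()].
#' @inheritParams acq_spec
#' @export
acq_for_task <- function(spec, tr = 3.132, dt = tr / 16) {
  acq_spec(tr = tr, dt = dt, run_length = spec$run_length)
}

new_event_table <- function(onset, duration, condition, correct, spec = NULL) {
  ev <- data.frame(onset = as.numeric(onset),
                   duration = as.numeric(duration),
                   condition = as.character(condition),
                   correct = as.logical(correct),
                   stringsAsFactors = FALSE)
  if (!is.null(spec)) {
    attr(ev, "conditions") <- spec$conditions
    attr(ev, "task") <- spec$name
    attr(ev, "run_length") <- spec$run_length
  }
  class(ev) <- c("event_table", "data.frame")
  validate_events(ev)
  ev
}

#' Validate an event table
#'
#' Checks the event-table invariants: strictly increasing onsets, positive
#' durations, events contained in the run, and condition labels drawn from
#' the declared condition set (when one is attached).
#' @param ev An `event_table`.
#' @return `ev`, invisibly; errors on violation.
#' @export
validate_events <- function(ev) {
  stopifnot(is.data.frame(ev))
  need <- c("onset", "duration", "condition", "correct")
  if (!all(need %in% names(ev)))
    stop_config("event table must have columns ", paste(need, collapse = ", "))
  if (nrow(ev) == 0L) return(invisible(ev))
  if (any(ev$onset < 0)) stop_config("onsets must be >= 0")
  if (any(diff(ev$onset) <= 0)) stop_config("onsets must be strictly increasing")
  if (any(ev$duration <= 0)) stop_config("durations must be positive")
  run_length <- attr(ev, "run_length")
  if (!is.null(run_length) &&
      any(ev$onset + ev$duration > run_length + 1e-6))
    stop_config("event extends past the end of the run")
  conds <- attr(ev, "conditions")
  if (!is.null(conds) && !all(ev$condition %in% conds))
    stop_config("condition labels outside the declared set: ",
                paste(setdiff(ev$condition, conds), collapse = ", "))
  invisible(ev)
}

#' Generate the event table for a task run
#'
#' Blocked designs (`FM`, `GC`) are fully deterministic given the spec:
#' block order, within-block stimulus timing and inter-block fixation are
#' laid out so that blocks are spread evenly over the run. The event-related
#' `EI` design shuffles the condition sequence (20 trials per emotion) and
#' draws uniformly jittered inter-trial intervals, rescaled so the 60 trials
#' exactly fill the run; both are reproducible from `rng_seed`.
#'
#' When `accuracy < 1`, each event's `correct` flag is drawn as a Bernoulli
#' variable with that probability (also from `rng_seed`).
#'
#' @param spec A [task_spec()].
#' @param rng_seed Integer seed for the jitter/order/accuracy draws;
#'   required for `EI` or when `accuracy < 1`.
#' @param accuracy Probability that a trial is answered correctly
#'   (default 1: all correct).
#' @return An `event_table` (data frame with columns `onset`, `duration`,
#'   `condition`, `correct`).
#' @export
make_task_events <- function(spec, rng_seed = NULL, accuracy = 1) {
  validate_task_spec(spec)
  stopifnot(accuracy >= 0, accuracy <= 1)
  if (is.null(rng_seed) && (spec$design == "event-related" || accuracy < 1))
    stop_config("rng_seed required for jittered designs or accuracy < 1")
  with_seed(rng_seed, {
    if (spec$design == "blocked") {
      ev <- blocked_events(spec)
    } else {
      ev <- event_related_events(spec)
    }
    correct <- if (accuracy < 1) {
      stats::runif(nrow(ev)) < accuracy
    } else rep(TRUE, nrow(ev))
    new_event_table(ev$onset, ev$duration, ev$condition, correct, spec)
  })
}

blocked_events <- function(spec) {
  if (spec$name == "FM") {
    blocks <- spec$block_order
    per_block <- spec$trials_per_block
  } else {
    # GC: four cycles of happy/fearful/neutral
    blocks <- rep(spec$conditions, length.out = spec$n_blocks)
    per_block <- spec$stimuli_per_block
  }
  block_len <- per_block * spec$stim_duration
  nb <- length(blocks)
  gap <- (spec$run_length - nb * block_len) / (nb + 1)
  onset <- numeric(0); cond <- character(0)
  t0 <- gap
  for (i in seq_len(nb)) {
    onset <- c(onset, t0 + (seq_len(per_block) - 1) * spec$stim_duration)
    cond <- c(cond, rep(blocks[i], per_block))
    t0 <- t0 + block_len + gap
  }
  data.frame(onset = onset, duration = spec$stim_duration, condition = cond)
}

event_related_events <- function(spec) {
  n <- spec$n_trials
  per_cond <- n / length(spec$conditions)
  if (per_cond != floor(per_cond))
    stop_config("EI trial count must divide evenly across conditions")
  cond <- sample(rep(spec$conditions, per_cond))
  # n + 1 fixation gaps (before each trial and after the last), jittered
  # uniformly then rescaled to fill the run exactly.
  free <- spec$run_length - n * spec$stim_duration
  if (free <= 0) stop_config("EI trials do not fit in the run")
  g <- stats::runif(n + 1L, spec$iti_range[1], spec$iti_range[2])
  g <- g * free / sum(g)
  onset <- cumsum(g)[seq_len(n)] + (seq_len(n) - 1L) * spec$stim_duration
  data.frame(onset = onset, duration = spec$stim_duration, condition = cond)
}

#' Canonical double-gamma haemodynamic response kernel
#'
#' Difference of two gamma densities (response peaking near 5 s minus a
#' scaled undershoot), sampled on a grid of step `dt` over `duration`
#' seconds and normalised to unit peak. The kernel is zero at `t = 0`.
#'
#' @param dt Sampling step in seconds (> 0).
#' @param peak_delay,peak_dispersion Gamma delay/dispersion of the positive
#'   lobe (defaults 6 and 1, i.e. shape 6, scale 1).
#' @param undershoot_delay,undershoot_dispersion Gamma delay/dispersion of
#'   the undershoot (defaults 16 and 1).
#' @param undershoot_ratio Relative undershoot amplitude (default 1/6).
#' @param duration Kernel length in seconds (default 32).
#' @return Numeric vector of kernel samples at `t = 0, dt, 2 dt, ...`.
#' @export
hrf_kernel <- function(dt, peak_delay = 6, peak_dispersion = 1,
                       undershoot_delay = 16, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6, duration = 32) {
  if (dt <= 0) stop_config("dt must be positive")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay / peak_dispersion,
                     scale = peak_dispersion) -
    undershoot_ratio *
      stats::dgamma(t, shape = undershoot_delay / undershoot_dispersion,
                    scale = undershoot_dispersion)
  h / max(h)
}

micro_grid_length <- function(acq) acq$scans * acq$nbin

scan_onset_index <- function(acq) (seq_len(acq$scans) - 1L) * acq$nbin + 1L

# Weighted microtime boxcar for an event table: `weights[condition]` during
# each event, 0 elsewhere.
micro_boxcar <- function(events, weights, acq) {
  n <- micro_grid_length(acq)
  x <- numeric(n)
  if (nrow(events) == 0L) return(x)
  present <- unique(events$condition)
  missing_w <- setdiff(present, names(weights))
  if (length(missing_w))
    stop_config("no weight defined for condition(s): ",
                paste(missing_w, collapse = ", "))
  eps <- 1e-9
  for (i in seq_len(nrow(events))) {
    w <- weights[[events$condition[i]]]
    if (w == 0) next
    # bin j spans [(j-1) dt, j dt); an event occupies the bins whose start
    # falls inside [onset, onset + duration), so abutting events tile
    # without overlap
    i0 <- ceiling(events$onset[i] / acq$dt - eps) + 1L
    i1 <- min(n, ceiling((events$onset[i] + events$duration[i]) / acq$dt - eps))
    if (i0 <= i1) x[i0:i1] <- x[i0:i1] + w
  }
  x
}

convolve_micro <- function(x, kernel, dt = 1) {
  # Linear (open) convolution truncated to the length of x; scaling by dt
  # approximates the continuous convolution integral, keeping regressor
  # amplitudes independent of the microtime resolution.
  n <- length(x)
  y <- stats::convolve(x, rev(kernel), type = "open")
  y[seq_len(n)] * dt
}

#' Convolve task events into a scan-resolution regressor
#'
#' Builds a microtime boxcar (each event contributes its condition weight
#' for its duration), convolves it with the double-gamma kernel sampled at
#' the microtime resolution, and samples the result at scan onsets.
#'
#' @param events An `event_table`.
#' @param weights Named numeric vector/list mapping condition labels to
#'   boxcar weights; every condition present in `events` must be covered.
#' @param acq An [acq_spec()].
#' @param kernel Optional pre-computed kernel (from [hrf_kernel()] at
#'   `acq$dt`); computed if missing.
#' @return Numeric vector of length `acq$scans`.
#' @export
convolve_to_scans <- function(events, weights, acq, kernel = NULL) {
  validate_events(events)
  kernel <- kernel %||% hrf_kernel(acq$dt)
  x <- micro_boxcar(events, weights, acq)
  convolve_micro(x, kernel, acq$dt)[scan_onset_index(acq)]
}

#' Centered psychological contrast code
#'
#' Encodes the task contrast as a microtime time course and mean-centers it
#' over the run: `faces > fixation` codes 1 during face events and 0
#' elsewhere; `faces > shapes` codes +1 during face blocks and -1 during
#' shape blocks. The centered code is the "psychological" factor entering
#' the PPI interaction term.
#'
#' @param events An `event_table`.
#' @param contrast Contrast specification: a list with `type`
#'   (`"faces_gt_fixation"` or `"faces_gt_shapes"`) and the condition labels
#'   it references (`faces`, and `shapes` for the latter). Usually taken
#'   from `task_spec(...)$contrast`.
#' @param acq An [acq_spec()].
#' @param at `"micro"` (default) returns the microtime code; `"scans"`
#'   samples at scan onsets before centering.
#' @return Mean-centered numeric vector (microtime grid or scans).
#' @export
contrast_code <- function(events, contrast, acq, at = c("micro", "scans")) {
  at <- match.arg(at)
  validate_events(events)
  declared <- attr(events, "conditions") %||% unique(events$condition)
  refs <- switch(contrast$type,
    faces_gt_fixation = contrast$faces,
    faces_gt_shapes = c(contrast$faces, contrast$shapes),
    stop_config("unknown contrast type: ", contrast$type))
  absent <- setdiff(refs, declared)
  if (length(absent))
    stop_config("contrast references absent condition(s): ",
                paste(absent, collapse = ", "))
  w <- switch(contrast$type,
    faces_gt_fixation = stats::setNames(rep(1, length(contrast$faces)),
                                        contrast$faces),
    faces_gt_shapes = c(stats::setNames(rep(1, length(contrast$faces)),
                                        contrast$faces),
                        stats::setNames(rep(-1, length(contrast$shapes)),
                                        contrast$shapes)))
  # conditions present but not referenced code as 0
  other <- setdiff(declared, names(w))
  if (length(other)) w <- c(w, stats::setNames(rep(0, length(other)), other))
  x <- micro_boxcar(events, w, acq)
  if (at == "scans") x <- x[scan_onset_index(acq)]
  x - mean(x)
}

#' Discrete-cosine high-pass drift basis
#'
#' Orthonormal DCT columns whose periods are shorter than `cutoff` seconds
#' are retained (the standard high-pass rule: `K = floor(2 * scans * tr /
#' cutoff)` columns). Returns a zero-column matrix when the cutoff is at or
#' beyond the run length.
#'
#' @param acq An [acq_spec()].
#' @param cutoff High-pass cutoff period in seconds (default 128); must
#'   exceed `2 * tr`.
#' @return `scans x K` matrix of orthonormal drift regressors.
#' @export
dct_highpass <- function(acq, cutoff = 128) {
  if (cutoff <= 2 * acq$tr)
    stop_config("cutoff must exceed 2 * tr")
  n <- acq$scans
  K <- floor(2 * n * acq$tr / cutoff)
  if (K < 1) return(matrix(numeric(0), nrow = n, ncol = 0))
  k <- seq_len(K)
  m <- outer(seq_len(n) - 1L, k,
             function(i, kk) sqrt(2 / n) * cos(pi * (2 * i + 1) * kk / (2 * n)))
  colnames(m) <- paste0("dct", k)
  m
}

#' Per-run regressor context for a task
#'
#' Pre-computes the regressors shared between the synthetic generator and
#' the PPI estimator for one event table: the HRF-convolved task regressor
#' `x` at scan resolution (all conditions of interest weighted 1), the
#' centered psychological contrast code at scan resolution and on the
#' microtime grid, and the kernel. Passing the same context to
#' [simulate_run()] and [fit_ppi_run()] makes the estimator exactly
#' conjugate to the generator and avoids recomputing convolutions in
#' Monte-Carlo loops.
#'
#' @param events An `event_table`.
#' @param spec The [task_spec()] the events were generated from.
#' @param acq An [acq_spec()].
#' @return Object of class `task_context`.
#' @export
task_context <- function(events, spec, acq) {
  kernel <- hrf_kernel(acq$dt)
  w <- stats::setNames(rep(1, length(spec$conditions)), spec$conditions)
  structure(list(
    events = events, spec = spec, acq = acq, kernel = kernel,
    x_scans = convolve_to_scans(events, w, acq, kernel),
    psy_scans = contrast_code(events, spec$contrast, acq, at = "scans"),
    psy_micro = contrast_code(events, spec$contrast, acq, at = "micro")
  ), class = "task_context")
}
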