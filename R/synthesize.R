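# Synthetic study generation: coupling coefficients with declared variance
# components, BOLD-level run simulation, and full study layouts.

#' Variance components of the coupling coefficient
#'
#' The per-cell interaction (PPI) coefficient is generated as
#' `b[i,d,r] = mu + u[i] + v[i,d] + w[i,d,r]` with independent Gaussian
#' components: `u` between-subject (variance `sigma_subject2`), `v`
#' subject-by-day (variance `sigma_day2`) and `w` residual run-level
#' (variance `sigma_run2`). The ratio of between-subject to total variance
#' fixes the true intraclass correlation of any battery cell (see
#' [true_icc()]), so reliability estimates can be checked against a known
#' truth.
#'
#' @param mu Mean interaction coupling (arbitrary units).
#' @param sigma_subject2,sigma_day2,sigma_run2 Non-negative variances of
#'   the three components.
#' @return Object of class `variance_components`.
#' @export
variance_components <- function(mu = 0.3, sigma_subject2 = 0.09,
                                sigma_day2 = 0.03, sigma_run2 = 0.045) {
  if (any(c(sigma_subject2, sigma_day2, sigma_run2) < 0))
    stop_config("variances must be non-negative")
  structure(list(mu = mu, sigma_subject2 = sigma_subject2,
                 sigma_day2 = sigma_day2, sigma_run2 = sigma_run2),
            class = "variance_components")
}

#' Draw true coupling coefficients for a study layout
#'
#' @param vc A [variance_components()] object.
#' @param n_subjects,n_days,n_runs Layout counts (all >= 1).
#' @param rng_seed Integer seed; the draw is reproducible.
#' @return Data frame (`beta_truth`) with columns `subject`, `day`, `run`,
#'   `b`.
#' @export
sample_coupling_betas <- function(vc, n_subjects, n_days = 2L, n_runs = 2L,
                                  rng_seed = NULL) {
  stopifnot(inherits(vc, "variance_components"),
            n_subjects >= 1, n_days >= 1, n_runs >= 1)
  with_seed(rng_seed, {
    u <- stats::rnorm(n_subjects, 0, sqrt(vc$sigma_subject2))
    v <- matrix(stats::rnorm(n_subjects * n_days, 0, sqrt(vc$sigma_day2)),
                n_subjects, n_days)
    grid <- expand.grid(run = seq_len(n_runs), day = seq_len(n_days),
                        subject = seq_len(n_subjects))[, 3:1]
    w <- stats::rnorm(nrow(grid), 0, sqrt(vc$sigma_run2))
    b <- vc$mu + u[grid$subject] + v[cbind(grid$subject, grid$day)] + w
    out <- data.frame(subject = grid$subject, day = grid$day, run = grid$run,
                      b = b)
    class(out) <- c("beta_truth", "data.frame")
    out
  })
}

#' Analytic (latent) intraclass correlation of a battery cell
#'
#' The true consistency ICC of the coupling coefficient implied by the
#' variance components, for one cell of the reliability battery:
#' \describe{
#'   \item{between-day, run-averaged}{`s2s / (s2s + s2d + s2r / n_runs_averaged)`}
#'   \item{between-day, single-run}{`s2s / (s2s + s2d + s2r)`}
#'   \item{within-day}{`(s2s + s2d) / (s2s + s2d + s2r)`}
#' }
#' with `s2s`, `s2d`, `s2r` the subject, day and run variances. This is the
#' latent single-measures ICC -- the value estimation would recover with no
#' measurement noise. `measures = "average"` applies the Spearman-Brown
#' step-up over the `k = 2` sessions entering the battery matrix,
#' `k * icc / (1 + (k - 1) * icc)`, matching the average-measures estimate.
#'
#' @param vc A [variance_components()] object.
#' @param scheme Battery cell: `"between_day_avg"`, `"between_day_single"`
#'   or `"within_day"`.
#' @param n_runs_averaged Number of runs averaged per day (between-day
#'   run-averaged scheme only; default 2).
#' @param measures `"single"` (latent formula) or `"average"`.
#' @param k Sessions per battery matrix (2 throughout the 2-day/2-run
#'   battery).
#' @return True ICC in (-Inf, 1].
#' @export
true_icc <- function(vc, scheme = c("between_day_avg", "between_day_single",
                                    "within_day"),
                     n_runs_averaged = 2L, measures = c("single", "average"),
                     k = 2L) {
  scheme <- match.arg(scheme)
  measures <- match.arg(measures)
  s2s <- vc$sigma_subject2; s2d <- vc$sigma_day2; s2r <- vc$sigma_run2
  if (s2s + s2d + s2r == 0)
    stop_config("true ICC undefined when all variance components are zero")
  icc <- switch(scheme,
    between_day_avg = s2s / (s2s + s2d + s2r / n_runs_averaged),
    between_day_single = s2s / (s2s + s2d + s2r),
    within_day = (s2s + s2d) / (s2s + s2d + s2r))
  if (measures == "average") icc <- k * icc / (1 + (k - 1) * icc)
  icc
}

#' Subject-level generative parameters
#'
#' Houses the per-subject coefficients of the BOLD generator: seed task
#' amplitude `a`, physiological seed-to-target coupling `lambda`, direct
#' task coupling `gamma`, baseline `beta0`, AR(1) coefficient `phi` and
#' innovation scales of the seed and target noise, motion random-walk step
#' size and the 6 motion nuisance coefficients `theta`.
#'
#' @param a Seed task-activation amplitude (0 gives a "non-responder" whose
#'   activation-thresholded seed mask comes up empty).
#' @param lambda Physiological coupling of target to seed.
#' @param gamma Direct task activation of the target.
#' @param beta0 Target baseline.
#' @param phi AR(1) coefficient of seed/target noise, `|phi| < 1`.
#' @param sigma_seed,sigma_target Stationary noise SDs (0 switches noise
#'   off).
#' @param motion_step SD of the motion random-walk increments.
#' @param theta Length-6 motion nuisance coefficients.
#' @return Object of class `subject_params`.
#' @export
subject_params <- function(a = 1, lambda = 0.5, gamma = 0.3, beta0 = 100,
                           phi = 0.3, sigma_seed = 0.5, sigma_target = 0.3,
                           motion_step = 0.02, theta = rep(0, 6)) {
  if (abs(phi) >= 1) stop_config("|phi| must be < 1")
  stopifnot(length(theta) == 6L, sigma_seed >= 0, sigma_target >= 0)
  structure(list(a = a, lambda = lambda, gamma = gamma, beta0 = beta0,
                 phi = phi, sigma_seed = sigma_seed,
                 sigma_target = sigma_target, motion_step = motion_step,
                 theta = theta),
            class = "subject_params")
}

# Draw per-subject parameters around population defaults.
draw_subject_params <- function(noise = list()) {
  d <- utils::modifyList(list(
    a_mean = 1, a_sd = 0.1, lambda_mean = 0.5, lambda_sd = 0.1,
    gamma_mean = 0.3, gamma_sd = 0.1, beta0 = 100, phi = 0.3,
    sigma_seed = 0.5, sigma_target = 0.3, motion_step = 0.02,
    theta_sd = 0.1), noise)
  subject_params(
    a = stats::rnorm(1, d$a_mean, d$a_sd),
    lambda = stats::rnorm(1, d$lambda_mean, d$lambda_sd),
    gamma = stats::rnorm(1, d$gamma_mean, d$gamma_sd),
    beta0 = d$beta0, phi = d$phi, sigma_seed = d$sigma_seed,
    sigma_target = d$sigma_target, motion_step = d$motion_step,
    theta = stats::rnorm(6, 0, d$theta_sd))
}

ar1_noise <- function(n, phi, sigma) {
  if (sigma == 0) return(numeric(n))
  innov_sd <- sigma * sqrt(1 - phi^2)
  e <- stats::rnorm(n, 0, innov_sd)
  if (phi == 0) return(e)
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

motion_walk <- function(scans, step) {
  m <- matrix(stats::rnorm(scans * 6L, 0, step), scans, 6L)
  m <- apply(m, 2, cumsum)
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' Simulate one subject-run recording
#'
#' Generates seed and target BOLD time courses at scan resolution:
#' \preformatted{
#'   seed(t)   = a * x(t) + AR1 noise
#'   target(t) = beta0 + lambda * seed(t) + gamma * x(t)
#'               + b * (seed(t) - mean(seed)) * psy(t)
#'               + motion(t)' theta + AR1 noise
#' }
#' where `x` is the HRF-convolved task regressor and `psy` the centered
#' psychological contrast code sampled at scans. The interaction is
#' injected at the BOLD level, conjugate to the default (`bold`-mode)
#' estimator; `neural = TRUE` instead forms the interaction on the
#' microtime neural boxcar before convolution (the deconvolution-style
#' generative model).
#'
#' @param sp A [subject_params()] object.
#' @param b True interaction (PPI) coefficient for this run.
#' @param events Event table for the run.
#' @param acq An [acq_spec()].
#' @param spec The [task_spec()]; may be omitted when `ctx` is given.
#' @param rng_seed Integer seed for the noise draws.
#' @param ctx Optional pre-computed [task_context()] (events/spec/acq are
#'   then taken from it).
#' @param neural Inject the interaction at the neural level instead of the
#'   BOLD level (default `FALSE`).
#' @return Object of class `recording`: list with `seed`, `target`
#'   (numeric, length scans), `motion` (scans x 6), `events`, `acq`,
#'   `spec`, and `meta`.
#' @export
simulate_run <- function(sp, b, events = NULL, acq = NULL, spec = NULL,
                         rng_seed = NULL, ctx = NULL, neural = FALSE) {
  if (is.null(ctx)) {
    stopifnot(!is.null(events), !is.null(acq), !is.null(spec))
    ctx <- task_context(events, spec, acq)
  }
  acq <- ctx$acq
  n <- acq$scans
  with_seed(rng_seed, {
    seed_tc <- sp$a * ctx$x_scans + ar1_noise(n, sp$phi, sp$sigma_seed)
    motion <- motion_walk(n, sp$motion_step)
    inter <- if (neural) {
      # neural-level: task boxcar x psy on the microtime grid, convolved
      w <- stats::setNames(rep(1, length(ctx$spec$conditions)),
                           ctx$spec$conditions)
      neu <- micro_boxcar(ctx$events, w, acq) * ctx$psy_micro
      convolve_micro(neu, ctx$kernel, acq$dt)[scan_onset_index(acq)]
    } else {
      (seed_tc - mean(seed_tc)) * ctx$psy_scans
    }
    target <- sp$beta0 + sp$lambda * seed_tc + sp$gamma * ctx$x_scans +
      b * inter + drop(motion %*% sp$theta) +
      ar1_noise(n, sp$phi, sp$sigma_target)
    structure(list(seed = seed_tc, target = target, motion = motion,
                   events = ctx$events, acq = acq, spec = ctx$spec,
                   meta = list(b = b, neural = neural)),
              class = "recording")
  })
}

#' Study configuration
#'
#' Assembles the full configuration of a synthetic reliability study:
#' layout (subjects x days x runs x tasks x seed regions), acquisition,
#' variance components, mean coupling per task/seed region, subject-level
#' noise parameters, behavioural accuracy per task, and optional exclusions
#' and a non-responding subject. The defaults emulate a 29-subject,
#' 2-day/2-run study over the three tasks, with mean couplings patterned so
#' the emotion-identification task shows a robust positive group PPI
#' effect, gender classification a negative amygdala effect with a null
#' sgACC, and face matching no effect (those seeds are gated out of the
#' reliability battery).
#'
#' @param n_subjects,n_days,n_runs Layout counts.
#' @param tasks Character vector of task names (subset of EI/FM/GC).
#' @param seed_regions Character vector of seed-region labels.
#' @param mu Named list `mu[[task]][[seed_region]]` of mean couplings;
#'   missing entries default to 0.
#' @param vc A [variance_components()] object (its `mu` field is ignored in
#'   favour of the per-task/seed `mu` table).
#' @param noise Named list overriding [draw_subject_params()] population
#'   defaults (e.g. `sigma_target`).
#' @param accuracy Named numeric vector of per-task response accuracies.
#' @param tr Repetition time (s).
#' @param exclusions Optional data frame with columns `subject`, `task`:
#'   those subject-task cells are flagged excluded (kept in the layout).
#' @param non_responder Integer subject id whose seed amplitude `a` is 0
#'   for all tasks (exercises the empty suprathreshold-seed path), or
#'   `NULL`.
#' @param master_seed Default master RNG seed (overridable in
#'   [simulate_study()]).
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_subjects = 29L, n_days = 2L, n_runs = 2L,
                         tasks = c("EI", "FM", "GC"),
                         seed_regions = c("lamyg", "ramyg", "sgacc"),
                         mu = NULL, vc = variance_components(),
                         noise = list(),
                         accuracy = c(EI = 0.91, FM = 1, GC = 0.94),
                         tr = 3.132, exclusions = NULL,
                         non_responder = NULL, master_seed = 1L) {
  if (n_subjects < 2) stop_config("need at least 2 subjects")
  if (anyDuplicated(seq_len(n_subjects))) stop_config("duplicate subjects")
  if (is.null(mu)) {
    full <- list(
      EI = list(lamyg = 0.35, ramyg = 0.30, sgacc = 0.35),
      FM = list(lamyg = 0, ramyg = 0, sgacc = 0),
      GC = list(lamyg = -0.25, ramyg = -0.25, sgacc = 0))
    mu <- lapply(stats::setNames(tasks, tasks), function(tk) {
      row <- full[[tk]] %||% list()
      lapply(stats::setNames(seed_regions, seed_regions),
             function(sr) row[[sr]] %||% 0)
    })
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_days = as.integer(n_days), n_runs = as.integer(n_runs),
                 tasks = tasks, seed_regions = seed_regions, mu = mu,
                 vc = vc, noise = noise, accuracy = accuracy, tr = tr,
                 exclusions = exclusions, non_responder = non_responder,
                 master_seed = as.integer(master_seed)),
            class = "study_config")
}

study_cell_key <- function(subject, day, run, task, seed_region) {
  sprintf("sub-%02d_ses-%d_run-%d_task-%s_seed-%s",
          subject, day, run, task, seed_region)
}

#' Simulate a complete reliability study
#'
#' Draws per-subject generative parameters once and reuses them across all
#' cells; draws the true coupling coefficients `b[i,d,r]` for every task x
#' seed-region channel from the configured variance components (centered on
#' the task/seed mean coupling); simulates every subject x day x run x task
#' x seed-region recording. Each seed region is an independent seed--target
#' channel, so each per-seed PPI estimate has an exact generative
#' counterpart. All randomness derives from per-cell substreams of the
#' master seed.
#'
#' @param config A [study_config()].
#' @param rng_seed Master seed (default `config$master_seed`).
#' @return Object of class `ppi_study`: list with `recordings` (named list
#'   of [simulate_run()] recordings keyed by cell), `truth` (data frame:
#'   `subject`, `task`, `seed`, `day`, `run`, `b`, `excluded`, `reason`),
#'   `config`, `master_seed`.
#' @export
simulate_study <- function(config = study_config(), rng_seed = NULL) {
  stopifnot(inherits(config, "study_config"))
  master <- as.integer(rng_seed %||% config$master_seed)
  specs <- lapply(stats::setNames(config$tasks, config$tasks), task_spec)
  acqs <- lapply(specs, acq_for_task, tr = config$tr)

  sps <- lapply(seq_len(config$n_subjects), function(i) {
    with_seed(seed_stream(master, paste0("subject/", i)),
              draw_subject_params(config$noise))
  })
  if (!is.null(config$non_responder)) {
    i <- config$non_responder
    sps[[i]]$a <- 0
  }

  vc0 <- config$vc
  truth <- NULL
  recordings <- list()
  for (tk in config$tasks) {
    spec <- specs[[tk]]; acq <- acqs[[tk]]
    acc <- unname(config$accuracy[tk]); if (is.na(acc)) acc <- 1
    # events (and hence regressors) are shared across seed-region channels
    ctx_cache <- new.env(parent = emptyenv())
    shared <- spec$design == "blocked" && acc >= 1  # identical event tables
    get_ctx <- function(i, d, rn) {
      ck <- if (shared) "shared" else paste(i, d, rn, sep = "/")
      if (is.null(ctx_cache[[ck]])) {
        ev_seed <- seed_stream(master,
                               paste0("events/", tk, "/", i, "/", d, "/", rn))
        events <- make_task_events(spec, rng_seed = ev_seed, accuracy = acc)
        ctx_cache[[ck]] <- task_context(events, spec, acq)
      }
      ctx_cache[[ck]]
    }
    for (sr in config$seed_regions) {
      vc <- variance_components(mu = config$mu[[tk]][[sr]],
                                sigma_subject2 = vc0$sigma_subject2,
                                sigma_day2 = vc0$sigma_day2,
                                sigma_run2 = vc0$sigma_run2)
      bt <- sample_coupling_betas(vc, config$n_subjects, config$n_days,
                                  config$n_runs,
                                  rng_seed = seed_stream(
                                    master, paste0("betas/", tk, "/", sr)))
      bt$task <- tk; bt$seed <- sr
      truth <- rbind(truth, bt[, c("subject", "task", "seed", "day", "run",
                                   "b")])
      for (r in seq_len(nrow(bt))) {
        i <- bt$subject[r]; d <- bt$day[r]; rn <- bt$run[r]
        key <- study_cell_key(i, d, rn, tk, sr)
        rec <- simulate_run(sps[[i]], bt$b[r], ctx = get_ctx(i, d, rn),
                            rng_seed = seed_stream(master,
                                                   paste0("noise/", key)))
        rec$meta <- c(rec$meta, list(subject = i, day = d, run = rn,
                                     task = tk, seed_region = sr))
        recordings[[key]] <- rec
      }
    }
  }
  truth$excluded <- FALSE
  truth$reason <- NA_character_
  if (!is.null(config$exclusions)) {
    for (r in seq_len(nrow(config$exclusions))) {
      hit <- truth$subject == config$exclusions$subject[r] &
        truth$task == config$exclusions$task[r]
      truth$excluded[hit] <- TRUE
      truth$reason[hit] <- "requested exclusion"
    }
  }
  structure(list(recordings = recordings, truth = truth, config = config,
                 master_seed = master),
            class = "ppi_study")
}
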