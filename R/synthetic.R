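#' Configuration for the synthetic BOLD generator
#'
#' Collects the acquisition constants of the emulated study (blocked
#' emotional-face task: 21 s blocks, 2 s trials, 1 s inter-trial interval,
#' 3 s cue, TR 0.72 s, 176 volumes per task session, two sessions; resting
#' state: two 1200-volume runs) together with the planted ground truth of the
#' simulation: modular resting covariance, per-module task activation, and
#' multiplicative task-by-seed connectivity effects on chosen directed edges.
#'
#' @param n_nodes Number of ROIs.
#' @param n_modules Number of planted modules.
#' @param module_sizes Integer vector summing to `n_nodes`.
#' @param within_module_corr Latent correlation inside modules, in \[0, 1).
#' @param between_module_corr Latent correlation between modules; must be
#'   smaller than `within_module_corr` so the planted structure is
#'   recoverable.
#' @param n_subjects Cohort size.
#' @param tr Repetition time in seconds.
#' @param rest_volumes_per_run Volumes per resting run (two runs are
#'   concatenated).
#' @param task_volumes_per_session Volumes per task session.
#' @param n_sessions Number of task sessions.
#' @param ppi_edges Data frame with columns `seed`, `target` (node indices),
#'   `condition`, `gamma` — the planted task-modulated directed edges.
#' @param ar_coefficient AR(1) parameter of the measurement noise, |.| < 1.
#' @param noise_sd Marginal standard deviation of the AR(1) noise (latent
#'   signals have unit variance, so this sets the noise floor).
#' @param drift_amplitude Standard deviation of the low-frequency drift.
#' @param motion_amplitude Standard deviation of the motion-like regressors.
#' @param activation_effects Length-`n_modules` vector of mean activation
#'   amplitudes for the emotion condition.
#' @param hrf [hrf_params()] used for generation.
#' @param seed Master seed of the cohort.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_nodes = 60, n_modules = 6,
                         module_sizes = rep(n_nodes / n_modules, n_modules),
                         within_module_corr = 0.5,
                         between_module_corr = 0,
                         n_subjects = 50,
                         tr = 0.72,
                         rest_volumes_per_run = 1200,
                         task_volumes_per_session = 176,
                         n_sessions = 2,
                         ppi_edges = NULL,
                         ar_coefficient = 0.3,
                         noise_sd = 0.3,
                         drift_amplitude = 0.2,
                         motion_amplitude = 0.5,
                         activation_effects = rep(0, n_modules),
                         hrf = hrf_params(),
                         seed = 1L) {
  module_sizes <- as.integer(module_sizes)
  if (sum(module_sizes) != n_nodes)
    stopf("module_sizes sum to %d, not n_nodes = %d", sum(module_sizes), n_nodes)
  if (length(module_sizes) != n_modules)
    stopf("module_sizes has %d entries for %d modules",
          length(module_sizes), n_modules)
  if (!(within_module_corr >= 0 && within_module_corr < 1))
    stopf("within_module_corr must lie in [0, 1)")
  if (within_module_corr <= between_module_corr)
    stopf("within_module_corr (%g) must exceed between_module_corr (%g)",
          within_module_corr, between_module_corr)
  if (abs(ar_coefficient) >= 1) stopf("|ar_coefficient| must be < 1")
  if (length(activation_effects) != n_modules)
    stopf("activation_effects must have one amplitude per module")
  if (!is.null(ppi_edges)) {
    ppi_edges <- as.data.frame(ppi_edges)
    need <- c("seed", "target", "condition", "gamma")
    if (!all(need %in% names(ppi_edges)))
      stopf("ppi_edges needs columns %s", paste(need, collapse = ", "))
    if (any(!is.finite(ppi_edges$gamma))) stopf("all gamma must be finite")
    if (any(ppi_edges$seed == ppi_edges$target))
      stopf("ppi_edges contain self-loops")
    if (any(ppi_edges$seed < 1 | ppi_edges$seed > n_nodes |
            ppi_edges$target < 1 | ppi_edges$target > n_nodes))
      stopf("ppi_edges reference nodes outside 1..%d", n_nodes)
  }
  structure(list(n_nodes = n_nodes, n_modules = n_modules,
                 module_sizes = module_sizes,
                 within_module_corr = within_module_corr,
                 between_module_corr = between_module_corr,
                 n_subjects = n_subjects, tr = tr,
                 rest_volumes_per_run = rest_volumes_per_run,
                 task_volumes_per_session = task_volumes_per_session,
                 n_sessions = n_sessions, ppi_edges = ppi_edges,
                 ar_coefficient = ar_coefficient, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 motion_amplitude = motion_amplitude,
                 activation_effects = activation_effects,
                 hrf = hrf, seed = as.integer(seed)),
            class = "synth_config")
}

#' Ground truth of a synthetic cohort
#'
#' @param cfg A [synth_config()].
#' @return List with the true partition (integer module labels), the planted
#'   directed signed PPI edge list, the sign of each module's activation and
#'   the generator seed.
#' @export
make_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  labels <- rep(seq_len(cfg$n_modules), cfg$module_sizes)
  structure(list(true_partition = labels,
                 true_ppi_edges = cfg$ppi_edges,
                 true_active_modules = sign(cfg$activation_effects),
                 generator_seed = cfg$seed),
            class = "ground_truth")
}

#' Blocked task design for the emotional-face paradigm
#'
#' Lays out alternating emotion and shape blocks. Each block consists of a
#' `cue_s` cue followed by matching trials and spans `block_s` seconds in
#' total; consecutive blocks are separated by `fix_s` of fixation. With the
#' HCP-style defaults (TR 0.72 s, 176 volumes, three 21 s blocks per
#' condition, no inter-block fixation) the design fills the 126.72 s session.
#'
#' @param tr Repetition time in seconds.
#' @param n_volumes Volumes per session.
#' @param block_s Block length in seconds (cue included).
#' @param trial_s,iti_s Trial duration and inter-trial interval (recorded for
#'   bookkeeping; trials are not modelled individually).
#' @param cue_s Cue duration at the start of each block.
#' @param fix_s Fixation gap between consecutive blocks.
#' @param blocks_per_condition Blocks per condition; 0 yields an empty
#'   (flagged) design.
#' @param first_condition Condition of the first block; sessions of a
#'   cohort counterbalance this so the session-averaged contrast is free of
#'   block-order artifacts (the final block's truncated response otherwise
#'   biases one condition).
#' @return A `task_design` data frame with columns `condition`, `onset`,
#'   `duration` and attributes `tr`, `n_volumes`, `cue_s`.
#' @export
generate_task_design <- function(tr = 0.72, n_volumes = 176, block_s = 21,
                                 trial_s = 2, iti_s = 1, cue_s = 3,
                                 fix_s = 0, blocks_per_condition = 3,
                                 first_condition = c("emotion", "shape")) {
  first_condition <- match.arg(first_condition)
  stopifnot(tr > 0, block_s > 0, trial_s > 0, iti_s >= 0, cue_s >= 0,
            fix_s >= 0, is_count(blocks_per_condition))
  scan_s <- n_volumes * tr
  if (blocks_per_condition == 0) {
    warnf("blocks_per_condition = 0: empty task design")
    d <- data.frame(condition = character(), onset = numeric(),
                    duration = numeric())
    return(structure(d, tr = tr, n_volumes = n_volumes, cue_s = cue_s,
                     empty = TRUE, class = c("task_design", "data.frame")))
  }
  n_blocks <- 2L * blocks_per_condition
  total_s <- n_blocks * block_s + (n_blocks - 1) * fix_s
  if (total_s > scan_s)
    stopf("design (%g s) exceeds scan duration (%g s) by %g s",
          total_s, scan_s, total_s - scan_s)
  onsets <- (seq_len(n_blocks) - 1) * (block_s + fix_s)
  pair <- if (first_condition == "emotion") c("emotion", "shape") else
    c("shape", "emotion")
  cond <- rep(pair, blocks_per_condition)
  d <- data.frame(condition = cond, onset = onsets, duration = block_s)
  structure(d, tr = tr, n_volumes = n_volumes, cue_s = cue_s,
            trial_s = trial_s, iti_s = iti_s,
            class = c("task_design", "data.frame"))
}

#' Condition boxcars sampled at the TR
#'
#' @param design A `task_design`.
#' @param n_volumes Number of volumes to sample (defaults to the design's).
#' @param cue_handling `"merge"` treats the cue as part of its block,
#'   `"ignore"` starts the block after the cue, `"separate"` adds a `cue`
#'   column.
#' @return T x (number of conditions) 0/1 matrix with condition names.
#' @export
condition_boxcar <- function(design, n_volumes = attr(design, "n_volumes"),
                             cue_handling = c("merge", "ignore", "separate")) {
  cue_handling <- match.arg(cue_handling)
  tr <- attr(design, "tr")
  cue_s <- attr(design, "cue_s")
  t <- (seq_len(n_volumes) - 1) * tr
  conds <- unique(design$condition)
  box <- matrix(0, n_volumes, length(conds), dimnames = list(NULL, conds))
  cue <- numeric(n_volumes)
  for (i in seq_len(nrow(design))) {
    on <- design$onset[i]; dur <- design$duration[i]
    if (cue_handling == "ignore") { on <- on + cue_s; dur <- dur - cue_s }
    if (cue_handling == "separate") {
      cue[t >= design$onset[i] & t < design$onset[i] + cue_s] <- 1
      on <- on + cue_s; dur <- dur - cue_s
    }
    box[t >= on & t < on + dur, design$condition[i]] <- 1
  }
  if (cue_handling == "separate") box <- cbind(box, cue = cue)
  box
}

# Block covariance of the latent neural signals (unit variance, planted
# within/between-module correlations). The HRF convolution amplifies the
# latents relative to the additive noise, so observed correlations sit
# within a few percent of the planted values.
latent_covariance <- function(cfg) {
  labels <- rep(seq_len(cfg$n_modules), cfg$module_sizes)
  sigma <- matrix(cfg$between_module_corr, cfg$n_nodes, cfg$n_nodes)
  for (m in seq_len(cfg$n_modules)) {
    idx <- which(labels == m)
    sigma[idx, idx] <- cfg$within_module_corr
  }
  diag(sigma) <- 1
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    stopf("implied latent covariance is not positive definite (min eigenvalue %.3g); reduce correlations or noise_sd",
          ev)
  sigma
}

# T x N draws: latent MVN rows (chol supplied), plus AR(1) noise and drift.
draw_noise <- function(cfg, n_time) {
  e <- matrix(stats::rnorm(n_time * cfg$n_nodes,
                           sd = cfg$noise_sd * sqrt(1 - cfg$ar_coefficient^2)),
              n_time, cfg$n_nodes)
  noise <- apply(e, 2, function(col)
    as.numeric(stats::filter(col, cfg$ar_coefficient, method = "recursive")))
  k <- min(3L, n_time - 1L)
  b <- dct_basis(n_time, k)
  coefs <- matrix(stats::rnorm(k * cfg$n_nodes), k, cfg$n_nodes)
  drift <- b %*% coefs
  drift <- sweep(drift, 2, apply(drift, 2, stats::sd) + 1e-12, "/") *
    cfg$drift_amplitude
  noise + drift
}

#' Generate resting ROI time series for one subject
#'
#' Latent neural signals are drawn from the block-structured covariance
#' (planted within/between-module correlations) and convolved with the HRF,
#' which gives them the low-pass spectral character of resting BOLD; AR(1)
#' measurement noise and low-frequency drift are added on top. Two runs are
#' generated independently and concatenated.
#'
#' @param cfg A [synth_config()].
#' @param subject_seed Integer seed for this subject.
#' @return A [roi_timeseries()] with two runs.
#' @export
generate_rest_timeseries <- function(cfg, subject_seed) {
  stopifnot(inherits(cfg, "synth_config"))
  ch <- chol(latent_covariance(cfg))
  with_seed(subject_seed, {
    runs <- lapply(1:2, function(r) {
      n_t <- cfg$rest_volumes_per_run
      latent <- matrix(stats::rnorm(n_t * cfg$n_nodes), n_t) %*% ch
      convolve_hrf(latent, cfg$hrf, cfg$tr) + draw_noise(cfg, n_t)
    })
    roi_timeseries(do.call(rbind, runs), cfg$tr,
                   rep(1:2, each = cfg$rest_volumes_per_run))
  })
}

#' Generate task ROI time series for one subject
#'
#' Neural-level signals are the block-covariance latents plus the module
#' activation amplitude times the emotion boxcar; each planted PPI edge
#' (seed, target, condition, gamma) adds `gamma * seed latent * condition
#' boxcar` to the target's neural signal. Neural signals are convolved with
#' the HRF, and AR(1) noise, drift and a small bleed of the motion-like
#' nuisance signals are added. One run per session. Block order is
#' counterbalanced across sessions (even sessions start with the other
#' condition) unless a list of per-session designs is supplied; an
#' uncounterbalanced order leaves the final, truncated block's response on
#' one condition only and biases the condition contrast.
#'
#' @param cfg A [synth_config()].
#' @param design A `task_design` for the first session, or a list with one
#'   design per session.
#' @param truth A [make_ground_truth()] object.
#' @param subject_seed Integer seed for this subject.
#' @return List of class `task_scan` with elements `ts` (a
#'   [roi_timeseries()], one run per session), `nuisance` (T x 6 motion-like
#'   table) and `designs` (per-session list).
#' @export
generate_task_timeseries <- function(cfg, design, truth, subject_seed) {
  stopifnot(inherits(cfg, "synth_config"))
  designs <- session_designs(design, cfg$n_sessions)
  edges <- truth$true_ppi_edges
  if (!is.null(edges) &&
      any(c(edges$seed, edges$target) < 1 | c(edges$seed, edges$target) > cfg$n_nodes))
    stopf("planted ppi edge references node outside 1..%d", cfg$n_nodes)
  n_t <- cfg$task_volumes_per_session
  ch <- chol(latent_covariance(cfg))
  labels <- truth$true_partition
  amp <- cfg$activation_effects[labels]
  with_seed(subject_seed, {
    sessions <- vector("list", cfg$n_sessions)
    motions <- vector("list", cfg$n_sessions)
    bleed <- matrix(stats::rnorm(6 * cfg$n_nodes, sd = 0.1), 6, cfg$n_nodes)
    for (s in seq_len(cfg$n_sessions)) {
      box <- condition_boxcar(designs[[s]], n_volumes = n_t,
                              cue_handling = "merge")
      latent <- matrix(stats::rnorm(n_t * cfg$n_nodes), n_t) %*% ch
      neural <- latent + outer(drop(box[, "emotion"]), amp)
      if (!is.null(edges) && nrow(edges) > 0) {
        for (i in seq_len(nrow(edges))) {
          bc <- box[, as.character(edges$condition[i])]
          neural[, edges$target[i]] <- neural[, edges$target[i]] +
            edges$gamma[i] * neural[, edges$seed[i]] * bc
        }
      }
      bold <- convolve_hrf(neural, cfg$hrf, cfg$tr)
      motion <- apply(matrix(stats::rnorm(n_t * 6), n_t), 2, cumsum)
      motion <- stats::filter(motion, rep(1 / 9, 9), sides = 2)
      motion[is.na(motion)] <- 0
      motion <- sweep(motion, 2, apply(motion, 2, stats::sd) + 1e-12, "/")
      sessions[[s]] <- bold + draw_noise(cfg, n_t) + motion %*% bleed
      motions[[s]] <- motion * cfg$motion_amplitude
    }
    ts <- roi_timeseries(do.call(rbind, sessions), cfg$tr,
                         rep(seq_len(cfg$n_sessions), each = n_t))
    structure(list(ts = ts, nuisance = do.call(rbind, motions),
                   designs = designs), class = "task_scan")
  })
}

# Expand a single first-session design into a counterbalanced per-session
# list (even sessions start with the other condition); pass lists through.
session_designs <- function(design, n_sessions) {
  if (is.list(design) && !inherits(design, "task_design")) {
    if (length(design) != n_sessions)
      stopf("need %d per-session designs, got %d", n_sessions, length(design))
    return(design)
  }
  stopifnot(inherits(design, "task_design"))
  first <- design$condition[1]
  other <- setdiff(unique(design$condition), first)[1]
  lapply(seq_len(n_sessions), function(s) {
    if (s %% 2 == 1) return(design)
    d2 <- design
    d2$condition <- rep(c(other, first), length.out = nrow(design))
    d2
  })
}

#' Simulate a full synthetic cohort
#'
#' Fans the master seed out into per-subject substreams and generates rest
#' and/or task scans for every subject, together with the ground truth.
#'
#' @param cfg A [synth_config()].
#' @param design A `task_design`; defaults to the HCP-style layout at the
#'   config's TR and session length.
#' @param what Which scans to generate: `"both"`, `"rest"` or `"task"`.
#' @return List with `cfg`, `truth`, `design`, and per-subject lists `rest`
#'   (of [roi_timeseries()]) and `task` (of `task_scan`).
#' @export
simulate_cohort <- function(cfg, design = NULL,
                            what = c("both", "rest", "task")) {
  what <- match.arg(what)
  truth <- make_ground_truth(cfg)
  if (is.null(design))
    design <- generate_task_design(tr = cfg$tr,
                                   n_volumes = cfg$task_volumes_per_session)
  rest <- task <- NULL
  if (what %in% c("both", "rest"))
    rest <- lapply(seq_len(cfg$n_subjects), function(i)
      generate_rest_timeseries(cfg, child_seed(cfg$seed, i)))
  if (what %in% c("both", "task"))
    task <- lapply(seq_len(cfg$n_subjects), function(i)
      generate_task_timeseries(cfg, design, truth,
                               child_seed(cfg$seed, 100000 + i)))
  list(cfg = cfg, truth = truth, design = design, rest = rest, task = task)
}
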