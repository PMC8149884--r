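#' Construct a task specification
#'
#' A task bundles the training conditions (input time courses), the target
#' constraints that define the loss, the per-gene initial-state policy and
#' the integration horizon.
#'
#' @param n_genes,n_inputs dimensions of the modelled system.
#' @param conditions list of `(N_T + 1) x n_inputs` input-course matrices,
#'   one per condition.
#' @param targets data.frame with columns `condition` (1-based), `step`
#'   (0-based time index, 0 = initial state), `gene` (1-based) and `value`
#'   in `[0, 1]`.
#' @param initial_policy list with `trainable` (logical per gene) and
#'   `value` (numeric per gene; used for non-trainable genes).
#' @param N_T horizon (number of Euler steps).
#' @param dt time step.
#' @param meta optional named list of task metadata (task kind, stimulus
#'   onset step, pre-stimulus level, ...), used by [phenotype_metrics()].
#' @return A validated `task_spec` object.
#' @export
task_spec <- function(n_genes, n_inputs, conditions, targets,
                      initial_policy, N_T, dt = 0.2, meta = list()) {
  stopifnot(n_genes >= 1, n_inputs >= 0, N_T >= 1, dt > 0)
  conditions <- lapply(conditions, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != N_T + 1 || ncol(m) != n_inputs) {
      stop("each condition must be an (N_T + 1) x n_inputs matrix",
           call. = FALSE)
    }
    m
  })
  targets <- as.data.frame(targets)
  stopifnot(all(c("condition", "step", "gene", "value") %in% names(targets)))
  if (nrow(targets) == 0) stop("at least one target constraint is required",
                               call. = FALSE)
  if (any(targets$value < 0 | targets$value > 1)) {
    stop("target values must lie in [0, 1]", call. = FALSE)
  }
  if (any(targets$condition < 1 | targets$condition > length(conditions)) ||
      any(targets$step < 0 | targets$step > N_T) ||
      any(targets$gene < 1 | targets$gene > n_genes)) {
    stop("target indices out of bounds", call. = FALSE)
  }
  stopifnot(length(initial_policy$trainable) == n_genes,
            length(initial_policy$value) == n_genes)
  structure(list(n_genes = n_genes, n_inputs = n_inputs,
                 conditions = conditions, targets = targets,
                 initial_policy = initial_policy, N_T = N_T, dt = dt,
                 meta = meta),
            class = "task_spec")
}

#' @exportS3Method base::print
print.task_spec <- function(x, ...) {
  cat(sprintf(
    "<task_spec%s: %d genes, %d inputs, %d condition%s, %d targets, N_T = %d>\n",
    if (!is.null(x$meta$kind)) paste0(" [", x$meta$kind, "]") else "",
    x$n_genes, x$n_inputs, length(x$conditions),
    if (length(x$conditions) == 1) "" else "s", nrow(x$targets), x$N_T))
  invisible(x)
}

# peak time and unit-peak normaliser of exp(-t/tau_slow) - exp(-t/tau_fast)
pulse_peak <- function(tau_fast, tau_slow) {
  t_star <- (log(tau_slow) - log(tau_fast)) / (1 / tau_fast - 1 / tau_slow)
  list(t_star = t_star,
       height = exp(-t_star / tau_slow) - exp(-t_star / tau_fast))
}

#' Adaptation task: pulse-like response returning to the pre-stimulus level
#'
#' The output gene `g1` starts at `pre_level`, and after a step increase of
#' the input its target course is `pre_level` plus a difference of two
#' exponentials (fast rise, slow recovery), returning to `pre_level`.
#' One condition is created per combination of input step height and
#' onset time (plus one no-stimulus condition with a flat target when the
#' levels include 0).  The pulse amplitude scales proportionally with the
#' step height.  Training jointly on several heights and onsets is what
#' makes the solution identifiable as genuine input-driven adaptation: a
#' single fixed condition can also be fitted by an input-independent
#' internal transient ("clock") aligned with the known onset, and by
#' non-monotonic single-height tricks; no such degenerate solution fits
#' several onsets and heights at once.  `g2` is unconstrained with a
#' trainable initial value; `g1`'s initial value is fixed at `pre_level`.
#'
#' @param pre_level pre-stimulus target level of `g1`.
#' @param input_levels step heights of the input; a 0 entry adds the
#'   no-stimulus condition.
#' @param pulse_amplitude peak deviation of the target pulse for the
#'   largest input level.
#' @param tau_fast,tau_slow rise and recovery time constants in time units
#'   (`0 < tau_fast < tau_slow`; the defaults, 2 and 8 steps of `dt = 0.2`,
#'   let the pulse decay to ~2% of its peak within the horizon).
#' @param N_T,dt horizon and time step.
#' @param onset_steps 0-based steps at which the input may turn on; one
#'   condition per (level, onset) pair.  Early onsets leave the
#'   post-stimulus horizon room for the full pulse decay.
#' @return A `task_spec` with `meta$kind == "adaptation"`.  The condition
#'   with the largest level and earliest onset is recorded as
#'   `meta$phenotype_condition` for [phenotype_metrics()].
#' @export
make_adaptation_task <- function(pre_level = 0.4,
                                 input_levels = c(0, 0.2, 0.4, 0.6, 0.8),
                                 pulse_amplitude = 0.5,
                                 tau_fast = 0.4, tau_slow = 1.6,
                                 N_T = 40, dt = 0.2,
                                 onset_steps = c(5, 10, 15)) {
  stopifnot(tau_fast > 0, tau_fast < tau_slow, length(input_levels) >= 1,
            all(onset_steps >= 0 & onset_steps < N_T))
  if (pre_level + pulse_amplitude > 1 || pre_level < 0) {
    stop("target pulse exceeds [0, 1]: pre_level + pulse_amplitude must be <= 1",
         call. = FALSE)
  }
  pk <- pulse_peak(tau_fast, tau_slow)
  steps <- 0:N_T
  grid <- expand.grid(onset = sort(onset_steps),
                      level = sort(input_levels))
  grid <- grid[!(grid$level == 0 & duplicated(grid$level)), ]
  conditions <- list()
  targets <- NULL
  for (r in seq_len(nrow(grid))) {
    lev <- grid$level[r]
    onset <- grid$onset[r]
    c_idx <- length(conditions) + 1L
    conditions[[c_idx]] <- matrix(ifelse(steps >= onset, lev, 0), ncol = 1)
    amp <- pulse_amplitude * lev / max(input_levels)
    tt <- pmax(0, (steps - onset) * dt)
    tgt <- pre_level + ifelse(steps > onset,
                              amp / pk$height *
                                (exp(-tt / tau_slow) - exp(-tt / tau_fast)),
                              0)
    targets <- rbind(targets,
                     data.frame(condition = c_idx, step = steps[-1],
                                gene = 1L, value = tgt[-1]))
  }
  phen_cond <- length(conditions) - length(onset_steps) + 1L
  task_spec(n_genes = 2L, n_inputs = 1L, conditions = conditions,
            targets = targets,
            initial_policy = list(trainable = c(FALSE, TRUE),
                                  value = c(pre_level, 0.5)),
            N_T = N_T, dt = dt,
            meta = list(kind = "adaptation",
                        onset_step = min(onset_steps),
                        phenotype_condition = phen_cond,
                        pre_level = pre_level, output_gene = 1L,
                        input_levels = input_levels,
                        onset_steps = sort(onset_steps),
                        tau_fast = tau_fast, tau_slow = tau_slow,
                        pulse_amplitude = pulse_amplitude))
}

# triangular wave over steps: value at step s, period P steps
triangle_wave <- function(s, period, lo, hi) {
  u <- s %% period
  frac <- ifelse(u <= period / 2, u / (period / 2), (period - u) / (period / 2))
  lo + (hi - lo) * frac
}

#' Controlled-oscillation task: oscillate under one input, settle under the
#' other
#'
#' Three conditions constrain the output gene `g1`: with no input it stays
#' at a low basal level; under `I1 = 0.8` it follows a triangular wave
#' between `osc_min` and `osc_max`; under `I2 = 0.8` it rises to
#' `high_level` and holds.  Only `g1` is constrained; its initial value is
#' fixed at `low_level` while the other genes' initial values are
#' trainable.
#'
#' @param low_level basal level (also `g1`'s fixed initial value).
#' @param high_level sustained level under `I2`.
#' @param osc_min,osc_max oscillation range under `I1`.
#' @param period oscillation period in steps (>= 2).
#' @param n_genes number of genes (2 for the minimal setting, 3 for sparse
#'   three-node searches).
#' @param input_level amplitude of the active input.
#' @param rise_steps steps over which the `I2` target ramps up.
#' @param N_T,dt horizon and time step.
#' @return A `task_spec` with `meta$kind == "controlled_oscillation"`.
#' @export
make_controlled_oscillation_task <- function(low_level = 0.1,
                                             high_level = 0.8,
                                             osc_min = 0.2, osc_max = 0.8,
                                             period = 20, n_genes = 2L,
                                             input_level = 0.8,
                                             rise_steps = 10,
                                             N_T = 60, dt = 0.2) {
  if (period < 2) stop("`period` must be at least 2 steps", call. = FALSE)
  stopifnot(low_level >= 0, low_level < high_level, high_level <= 1,
            osc_min >= 0, osc_min < osc_max, osc_max <= 1, n_genes >= 2)
  steps <- 0:N_T
  zero <- matrix(0, N_T + 1, 2)
  c1 <- zero
  c2 <- zero; c2[, 1] <- input_level
  c3 <- zero; c3[, 2] <- input_level
  tri <- triangle_wave(steps, period, osc_min, osc_max)
  ramp <- low_level + (high_level - low_level) * pmin(1, steps / rise_steps)
  targets <- rbind(
    data.frame(condition = 1L, step = steps[-1], gene = 1L, value = low_level),
    data.frame(condition = 2L, step = steps[-1], gene = 1L, value = tri[-1]),
    data.frame(condition = 3L, step = steps[-1], gene = 1L, value = ramp[-1]))
  task_spec(n_genes = n_genes, n_inputs = 2L,
            conditions = list(c1, c2, c3), targets = targets,
            initial_policy = list(trainable = c(FALSE, rep(TRUE, n_genes - 1)),
                                  value = c(low_level, rep(0.5, n_genes - 1))),
            N_T = N_T, dt = dt,
            meta = list(kind = "controlled_oscillation",
                        low_level = low_level, high_level = high_level,
                        osc_min = osc_min, osc_max = osc_max,
                        period = period, input_level = input_level,
                        output_gene = 1L))
}

#' Synthetic morphogen and gap-gene target profiles
#'
#' Generates a stand-in for anterior-posterior expression profiles of the
#' Drosophila trunk patterning system: a Bicoid-like exponential gradient
#' (strictly decreasing head to tail), a Torso-like terminal signal
#' (elevated at both ends of the axis) and four band-like target gene
#' profiles (`hb`, `Kr`, `kni`, `gt`) with distinct, ordered peak
#' positions.  All values lie in `[0, 1]` and are reproducible from the
#' seed.  This is synthetic data: it emulates the shapes of the real
#' profiles, not their measured values.
#'
#' @param n_positions number of positions along the axis (>= 10).
#' @param seed integer seed (jitters peak positions and widths slightly).
#' @return List with `x` (positions in `[0, 1]`), `morphogens`
#'   (`n_positions x 2`, columns `Bcd`, `Tor`) and `targets`
#'   (`n_positions x 4`, columns `hb`, `Kr`, `kni`, `gt`).
#' @export
synth_gap_gene_profiles <- function(n_positions = 40, seed = 1) {
  stopifnot(n_positions >= 10)
  x <- seq(0, 1, length.out = n_positions)
  with_local_seed(seed, {
    bcd <- exp(-x / 0.25)
    bcd <- 0.02 + 0.96 * (bcd - min(bcd)) / (max(bcd) - min(bcd))
    tor <- exp(-x / 0.07) + exp(-(1 - x) / 0.07)
    tor <- pmin(1, 0.02 + 0.9 * tor / max(tor))
    centers <- c(0.18, 0.42, 0.6, 0.78) + rnorm(4, 0, 0.015)
    widths <- c(0.12, 0.08, 0.07, 0.08) * exp(rnorm(4, 0, 0.05))
    tg <- vapply(1:4, function(k) {
      0.03 + 0.9 * exp(-((x - centers[k])^2) / (2 * widths[k]^2))
    }, numeric(n_positions))
    colnames(tg) <- c("hb", "Kr", "kni", "gt")
    morph <- cbind(Bcd = bcd, Tor = tor)
    list(x = x, morphogens = morph, targets = tg)
  })
}

#' Gap-gene patterning tasks, one per spatial position
#'
#' Each position is an independent dynamical system (no spatial coupling):
#' its two static morphogen levels act as constant inputs, all four gap
#' genes start at zero (pre-zygotic state), and the only constraints are
#' the four target expression levels at the final time point.  Use
#' [merge_task_list()] to train one shared synthesis function across all
#' positions jointly.
#'
#' @param profiles output of [synth_gap_gene_profiles()] (or any list with
#'   `morphogens` and `targets` matrices of matching row count).
#' @param N_T,dt horizon and time step.
#' @return List of `task_spec` objects, one per position.
#' @export
make_gap_gene_task <- function(profiles, N_T = 30, dt = 0.2) {
  m <- as.matrix(profiles$morphogens)
  tg <- as.matrix(profiles$targets)
  stopifnot(nrow(m) == nrow(tg), ncol(m) == 2, ncol(tg) == 4)
  lapply(seq_len(nrow(m)), function(p) {
    cond <- matrix(rep(m[p, ], each = N_T + 1), N_T + 1, 2)
    task_spec(n_genes = 4L, n_inputs = 2L, conditions = list(cond),
              targets = data.frame(condition = 1L, step = N_T,
                                   gene = 1:4, value = as.numeric(tg[p, ])),
              initial_policy = list(trainable = rep(FALSE, 4),
                                    value = rep(0, 4)),
              N_T = N_T, dt = dt,
              meta = list(kind = "gap_gene", position = p,
                          morphogens = as.numeric(m[p, ])))
  })
}

#' Merge single-condition tasks into one multi-condition task
#'
#' The tasks must agree in dimensions, horizon, time step and
#' initial-state policy; their conditions and targets are concatenated.
#'
#' @param tasks list of `task_spec` objects.
#' @return One `task_spec`.
#' @export
merge_task_list <- function(tasks) {
  stopifnot(length(tasks) >= 1)
  t1 <- tasks[[1]]
  conditions <- list()
  targets <- NULL
  for (tk in tasks) {
    stopifnot(tk$n_genes == t1$n_genes, tk$n_inputs == t1$n_inputs,
              tk$N_T == t1$N_T, tk$dt == t1$dt,
              identical(tk$initial_policy, t1$initial_policy))
    off <- length(conditions)
    conditions <- c(conditions, tk$conditions)
    tg <- tk$targets
    tg$condition <- tg$condition + off
    targets <- rbind(targets, tg)
  }
  task_spec(t1$n_genes, t1$n_inputs, conditions, targets,
            t1$initial_policy, t1$N_T, t1$dt,
            meta = c(t1$meta["kind"], list(merged_from = length(tasks))))
}

#' Task loss: pooled Euclidean distance to the target constraints
#'
#' The loss is the square root of the sum of squared deviations over all
#' target constraints, pooled across conditions, and is zero exactly when
#' every constraint is met.
#'
#' @param trajectories list of `trajectory` objects, one per condition of
#'   the task (a single `trajectory` is accepted for one-condition tasks).
#' @param task a `task_spec`.
#' @return Non-negative scalar loss.
#' @export
task_loss <- function(trajectories, task) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  if (length(trajectories) < length(task$conditions)) {
    stop("one trajectory per task condition is required", call. = FALSE)
  }
  s <- 0
  for (k in seq_len(nrow(task$targets))) {
    tg <- task$targets[k, ]
    tr <- trajectories[[tg$condition]]
    if (nrow(tr$values) != task$N_T + 1) {
      stop("trajectory horizon does not match the task", call. = FALSE)
    }
    s <- s + (tr$values[tg$step + 1L, tg$gene] - tg$value)^2
  }
  sqrt(s)
}

#' Phenotype metrics of a trajectory
#'
#' For step-stimulus (adaptation-style) tasks: sensitivity is the peak
#' absolute deviation of the output gene from its pre-stimulus level after
#' stimulus onset, and the adaptation error is the absolute deviation at
#' the end of the run.  Oscillation amplitude and period are estimated by
#' peak detection on the second half of the trajectory.
#'
#' @param traj a `trajectory`.
#' @param task a `task_spec` whose `meta` provides `output_gene`,
#'   `pre_level` (or `low_level`) and optionally `onset_step`.
#' @param onset_step override for the stimulus onset step.
#' @param pre_level override for the pre-stimulus reference level.
#' @return A `phenotype_metrics` object: list with `sensitivity`,
#'   `adaptation_error`, `steady_level`, `oscillation_amplitude`,
#'   `oscillation_period`.
#' @export
phenotype_metrics <- function(traj, task, onset_step = NULL,
                              pre_level = NULL) {
  out_gene <- task$meta$output_gene %||% 1L
  onset <- onset_step %||% task$meta$onset_step %||% 0L
  pre <- pre_level %||% task$meta$pre_level %||% task$meta$low_level %||%
    traj$values[1, out_gene]
  n_steps <- nrow(traj$values) - 1L
  if (onset >= n_steps) stop("no post-stimulus samples", call. = FALSE)
  g <- traj$values[, out_gene]
  post <- g[(onset + 2L):(n_steps + 1L)]    # strictly after onset
  sensitivity <- max(abs(post - pre))
  adaptation_error <- abs(g[n_steps + 1L] - pre)
  steady_level <- g[n_steps + 1L]
  win <- g[(floor(n_steps / 2) + 1L):(n_steps + 1L)]
  pk <- find_peaks(win)
  amplitude <- if (length(win)) max(win) - min(win) else 0
  period <- if (length(pk) >= 2) mean(diff(pk)) * traj$dt else NA_real_
  structure(list(sensitivity = sensitivity,
                 adaptation_error = adaptation_error,
                 steady_level = steady_level,
                 oscillation_amplitude = amplitude,
                 oscillation_period = period),
            class = "phenotype_metrics")
}

#' @exportS3Method base::print
print.phenotype_metrics <- function(x, ...) {
  cat(sprintf(
    "<phenotype: sensitivity %.3f, adaptation error %.3f, steady %.3f, osc amp %.3f>\n",
    x$sensitivity, x$adaptation_error, x$steady_level,
    x$oscillation_amplitude))
  invisible(x)
}

# indices of strict local maxima of a numeric series
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

#' Save / load a task specification (YAML)
#'
#' Conditions are stored as arrays, targets as records and the initial
#' policy as a per-gene map; round-trips losslessly up to numeric
#' precision.
#'
#' @param task a `task_spec`.
#' @param path file path (`.yaml`).
#' @return `path` invisibly for save; the restored `task_spec` for load.
#' @export
save_task <- function(task, path) {
  obj <- list(
    n_genes = task$n_genes, n_inputs = task$n_inputs,
    N_T = task$N_T, dt = task$dt,
    conditions = lapply(task$conditions, function(m)
      apply(m, 1, function(r) as.numeric(r), simplify = FALSE)),
    targets = lapply(seq_len(nrow(task$targets)), function(k)
      as.list(task$targets[k, ])),
    initial_policy = lapply(seq_len(task$n_genes), function(j)
      list(trainable = task$initial_policy$trainable[j],
           value = task$initial_policy$value[j])),
    meta = task$meta)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname save_task
#' @export
load_task <- function(path) {
  obj <- yaml::read_yaml(path)
  conditions <- lapply(obj$conditions, function(cond)
    do.call(rbind, lapply(cond, as.numeric)))
  targets <- do.call(rbind, lapply(obj$targets, function(tg)
    data.frame(condition = tg$condition, step = tg$step,
               gene = tg$gene, value = tg$value)))
  initial_policy <- list(
    trainable = vapply(obj$initial_policy, function(p) p$trainable, logical(1)),
    value = vapply(obj$initial_policy, function(p) p$value, numeric(1)))
  task_spec(obj$n_genes, obj$n_inputs, conditions, targets,
            initial_policy, obj$N_T, obj$dt, meta = obj$meta %||% list())
}
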