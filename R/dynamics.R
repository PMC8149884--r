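#' One forward-Euler update of the gene dynamics
#'
#' Applies the discrete-time update
#' \eqn{g(t + dt) = (1 - \gamma\,dt)\,g(t) + f\,dt} elementwise.  With
#' synthesis rates bounded in \eqn{[0, 1]}, \eqn{\gamma\,dt \le 1} and
#' states starting in \eqn{[0, 1]}, the update keeps states in
#' \eqn{[0, 1]}.
#'
#' @param g numeric vector of current gene levels.
#' @param f_value numeric vector of synthesis rates, same length as `g`.
#' @param gamma non-negative decay rate (default 1).
#' @param dt positive time step (default 0.2).
#' @return Updated gene-level vector.
#' @export
#' @examples
#' euler_step(0, 1)          # 0.2
#' euler_step(0.7, 0.7)      # fixed point f / gamma
euler_step <- function(g, f_value, gamma = 1, dt = 0.2) {
  if (length(g) != length(f_value)) {
    stop("`g` and `f_value` must have the same length", call. = FALSE)
  }
  stopifnot(dt > 0, gamma >= 0)
  (1 - gamma * dt) * g + f_value * dt
}

#' Simulate the gene dynamics with a pluggable synthesis function
#'
#' Iterates [euler_step()] for `n_steps` steps.  Inputs are held
#' piecewise-constant over each step (the value at the step's left
#' endpoint is used).  Optional Gaussian state noise is added after each
#' update and the state is clipped at zero, a simple Langevin-style
#' perturbation.
#'
#' @param synth a synthesis function: an object created by
#'   [build_synthesis()] or [hill_model()], or a plain R function
#'   `function(g, I)` returning a synthesis-rate vector.
#' @param g0 initial gene levels in `[0, 1]`.
#' @param input_course matrix with `n_steps + 1` rows of input values, or a
#'   single vector of constant input levels (broadcast over time).
#' @param n_steps number of Euler steps (>= 1).
#' @param gamma,dt decay rate and time step.
#' @param noise_sd standard deviation of the additive state noise
#'   (0 = deterministic).
#' @param seed integer seed used when `noise_sd > 0`; identical seeds and
#'   inputs give identical trajectories.
#' @return A `trajectory` object: list with `values`
#'   (`(n_steps + 1) x n_genes` matrix, row 1 = `g0`), `inputs`
#'   (`(n_steps + 1) x n_inputs`), `dt`, `gamma`, `noise_sd`, `seed`.
#' @export
simulate_dynamics <- function(synth, g0, input_course, n_steps,
                              gamma = 1, dt = 0.2, noise_sd = 0,
                              seed = NULL) {
  if (n_steps < 1) stop("`n_steps` must be at least 1", call. = FALSE)
  stopifnot(noise_sd >= 0)
  n_genes <- length(g0)
  if (is.null(dim(input_course))) {
    input_course <- matrix(input_course, nrow = n_steps + 1,
                           ncol = length(input_course), byrow = TRUE)
  }
  input_course <- as.matrix(input_course)
  if (nrow(input_course) != n_steps + 1) {
    stop("`input_course` must have n_steps + 1 rows", call. = FALSE)
  }
  values <- matrix(NA_real_, n_steps + 1, n_genes)
  values[1, ] <- g0
  step_fun <- function() {
    g <- g0
    for (t in seq_len(n_steps)) {
      f <- synth_eval(synth, g, input_course[t, ])
      g <- euler_step(g, f, gamma = gamma, dt = dt)
      if (noise_sd > 0) {
        g <- pmax(g + rnorm(n_genes, 0, noise_sd), 0)
      }
      values[t + 1, ] <<- g
    }
  }
  if (noise_sd > 0 && !is.null(seed)) with_local_seed(seed, step_fun())
  else step_fun()
  trajectory(values, input_course, dt = dt, gamma = gamma,
             noise_sd = noise_sd, seed = seed)
}

#' Construct a trajectory object
#'
#' @param values `(T + 1) x n_genes` matrix of gene levels; row 1 is the
#'   initial condition.
#' @param inputs `(T + 1) x n_inputs` matrix of the input course that
#'   produced the trajectory.
#' @param dt time step; `gamma`, `noise_sd`, `seed` are provenance
#'   metadata.
#' @param gamma decay rate used.
#' @param noise_sd,seed noise provenance.
#' @return A `trajectory` object.
#' @export
trajectory <- function(values, inputs, dt = 0.2, gamma = 1,
                       noise_sd = 0, seed = NULL) {
  values <- as.matrix(values)
  inputs <- as.matrix(inputs)
  stopifnot(nrow(values) == nrow(inputs))
  structure(list(values = values, inputs = inputs, dt = dt, gamma = gamma,
                 noise_sd = noise_sd, seed = seed),
            class = "trajectory")
}

#' @exportS3Method base::print
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d steps, %d genes, %d inputs, dt = %g>\n",
              nrow(x$values) - 1L, ncol(x$values), ncol(x$inputs), x$dt))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  n <- nrow(x$values)
  g <- x$values
  colnames(g) <- paste0("g_", seq_len(ncol(g)))
  i <- x$inputs
  colnames(i) <- paste0("I_", seq_len(ncol(i)))
  data.frame(step = seq_len(n) - 1L, time = (seq_len(n) - 1L) * x$dt, g, i)
}

#' Write a trajectory to a tab-separated file
#'
#' Columns: `step`, `time`, `g_1..g_n`, `I_1..I_m`.
#'
#' @param traj a `trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  df <- as.data.frame(traj)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_tsv()]
#'
#' @param path file path.
#' @param dt time step recorded with the trajectory (the file stores the
#'   time column; `dt` is inferred from it when `NULL`).
#' @return A `trajectory`.
#' @export
read_trajectory_tsv <- function(path, dt = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  gcols <- grep("^g_", names(df))
  icols <- grep("^I_", names(df))
  if (is.null(dt)) dt <- if (nrow(df) > 1) df$time[2] - df$time[1] else 0.2
  trajectory(as.matrix(df[gcols]), as.matrix(df[icols]), dt = dt)
}
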