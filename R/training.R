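#' Default training configuration
#'
#' @param lr Adam learning rate.
#' @param max_iter maximum gradient iterations.
#' @param noise_sd run-time Langevin state noise during training.
#' @param seed integer seed (noise stream; weight initialisation is seeded
#'   in [build_synthesis()]).
#' @param tol,patience early stopping: stop when the best loss has not
#'   improved by more than `tol` over `patience` iterations.
#' @return Named list of settings.
#' @export
train_config <- function(lr = 1e-2, max_iter = 3000, noise_sd = 0.01,
                         seed = 1, tol = 1e-6, patience = 500) {
  list(optimizer = "adam", lr = lr, max_iter = max_iter,
       noise_sd = noise_sd, seed = seed, tol = tol, patience = patience)
}

# assemble the C++ trainer arguments for a task
task_train_args <- function(synth, task) {
  n_cond <- length(task$conditions)
  inputs <- array(0, dim = c(n_cond, task$n_inputs, task$N_T + 1))
  for (c_idx in seq_len(n_cond)) {
    inputs[c_idx, , ] <- t(task$conditions[[c_idx]])
  }
  G0 <- matrix(rep(task$initial_policy$value, each = n_cond),
               n_cond, task$n_genes)
  tgt_idx <- cbind(task$targets$condition - 1L, task$targets$step,
                   task$targets$gene - 1L)
  storage.mode(tgt_idx) <- "integer"
  list(inputs = inputs, G0 = G0, tgt_idx = tgt_idx,
       tgt_val = task$targets$value)
}

#' Fit a synthesis function to a task by backpropagation through time
#'
#' The dynamics are unrolled over the task horizon for every condition,
#' the pooled target loss is backpropagated through the unrolled
#' computation, and all network weights plus the trainable initial values
#' are updated with Adam.  The returned parameters are the ones with the
#' lowest observed loss.  Runs are deterministic given the seed.
#'
#' @param synth a `synthesis_fn` whose dimensions match the task.
#' @param task a `task_spec`.
#' @param config a [train_config()] list.
#' @param gamma decay rate of the dynamics.
#' @return A `train_result`: list with `synth` (trained), `loss_history`,
#'   `best_loss`, `initial_loss`, `converged`.
#' @export
train_synthesis <- function(synth, task, config = train_config(),
                            gamma = 1) {
  stopifnot(inherits(synth, "synthesis_fn"), inherits(task, "task_spec"))
  if (synth$n_genes != task$n_genes || synth$n_inputs != task$n_inputs) {
    stop("synthesis function dimensions do not match the task", call. = FALSE)
  }
  synth$init$trainable <- task$initial_policy$trainable
  synth$init$value <- task$initial_policy$value
  args <- task_train_args(synth, task)
  fit <- train_rnn_cpp(synth$params, synth$architecture, synth$mask,
                       args$G0, synth$init$trainable, synth$init$theta,
                       args$inputs, args$tgt_idx, args$tgt_val,
                       gamma, task$dt, config$noise_sd,
                       as.integer(config$max_iter), config$lr,
                       config$tol, as.integer(config$patience),
                       as.integer(config$seed))
  if (isTRUE(fit$diverged) || !is.finite(fit$best_loss)) {
    stop("training diverged: non-finite loss after ",
         length(fit$loss_history), " iterations", call. = FALSE)
  }
  synth$params <- fit$params
  if (synth$architecture == "per_gene") {
    synth$params <- lapply(synth$params, function(p) {
      p$b1 <- as.numeric(p$b1); p$b2 <- as.numeric(p$b2)
      p$b3 <- as.numeric(p$b3); p
    })
  } else {
    synth$params$b1 <- as.numeric(synth$params$b1)
    synth$params$b2 <- as.numeric(synth$params$b2)
    synth$params$b3 <- as.numeric(synth$params$b3)
  }
  synth$init$theta <- as.numeric(fit$init_theta)
  structure(list(synth = synth,
                 loss_history = as.numeric(fit$loss_history),
                 best_loss = fit$best_loss,
                 initial_loss = fit$loss_history[1],
                 converged = length(fit$loss_history) < config$max_iter),
            class = "train_result")
}

#' @exportS3Method base::print
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result: loss %.4g -> %.4g in %d iterations%s>\n",
              x$initial_loss, x$best_loss, length(x$loss_history),
              if (x$converged) " (early stop)" else ""))
  invisible(x)
}

#' Simulate every task condition with a synthesis function
#'
#' @param synth a synthesis function (neural or Hill).
#' @param task a `task_spec`.
#' @param noise_sd,seed optional run-time noise.
#' @param gamma decay rate.
#' @return List of `trajectory` objects, one per condition.
#' @export
simulate_task <- function(synth, task, noise_sd = 0, seed = NULL,
                          gamma = 1) {
  g0 <- if (inherits(synth, "synthesis_fn")) synth_g0(synth)
        else task$initial_policy$value
  lapply(seq_along(task$conditions), function(c_idx) {
    simulate_dynamics(synth, g0, task$conditions[[c_idx]], task$N_T,
                      gamma = gamma, dt = task$dt, noise_sd = noise_sd,
                      seed = if (is.null(seed)) NULL
                             else derive_seed(seed, paste0("cond-", c_idx)))
  })
}

#' Train an ensemble of restarts on one task
#'
#' Each restart uses a distinct derived seed for weight initialisation and
#' run-time noise.  Restarts whose training diverges are recorded and
#' skipped, not fatal; an error is raised only if every restart fails.
#'
#' @param task a `task_spec`.
#' @param n_restarts number of restarts (>= 1).
#' @param base_seed integer; restart seeds are derived from it.
#' @param config a [train_config()].
#' @param hidden_sizes,architecture passed to [build_synthesis()].
#' @param mask optional forbidden links applied to every restart (as in
#'   [apply_structural_mask()]).
#' @return An `ensemble` object: list of `train_result`s with attribute
#'   `failures` (list of restart indices and error messages).
#' @export
train_ensemble <- function(task, n_restarts, base_seed = 1,
                           config = train_config(),
                           hidden_sizes = c(16, 16),
                           architecture = "per_gene",
                           mask = NULL) {
  stopifnot(n_restarts >= 1)
  results <- list()
  failures <- list()
  for (r in seq_len(n_restarts)) {
    seed_r <- derive_seed(base_seed, paste0("restart-", r))
    synth <- build_synthesis(task$n_genes, task$n_inputs,
                             hidden_sizes = hidden_sizes,
                             architecture = architecture, seed = seed_r)
    if (!is.null(mask)) synth <- apply_structural_mask(synth, mask)
    cfg <- config
    cfg$seed <- derive_seed(base_seed, paste0("noise-", r))
    res <- tryCatch(train_synthesis(synth, task, cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(restart = r,
                                               message = conditionMessage(res))
    } else {
      res$restart <- r
      res$seed <- seed_r
      results[[length(results) + 1]] <- res
    }
  }
  if (length(results) == 0) {
    stop("all ", n_restarts, " restarts failed to train", call. = FALSE)
  }
  structure(results, class = "ensemble", failures = failures)
}
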