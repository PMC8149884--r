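#' Generate a random ground-truth cellular-automaton rule
#'
#' A rule is a shared 10-gene regulation network in which each cell's
#' synthesis rates depend on its own state `g` and the average `h` of its
#' two neighbours, giving 20 x 10 = 200 candidate regulatory links.  Each
#' link is independently activating with probability 0.35, absent with
#' 0.30 and inhibiting with 0.35; Hill parameters are drawn from the
#' standard exponential.  Candidate rules are accepted only if a test
#' simulation from random initial conditions displays a non-uniform
#' spatio-temporal pattern (time-averaged spatial variance above the
#' threshold for at least one gene); rejected candidates are retried with
#' derived seeds.
#'
#' @param seed integer seed.
#' @param n_genes genes per cell (default 10).
#' @param p_link probabilities `(activating, absent, inhibiting)`.
#' @param n_cells,test_steps lattice size and length of the acceptance
#'   test run.
#' @param var_threshold acceptance threshold on the time-mean spatial
#'   variance of the most variable gene.
#' @param max_tries maximum number of candidate draws.
#' @return A `ca_rule`: list with `topology` (20 x 10 signed links over
#'   regulators `g1..g10, h1..h10`), `params`, `model` (a `hill_model`),
#'   `seed` and acceptance `diagnostics`.
#' @export
generate_ca_rule <- function(seed = 1, n_genes = 10,
                             p_link = c(0.35, 0.30, 0.35),
                             n_cells = 32, test_steps = 200,
                             var_threshold = 0.01, max_tries = 100) {
  stopifnot(abs(sum(p_link) - 1) < 1e-9)
  for (try in seq_len(max_tries)) {
    seed_t <- derive_seed(seed, paste0("ca-rule-", try))
    cand <- with_local_seed(seed_t, {
      signs <- matrix(sample(c(1L, 0L, -1L), 2 * n_genes * n_genes,
                             replace = TRUE, prob = p_link),
                      2 * n_genes, n_genes)
      dimnames(signs) <- list(c(paste0("g", seq_len(n_genes)),
                                paste0("h", seq_len(n_genes))),
                              paste0("g", seq_len(n_genes)))
      topology(signs, n_genes = n_genes, n_inputs = n_genes)
    })
    params <- sample_hill_params(cand, seed = derive_seed(seed_t, "params"))
    model <- hill_model(cand, params)
    init <- with_local_seed(derive_seed(seed_t, "test-init"),
                            matrix(runif(n_cells * n_genes), n_cells, n_genes))
    arr <- simulate_ca_model(model, init, test_steps)
    spat_var <- apply(arr, c(1, 3), var)       # time x gene
    score <- max(colMeans(spat_var))
    if (is.finite(score) && score > var_threshold) {
      return(structure(list(topology = cand, params = params, model = model,
                            seed = seed, candidate_seed = seed_t,
                            diagnostics = list(tries = try,
                                               pattern_variance = score)),
                       class = "ca_rule"))
    }
  }
  stop("no patterned CA rule found in ", max_tries, " tries", call. = FALSE)
}

#' @exportS3Method base::print
print.ca_rule <- function(x, ...) {
  cat(sprintf(
    "<ca_rule: %d genes, %d existing links of %d, pattern variance %.3g>\n",
    x$topology$n_genes, sum(x$topology$sign != 0),
    length(x$topology$sign), x$diagnostics$pattern_variance))
  invisible(x)
}

# neighbour average with periodic boundary: h_x = (g_{x-1} + g_{x+1}) / 2
neighbor_average <- function(G) {
  n <- nrow(G)
  (G[c(n, seq_len(n - 1)), , drop = FALSE] +
   G[c(seq_len(n - 1) + 1, 1), , drop = FALSE]) / 2
}

# shared core of simulate_ca for any batch-evaluable synthesis function
simulate_ca_model <- function(model, init, n_steps, gamma = 1, dt = 0.2) {
  G <- as.matrix(init)
  n_cells <- nrow(G)
  n_genes <- ncol(G)
  arr <- array(NA_real_, c(n_steps + 1, n_cells, n_genes))
  arr[1, , ] <- G
  a <- 1 - gamma * dt
  for (t in seq_len(n_steps)) {
    H <- neighbor_average(G)
    F <- synth_eval_batch(model, G, H)
    G <- a * G + dt * F
    if (any(!is.finite(G))) stop("CA simulation produced non-finite states",
                                 call. = FALSE)
    arr[t + 1, , ] <- G
  }
  arr
}

#' Simulate a cellular automaton
#'
#' All cells share the rule's regulation network; each updates by the
#' forward-Euler dynamics with its own state and the average of its two
#' nearest neighbours as regulators, with periodic boundaries.
#'
#' @param rule a `ca_rule` (or any batch-evaluable synthesis function over
#'   `n_genes` genes and `n_genes` neighbour inputs).
#' @param init `n_cells x n_genes` matrix of initial states (`n_cells` >=
#'   3).
#' @param n_steps number of Euler steps.
#' @param gamma,dt dynamics parameters.
#' @return Array of shape `(n_steps + 1) x n_cells x n_genes`.
#' @export
simulate_ca <- function(rule, init, n_steps, gamma = 1, dt = 0.2) {
  if (nrow(as.matrix(init)) < 3) stop("at least 3 cells are required",
                                      call. = FALSE)
  model <- if (inherits(rule, "ca_rule")) rule$model else rule
  simulate_ca_model(model, init, n_steps, gamma = gamma, dt = dt)
}

#' Down-sample a spatio-temporal array into training pairs
#'
#' Observation frames are taken every `factor` raw steps; each
#' consecutive frame pair, flattened over cells, becomes one training
#' example recording the cell's state `g`, its neighbour average `h` at
#' the start frame, and the next observed state.
#'
#' @param arr array from [simulate_ca()] (or a list of such arrays, whose
#'   pairs are concatenated).
#' @param factor down-sampling factor (>= 1; default 10).
#' @return A `ca_pairs` object: list with matrices `g0`, `h0`, `g1`
#'   (`n_pairs x n_genes`) plus `factor` and bookkeeping fields.
#' @export
downsample_temporal <- function(arr, factor = 10) {
  stopifnot(factor >= 1)
  if (is.list(arr)) {
    parts <- lapply(arr, downsample_temporal, factor = factor)
    return(structure(list(
      g0 = do.call(rbind, lapply(parts, `[[`, "g0")),
      h0 = do.call(rbind, lapply(parts, `[[`, "h0")),
      g1 = do.call(rbind, lapply(parts, `[[`, "g1")),
      factor = factor,
      n_frames = sum(vapply(parts, `[[`, numeric(1), "n_frames")),
      n_cells = parts[[1]]$n_cells), class = "ca_pairs"))
  }
  n_frames_total <- dim(arr)[1]
  if (n_frames_total < factor + 1) {
    stop("need at least factor + 1 frames to form one pair", call. = FALSE)
  }
  obs_idx <- seq(1, n_frames_total, by = factor)
  n_pairs <- length(obs_idx) - 1
  g0 <- h0 <- g1 <- NULL
  for (k in seq_len(n_pairs)) {
    Gk <- arr[obs_idx[k], , , drop = TRUE]
    Gn <- arr[obs_idx[k + 1], , , drop = TRUE]
    g0 <- rbind(g0, Gk)
    h0 <- rbind(h0, neighbor_average(Gk))
    g1 <- rbind(g1, Gn)
  }
  structure(list(g0 = g0, h0 = h0, g1 = g1, factor = factor,
                 n_frames = length(obs_idx), n_cells = dim(arr)[2]),
            class = "ca_pairs")
}

#' @exportS3Method base::print
print.ca_pairs <- function(x, ...) {
  cat(sprintf("<ca_pairs: %d pairs (%d genes), factor %d>\n",
              nrow(x$g0), ncol(x$g0), x$factor))
  invisible(x)
}

#' Train a neural synthesis function on down-sampled CA observations
#'
#' The model starts from each observed state and runs freely for `factor`
#' fine-grained Euler steps; the loss compares the free-run end state with
#' the next observed state, pooled over all pairs.  During the free run
#' the neighbour input `h` is frozen at its value in the start frame, so
#' pairs are independent training examples; full spatially coupled
#' simulation is used only at evaluation time.
#'
#' Observed gene levels are first normalised by their maximum so the
#' trajectories fit inside the unit range of the sigmoid-bounded
#' synthesis function (Hill-function ground truths can express above 1);
#' the fitted model carries this `data_scale` and downstream scoring and
#' free-running prediction apply it transparently.
#'
#' With `couple_h = "evolve"` (the default) the free run co-simulates the
#' whole lattice: the neighbour average is recomputed from the evolving
#' states at every fine step, exactly as in the generating process, and
#' gradients flow through the spatial coupling.  `"freeze"` instead holds
#' `h` at its start-frame observation, making every cell an independent
#' training example; this is cheaper but biases the learned rate function
#' when neighbours move appreciably between observations.
#'
#' @param pairs a `ca_pairs`.
#' @param hidden_sizes hidden-layer widths (default `c(64, 64)`).
#' @param config a [train_config()].
#' @param couple_h `"evolve"` (lattice co-simulation) or `"freeze"`.
#' @param restarts fresh-initialisation refits attempted while the best
#'   loss stays above 5% of the initial loss (stalled optimisation).
#' @param gamma,dt dynamics parameters.
#' @return List with `synth` (trained shared-architecture
#'   `synthesis_fn`, with a `data_scale` field), `loss_history`,
#'   `best_loss`, `scale`.
#' @export
train_ca_rnn <- function(pairs, hidden_sizes = c(64, 64),
                         config = train_config(max_iter = 2000, noise_sd = 0),
                         couple_h = c("evolve", "freeze"),
                         restarts = 2, gamma = 1, dt = 0.2) {
  couple_h <- match.arg(couple_h)
  stopifnot(inherits(pairs, "ca_pairs"), nrow(pairs$g0) >= 1)
  n_genes <- ncol(pairs$g0)
  n_pairs <- nrow(pairs$g0)
  s_scale <- max(pairs$g0, pairs$g1, 1)
  synth <- build_synthesis(n_genes, n_genes, hidden_sizes = hidden_sizes,
                           architecture = "shared", seed = config$seed)
  synth$input_names <- paste0("h", seq_len(n_genes))
  rownames(synth$mask) <- c(synth$gene_names, synth$input_names)
  inputs <- array(rep(as.numeric(pairs$h0) / s_scale, pairs$factor + 1),
                  dim = c(n_pairs, n_genes, pairs$factor + 1))
  tgt_idx <- cbind(rep(seq_len(n_pairs) - 1L, n_genes),
                   pairs$factor,
                   rep(seq_len(n_genes) - 1L, each = n_pairs))
  storage.mode(tgt_idx) <- "integer"
  couple <- couple_h == "evolve"
  P <- NULL
  if (couple) {
    nc <- pairs$n_cells
    if (n_pairs %% nc != 0) {
      stop("coupled training needs whole lattice frames: the number of ",
           "pairs must be a multiple of n_cells", call. = FALSE)
    }
    left <- c(nc, seq_len(nc - 1))
    right <- c(seq_len(nc - 1) + 1, 1)
    blocks <- n_pairs / nc
    off <- rep((seq_len(blocks) - 1) * nc, each = nc)
    rows <- rep(seq_len(nc), blocks) + off
    P <- Matrix::sparseMatrix(
      i = c(rows, rows),
      j = c(rep(left, blocks) + off, rep(right, blocks) + off),
      x = 0.5, dims = c(n_pairs, n_pairs))
  }
  # per-gene inverse-variance weights: without them the loss is dominated
  # by the high-amplitude genes and the optimiser never resolves the small
  # but informative variations of weakly expressed ones
  gene_sd <- pmax(apply(pairs$g1 / s_scale, 2, sd), 0.02)
  tgt_w <- rep(1 / gene_sd^2, each = n_pairs)
  run_fit <- function(synth, seed) {
    train_rnn_cpp(synth$params, synth$architecture, synth$mask,
                  pairs$g0 / s_scale, rep(FALSE, n_genes),
                  rep(0, n_genes),
                  inputs, tgt_idx, as.numeric(pairs$g1) / s_scale,
                  gamma, dt, config$noise_sd,
                  as.integer(config$max_iter), config$lr,
                  config$tol, as.integer(config$patience),
                  as.integer(seed), couple, P, tgt_w)
  }
  fit <- run_fit(synth, config$seed)
  # optimisation occasionally stalls in a poor basin; refit from fresh
  # weights and keep the best
  att <- 0
  while (att < restarts &&
         (isTRUE(fit$diverged) ||
          !is.finite(fit$best_loss) ||
          fit$best_loss > 0.05 * fit$loss_history[1])) {
    att <- att + 1
    seed_a <- derive_seed(config$seed, paste0("ca-restart-", att))
    synth_a <- build_synthesis(n_genes, n_genes, hidden_sizes = hidden_sizes,
                               architecture = "shared", seed = seed_a)
    fit_a <- run_fit(synth_a, seed_a)
    if (!isTRUE(fit_a$diverged) && is.finite(fit_a$best_loss) &&
        (!is.finite(fit$best_loss) || isTRUE(fit$diverged) ||
         fit_a$best_loss < fit$best_loss)) {
      fit <- fit_a
      synth$params <- fit_a$params
      synth$seed <- seed_a
    }
  }
  if (isTRUE(fit$diverged)) stop("CA training diverged", call. = FALSE)
  synth$params <- fit$params
  synth$params$b1 <- as.numeric(synth$params$b1)
  synth$params$b2 <- as.numeric(synth$params$b2)
  synth$params$b3 <- as.numeric(synth$params$b3)
  synth$data_scale <- s_scale
  list(synth = synth, loss_history = as.numeric(fit$loss_history),
       best_loss = fit$best_loss, scale = s_scale)
}

#' Free-running prediction with a trained CA model
#'
#' Runs the trained synthesis function as a fully coupled lattice (the
#' neighbour average recomputed every step, periodic boundary) from a new
#' initial condition, applying the model's training normalisation.
#'
#' @param synth a trained `synthesis_fn` from [train_ca_rnn()].
#' @param init `n_cells x n_genes` initial states (raw scale).
#' @param n_steps number of Euler steps.
#' @param gamma,dt dynamics parameters.
#' @return Array `(n_steps + 1) x n_cells x n_genes` on the raw scale.
#' @export
ca_free_run <- function(synth, init, n_steps, gamma = 1, dt = 0.2) {
  s <- synth$data_scale %||% 1
  simulate_ca_model(synth, as.matrix(init) / s, n_steps,
                    gamma = gamma, dt = dt) * s
}

#' Knockdown link scores for a CA model
#'
#' Applies the trajectory-averaged knockdown score over the pooled
#' observed states, treating the 20 regulators (10 own-cell genes and 10
#' neighbour averages) independently.
#'
#' @param model a synthesis function over `n_genes` genes + `n_genes`
#'   neighbour inputs (trained `synthesis_fn` or a ground-truth
#'   `hill_model`).
#' @param states a `ca_pairs` (its start frames are used) or a
#'   `trajectory`.
#' @param lam knockdown factor.
#' @return A `link_scores` with a `2 n_genes x n_genes` value matrix.
#' @export
score_ca_links <- function(model, states, lam = 0.95) {
  if (is.list(model) && !is.null(model$synth)) model <- model$synth
  s <- if (inherits(model, "synthesis_fn")) model$data_scale %||% 1 else 1
  traj <- if (inherits(states, "ca_pairs")) {
    trajectory(states$g0 / s, states$h0 / s)
  } else {
    trajectory(states$values / s, states$inputs / s, dt = states$dt)
  }
  delta_matrix(model, traj, lam = lam)
}

#' Three-way link classification against the ground truth
#'
#' Ranks the 200 candidate links by absolute score, predicts the weakest
#' `discard_fraction` as non-existent, signs the rest by their score, and
#' tabulates the 3 x 3 confusion matrix against the true link types.
#'
#' @param scores a `link_scores` or bare score matrix.
#' @param truth the ground-truth `topology` (matching shape).
#' @param discard_fraction fraction of links predicted non-existent.
#' @return List with `confusion` (true x predicted counts over
#'   inhibiting / non-existent / activating) and `predicted` (signed
#'   matrix).
#' @export
classify_links <- function(scores, truth, discard_fraction = 0.30) {
  stopifnot(discard_fraction >= 0, discard_fraction < 1)
  v <- if (inherits(scores, "link_scores")) scores$values else as.matrix(scores)
  ts <- if (inherits(truth, "topology")) truth$sign else as.matrix(truth)
  if (!all(dim(v) == dim(ts))) stop("score/truth shapes do not match",
                                    call. = FALSE)
  n_links <- length(v)
  n_discard <- round(discard_fraction * n_links)
  ord <- order(abs(v))
  pred <- sign(v)
  pred[ord[seq_len(n_discard)]] <- 0
  lv <- c(-1, 0, 1)
  lab <- c("inhibiting", "non_exist", "activating")
  confusion <- table(true = factor(ts, levels = lv, labels = lab),
                     predicted = factor(pred, levels = lv, labels = lab))
  list(confusion = unclass(confusion), predicted = pred)
}

# ROC by threshold sweep on a score for a binary label
roc_curve <- function(score, label) {
  ord <- order(score, decreasing = TRUE)
  lab <- label[ord]
  n_pos <- sum(label)
  n_neg <- sum(!label)
  tpr <- c(0, cumsum(lab) / n_pos)
  fpr <- c(0, cumsum(!lab) / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' ROC analysis of link scores against the ground truth
#'
#' Sweeps a threshold on the score to classify activating links against
#' all others (and, on the negated score, inhibiting links), giving ROC
#' curves and trapezoidal AUCs.
#'
#' @param scores a `link_scores` or score matrix.
#' @param truth ground-truth `topology`.
#' @return List with `roc_activating`, `roc_inhibiting` (data.frames of
#'   `fpr`, `tpr`), `auc_activating`, `auc_inhibiting`.
#' @export
roc_analysis <- function(scores, truth) {
  v <- if (inherits(scores, "link_scores")) scores$values else as.matrix(scores)
  ts <- if (inherits(truth, "topology")) truth$sign else as.matrix(truth)
  if (!all(dim(v) == dim(ts))) stop("score/truth shapes do not match",
                                    call. = FALSE)
  if (!any(ts == 1) || !any(ts == -1)) {
    stop("ground truth must contain at least one activating and one inhibiting link",
         call. = FALSE)
  }
  act <- roc_curve(as.numeric(v), as.numeric(ts) == 1)
  inh <- roc_curve(-as.numeric(v), as.numeric(ts) == -1)
  list(roc_activating = act$curve, roc_inhibiting = inh$curve,
       auc_activating = act$auc, auc_inhibiting = inh$auc)
}

#' Linear auto-regressor baseline for link scoring
#'
#' Fits the next observed state as an affine function of the current
#' `(g, h)` by least squares over all pairs; the fitted coefficient
#' matrix provides the link scores.
#'
#' @param pairs a `ca_pairs`.
#' @return A `link_scores` whose values are the `2 n_genes x n_genes`
#'   coefficient matrix.
#' @export
linear_autoregressor_baseline <- function(pairs) {
  stopifnot(inherits(pairs, "ca_pairs"))
  X <- cbind(1, pairs$g0, pairs$h0)
  if (nrow(X) < ncol(X)) {
    stop("not enough pairs for a determined least-squares fit", call. = FALSE)
  }
  fit <- lm.fit(X, pairs$g1)
  if (fit$rank < ncol(X)) {
    stop(sprintf("rank-deficient design (rank %d of %d columns)",
                 fit$rank, ncol(X)), call. = FALSE)
  }
  W <- fit$coefficients[-1, , drop = FALSE]
  n_genes <- ncol(pairs$g0)
  dimnames(W) <- list(c(paste0("g", seq_len(n_genes)),
                        paste0("h", seq_len(n_genes))),
                      paste0("g", seq_len(n_genes)))
  structure(list(values = W, lambda = NA_real_, n_states = nrow(X)),
            class = "link_scores")
}

#' Run the CA link-inference benchmark
#'
#' For each generated ground-truth rule: simulate training trajectories
#' from random initial conditions, down-sample 10-fold, train the neural
#' model on the free-run objective, score the 200 links by knockdown, and
#' compare ROC AUCs against the linear auto-regressor on the same pairs.
#'
#' @param n_rules number of ground-truth rules.
#' @param seed base seed.
#' @param n_cells lattice size.
#' @param n_traj,n_steps training trajectories per rule and raw steps
#'   each.
#' @param factor temporal down-sampling factor.
#' @param hidden_sizes,train_iter neural model size and iteration budget.
#' @param n_models independently initialised models per rule; their
#'   knockdown scores are averaged, which suppresses the arbitrary shape
#'   a single network adopts where the data constrain it weakly.
#' @param lam knockdown factor for scoring.
#' @return data.frame with one row per rule: RNN and linear AUCs for
#'   activating and inhibiting link detection, training losses.
#' @export
ca_benchmark <- function(n_rules = 4, seed = 1, n_cells = 32,
                         n_traj = 2, n_steps = 400, factor = 10,
                         hidden_sizes = c(32, 32), train_iter = 20000,
                         n_models = 2, lam = 0.95) {
  rows <- lapply(seq_len(n_rules), function(r) {
    seed_r <- derive_seed(seed, paste0("ca-bench-", r))
    rule <- generate_ca_rule(seed_r, n_cells = n_cells)
    arrs <- lapply(seq_len(n_traj), function(tr) {
      init <- with_local_seed(derive_seed(seed_r, paste0("traj-", tr)),
                              matrix(runif(n_cells * 10), n_cells, 10))
      simulate_ca(rule, init, n_steps)
    })
    pairs <- downsample_temporal(arrs, factor = factor)
    loss0 <- NA_real_
    loss1 <- NA_real_
    scores <- NULL
    for (m in seq_len(n_models)) {
      fit <- train_ca_rnn(pairs, hidden_sizes = hidden_sizes,
                          config = train_config(max_iter = train_iter,
                                                noise_sd = 0,
                                                seed = derive_seed(seed_r,
                                                                   paste0("train-", m))),
                          restarts = 1)
      sc <- score_ca_links(fit$synth, pairs, lam = lam)$values
      scores <- if (is.null(scores)) sc else scores + sc
      if (m == 1) { loss0 <- fit$loss_history[1]; loss1 <- fit$best_loss }
    }
    rnn_scores <- scores / n_models
    lin_scores <- linear_autoregressor_baseline(pairs)
    rnn_roc <- roc_analysis(rnn_scores, rule$topology)
    lin_roc <- roc_analysis(lin_scores, rule$topology)
    data.frame(rule = r,
               auc_act_rnn = rnn_roc$auc_activating,
               auc_inh_rnn = rnn_roc$auc_inhibiting,
               auc_act_lin = lin_roc$auc_activating,
               auc_inh_lin = lin_roc$auc_inhibiting,
               loss_initial = loss0,
               loss_final = loss1)
  })
  do.call(rbind, rows)
}
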