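#' Hill activation and repression terms
#'
#' Activation contributes \eqn{b\,g^n / (K^n + g^n)}; repression
#' multiplies by \eqn{K^n / (K^n + g^n)}.  Both are half-maximal at
#' `g = K`; activation is monotone increasing, repression monotone
#' decreasing.
#'
#' @param g regulator level (non-negative; vectorised).
#' @param K half-saturation constant (> 0).
#' @param b activation strength (> 0).
#' @param n Hill coefficient (default 2).
#' @return Numeric term value(s).
#' @export
hill_activation <- function(g, K, b, n = 2) {
  if (any(K <= 0)) stop("`K` must be positive", call. = FALSE)
  b * g^n / (K^n + g^n)
}

#' @rdname hill_activation
#' @export
hill_repression <- function(g, K, n = 2) {
  if (any(K <= 0)) stop("`K` must be positive", call. = FALSE)
  K^n / (K^n + g^n)
}

# nonzero links of a topology in a fixed (column-major) order
topology_links <- function(topo) {
  idx <- which(topo$sign != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
             sign = topo$sign[idx])
}

#' Sample Hill parameters for a topology
#'
#' Every half-saturation constant `K` (all links) and strength `b`
#' (activating links only) is drawn i.i.d. from the standard exponential
#' distribution; repressive links carry no `b`.
#'
#' @param topo a `topology`.
#' @param seed integer seed.
#' @param n Hill coefficient stored with the parameters.
#' @return A `hill_params` object: `links` (data.frame `i`, `j`, `sign`),
#'   `K`, `b` (NA for repressive links) and `n`.
#' @export
sample_hill_params <- function(topo, seed = 1, n = 2) {
  links <- topology_links(topo)
  nl <- nrow(links)
  with_local_seed(seed, {
    K <- rexp(nl)
    b <- rep(NA_real_, nl)
    act <- links$sign > 0
    b[act] <- rexp(sum(act))
    structure(list(links = links, K = K, b = b, n = n),
              class = "hill_params")
  })
}

#' Hill-function dynamical model for a topology
#'
#' Builds a synthesis function where activating inputs are additive Hill
#' terms and repressing inputs multiplicative ones:
#' \eqn{f_i = (\sum_j h^+_{ij}) \prod_l h^-_{il}}.  An empty repressor
#' product is 1 and an empty activator sum is 0 -- basal expression is
#' ignored, so a gene with no activating input is never expressed.
#'
#' @param topo a `topology`.
#' @param params a `hill_params` whose links match the topology's nonzero
#'   links exactly.
#' @return A `hill_model` usable with [simulate_dynamics()],
#'   [synth_eval()], [delta_matrix()] and friends.
#' @export
hill_model <- function(topo, params) {
  stopifnot(inherits(topo, "topology"), inherits(params, "hill_params"))
  expect <- topology_links(topo)
  got <- params$links[, c("i", "j", "sign")]
  if (!isTRUE(all.equal(as.matrix(expect), as.matrix(got),
                        check.attributes = FALSE))) {
    stop("hill parameters do not match the topology's links", call. = FALSE)
  }
  if (any(params$K <= 0) || any(params$b[params$links$sign > 0] <= 0,
                                na.rm = TRUE)) {
    stop("hill parameters must be positive", call. = FALSE)
  }
  structure(list(topology = topo, params = params, n = params$n,
                 n_genes = topo$n_genes, n_inputs = topo$n_inputs,
                 gene_names = topo$gene_names,
                 input_names = topo$input_names),
            class = "hill_model")
}

#' @exportS3Method base::print
print.hill_model <- function(x, ...) {
  cat(sprintf("<hill_model: %d genes, %d inputs, %d links, n = %g>\n",
              x$n_genes, x$n_inputs, nrow(x$params$links), x$n))
  invisible(x)
}

#' Hill synthesis rates for a topology and parameter set
#'
#' @param topo a `topology`.
#' @param params a matching `hill_params`.
#' @param g gene-level vector.
#' @param I input vector.
#' @return Synthesis-rate vector (length `n_genes`).
#' @export
hill_synthesis <- function(topo, params, g, I = numeric(0)) {
  synth_eval(hill_model(topo, params), g, I)
}

#' @export
synth_eval.hill_model <- function(synth, g, I = numeric(0)) {
  drop(synth_eval_batch(synth, matrix(g, nrow = 1),
                        matrix(I, nrow = 1)))
}

#' @export
synth_eval_batch.hill_model <- function(synth, G, I = NULL) {
  G <- as.matrix(G)
  if (is.null(I)) I <- matrix(0, nrow(G), synth$n_inputs)
  I <- as.matrix(I)
  X <- cbind(G, I)
  links <- synth$params$links
  n <- synth$n
  A <- matrix(0, nrow(G), synth$n_genes)
  R <- matrix(1, nrow(G), synth$n_genes)
  for (l in seq_len(nrow(links))) {
    x <- X[, links$i[l]]
    K <- synth$params$K[l]
    if (links$sign[l] > 0) {
      A[, links$j[l]] <- A[, links$j[l]] +
        hill_activation(x, K, synth$params$b[l], n)
    } else {
      R[, links$j[l]] <- R[, links$j[l]] * hill_repression(x, K, n)
    }
  }
  A * R
}

#' Enumerate all connected two-gene, two-input topologies
#'
#' Each of the 8 directed links (I1/I2 onto g1/g2, both self links, both
#' cross links) can be activating, absent or inhibiting; of the 3^8 = 6561
#' sign assignments, those where each input regulates at least one gene
#' and the two genes are connected bidirectionally (so the module is not
#' reducible to one gene) are kept -- 2304 topologies with 4 to 8 links.
#'
#' @return List of `topology` objects in deterministic order.
#' @export
enumerate_topologies_2node <- function() {
  vals <- c(-1, 0, 1)
  grid <- expand.grid(i1g1 = vals, i1g2 = vals, i2g1 = vals, i2g2 = vals,
                      g1g1 = vals, g1g2 = vals, g2g1 = vals, g2g2 = vals)
  keep <- (abs(grid$i1g1) + abs(grid$i1g2) > 0) &
          (abs(grid$i2g1) + abs(grid$i2g2) > 0) &
          grid$g1g2 != 0 & grid$g2g1 != 0
  grid <- grid[keep, ]
  lapply(seq_len(nrow(grid)), function(r) {
    s <- matrix(c(grid$g1g1[r], grid$g1g2[r],
                  grid$g2g1[r], grid$g2g2[r],
                  grid$i1g1[r], grid$i1g2[r],
                  grid$i2g1[r], grid$i2g2[r]),
                nrow = 4, byrow = TRUE,
                dimnames = list(c("g1", "g2", "I1", "I2"), c("g1", "g2")))
    topology(s, n_genes = 2L, n_inputs = 2L)
  })
}

# ---- reference topologies -------------------------------------------------

#' Reference network motifs
#'
#' Small hand-specified topologies used throughout:
#' `topology_min_iff()` -- minimal incoherent feed-forward adaptation
#' motif (input activates output directly and represses it through the
#' buffer gene); `topology_min_nfb_adapt()` -- minimal negative-feedback
#' adaptation motif; `topology_osc_self_activation()` -- the
#' controlled-oscillation module built around the robust two-node
#' relaxation-oscillator core (output self-activation, output activates
#' the repressor, repressor inhibits output; the buffer also
#' self-activates), with `I1` driving the loop and `I2` driving the
#' output high while shutting the repressor off.  A bare two-node
#' negative feedback pair cannot sustain oscillations in this model
#' class (first-order decay, Hill coefficient 2) -- positive feedback is
#' required -- so `topology_min_nfb_oscillator()` is the minimal-link
#' robust negative-feedback oscillator identified by a reduced
#' exhaustive screen: a mutually coupled activator--repressor pair with
#' both self-activations, both inputs acting on the repressed node
#' (their independently drawn coupling strengths let one input sustain
#' the oscillation and the other saturate it);
#' `topology_p53_like()` -- a three-gene controlled-oscillation module
#' with the p53-core structure (input activates a sensor gene that
#' activates the output, the output activates a phosphatase-like gene
#' that shuts the sensor down; the second input drives the output
#' directly and suppresses the sensor).
#'
#' @return A `topology`.
#' @export
topology_min_iff <- function() {
  s <- matrix(0, 3, 2, dimnames = list(c("g1", "g2", "I"), c("g1", "g2")))
  s["I", "g1"] <- 1
  s["I", "g2"] <- 1
  s["g2", "g1"] <- -1
  topology(s, n_genes = 2L, n_inputs = 1L)
}

#' @rdname topology_min_iff
#' @export
topology_min_nfb_adapt <- function() {
  s <- matrix(0, 3, 2, dimnames = list(c("g1", "g2", "I"), c("g1", "g2")))
  s["I", "g1"] <- 1
  s["g1", "g2"] <- 1
  s["g2", "g1"] <- -1
  topology(s, n_genes = 2L, n_inputs = 1L)
}

#' @rdname topology_min_iff
#' @export
topology_osc_self_activation <- function() {
  s <- matrix(0, 4, 2,
              dimnames = list(c("g1", "g2", "I1", "I2"), c("g1", "g2")))
  s["g1", "g1"] <- 1
  s["g2", "g2"] <- 1
  s["g1", "g2"] <- 1
  s["g2", "g1"] <- -1
  s["I1", "g1"] <- 1
  s["I2", "g1"] <- 1
  s["I2", "g2"] <- -1
  topology(s, n_genes = 2L, n_inputs = 2L)
}

#' @rdname topology_min_iff
#' @export
topology_min_nfb_oscillator <- function() {
  s <- matrix(0, 4, 2,
              dimnames = list(c("g1", "g2", "I1", "I2"), c("g1", "g2")))
  s["g1", "g1"] <- 1
  s["g2", "g2"] <- 1
  s["g2", "g1"] <- 1
  s["g1", "g2"] <- -1
  s["I1", "g2"] <- 1
  s["I2", "g2"] <- 1
  topology(s, n_genes = 2L, n_inputs = 2L)
}

#' @rdname topology_min_iff
#' @export
topology_p53_like <- function() {
  s <- matrix(0, 5, 3,
              dimnames = list(c("g1", "g2", "g3", "I1", "I2"),
                              c("g1", "g2", "g3")))
  s["I1", "g3"] <- 1
  s["g3", "g1"] <- 1
  s["g1", "g2"] <- 1
  s["g2", "g3"] <- -1
  s["I2", "g1"] <- 1
  s["I2", "g3"] <- -1
  topology(s, n_genes = 3L, n_inputs = 2L)
}

# ---- batched Hill simulation and screening --------------------------------

# Simulate S parameter sets of one topology under a constant input,
# recording the output gene's level after every step.
# K, b: n_links x S matrices.  Returns n_steps x S matrix.
hf_sim_batch <- function(links, K, b, n, n_genes, I_const, g0 = 0.1,
                         n_steps = 200, dt = 0.2, gamma = 1,
                         record_gene = 1) {
  S <- ncol(K)
  G <- matrix(g0, n_genes, S)
  a <- 1 - gamma * dt
  out <- matrix(NA_real_, n_steps, S)
  nl <- nrow(links)
  Kn <- K^n
  for (t in seq_len(n_steps)) {
    A <- matrix(0, n_genes, S)
    R <- matrix(1, n_genes, S)
    for (l in seq_len(nl)) {
      i <- links$i[l]
      x <- if (i <= n_genes) G[i, ] else rep(I_const[i - n_genes], S)
      xn <- x^n
      j <- links$j[l]
      if (links$sign[l] > 0) {
        A[j, ] <- A[j, ] + b[l, ] * xn / (Kn[l, ] + xn)
      } else {
        R[j, ] <- R[j, ] * Kn[l, ] / (Kn[l, ] + xn)
      }
    }
    G <- a * G + dt * (A * R)
    out[t, ] <- G[record_gene, ]
  }
  out
}

#' Evaluation settings for the Hill-function screens
#'
#' @param n_steps,dt,gamma forward-Euler simulation settings.
#' @param g0 initial level of every gene (mid-range by default so
#'   self-activating modules can ignite despite the no-basal-expression
#'   convention).
#' @param input_level amplitude of the active input.
#' @param window steps scored for oscillation (after transients).
#' @param var_threshold temporal-variance threshold separating
#'   oscillation from steady behaviour.
#' @param low_threshold,high_threshold mean-level bounds for "settles
#'   low" / "settles high".
#' @param amp_threshold,cv_threshold,min_peaks oscillation regularity
#'   check: peak count, inter-peak-interval coefficient of variation and
#'   amplitude.
#' @param pre_input,pre_steps,post_steps adaptation protocol: equilibrate
#'   at the low input, then step up.
#' @param sens_floor,adapt_ratio adaptation success: sensitivity above
#'   the floor and final error below `adapt_ratio` x sensitivity.
#' @param n_hill Hill coefficient.
#' @return Named list of settings.
#' @export
hf_eval_config <- function(n_steps = 200, dt = 0.2, gamma = 1, g0 = 0.5,
                           input_level = 0.8, window = 101:200,
                           var_threshold = 1e-3, low_threshold = 0.2,
                           high_threshold = 0.4, amp_threshold = 0.05,
                           cv_threshold = 0.2, min_peaks = 3,
                           pre_input = 0.1, pre_steps = 150,
                           post_steps = 200, sens_floor = 0.1,
                           adapt_ratio = 0.1, n_hill = 2) {
  as.list(environment())
}

# per-trace oscillation regularity: >= min_peaks strict local maxima with
# consistent spacing and sufficient amplitude over the scoring window
osc_regular <- function(trace, cfg) {
  if (any(!is.finite(trace))) return(FALSE)
  pk <- find_peaks(trace)
  if (length(pk) < cfg$min_peaks) return(FALSE)
  if (max(trace) - min(trace) <= cfg$amp_threshold) return(FALSE)
  gaps <- diff(pk)
  length(gaps) >= 2 && sd(gaps) / mean(gaps) < cfg$cv_threshold
}

# vectorised controlled-oscillation success over S parameter sets
osc_success_batch <- function(links, K, b, n_genes, cfg) {
  w <- cfg$window
  lvl <- cfg$input_level
  tA <- hf_sim_batch(links, K, b, cfg$n_hill, n_genes, c(0, 0),
                     cfg$g0, cfg$n_steps, cfg$dt, cfg$gamma)
  tB <- hf_sim_batch(links, K, b, cfg$n_hill, n_genes, c(lvl, 0),
                     cfg$g0, cfg$n_steps, cfg$dt, cfg$gamma)
  tC <- hf_sim_batch(links, K, b, cfg$n_hill, n_genes, c(0, lvl),
                     cfg$g0, cfg$n_steps, cfg$dt, cfg$gamma)
  finite <- apply(is.finite(tA[w, , drop = FALSE]), 2, all) &
            apply(is.finite(tB[w, , drop = FALSE]), 2, all) &
            apply(is.finite(tC[w, , drop = FALSE]), 2, all)
  vA <- apply(tA[w, , drop = FALSE], 2, var)
  mA <- colMeans(tA[w, , drop = FALSE])
  vB <- apply(tB[w, , drop = FALSE], 2, var)
  vC <- apply(tC[w, , drop = FALSE], 2, var)
  mC <- colMeans(tC[w, , drop = FALSE])
  ok <- finite & vA < cfg$var_threshold & mA < cfg$low_threshold &
        vB > cfg$var_threshold & vC < cfg$var_threshold &
        mC > cfg$high_threshold
  cand <- which(ok)
  for (s in cand) {
    if (!osc_regular(tB[w, s], cfg)) ok[s] <- FALSE
  }
  list(success = ok,
       diagnostics = list(var_rest = vA, mean_rest = mA, var_osc = vB,
                          var_high = vC, mean_high = mC))
}

# vectorised adaptation success: pre-stimulus equilibration at a low
# input, then a step to the high level; sensitivity is the peak deviation
# from the pre-stimulus output, adaptation error the final deviation
adapt_success_batch <- function(links, K, b, n_genes, cfg) {
  S <- ncol(K)
  G <- matrix(cfg$g0, n_genes, S)
  a <- 1 - cfg$gamma * cfg$dt
  n <- cfg$n_hill
  Kn <- K^n
  run <- function(G, I_val, n_steps, record) {
    out <- if (record) matrix(NA_real_, n_steps, S) else NULL
    for (t in seq_len(n_steps)) {
      A <- matrix(0, n_genes, S)
      R <- matrix(1, n_genes, S)
      for (l in seq_len(nrow(links))) {
        i <- links$i[l]
        x <- if (i <= n_genes) G[i, ] else rep(I_val, S)
        xn <- x^n
        j <- links$j[l]
        if (links$sign[l] > 0) A[j, ] <- A[j, ] + b[l, ] * xn / (Kn[l, ] + xn)
        else R[j, ] <- R[j, ] * Kn[l, ] / (Kn[l, ] + xn)
      }
      G <- a * G + cfg$dt * (A * R)
      if (record) out[t, ] <- G[1, ]
    }
    list(G = G, out = out)
  }
  pre <- run(G, cfg$pre_input, cfg$pre_steps, record = FALSE)
  g1_pre <- pre$G[1, ]
  post <- run(pre$G, cfg$input_level, cfg$post_steps, record = TRUE)
  dev <- abs(sweep(post$out, 2, g1_pre))
  sens <- apply(dev, 2, max)
  err <- dev[cfg$post_steps, ]
  finite <- is.finite(sens) & is.finite(err)
  ok <- finite & sens > cfg$sens_floor & err < cfg$adapt_ratio * sens
  list(success = ok,
       diagnostics = list(sensitivity = sens, adaptation_error = err,
                          pre_level = g1_pre))
}

#' Evaluate one Hill parameter set on the controlled-oscillation task
#'
#' Simulates 200 forward-Euler steps under three conditions (no input,
#' `I1` on, `I2` on).  Success requires the output to settle low with no
#' input; to oscillate under `I1` (temporal variance of the output over
#' steps 101-200 above the threshold, at least 3 regularly spaced peaks,
#' amplitude above 0.05); and to settle high under `I2` with
#' sub-threshold variance.
#'
#' @param topo a `topology` (2 inputs).
#' @param params a matching `hill_params`.
#' @param config an [hf_eval_config()] list.
#' @return List with `success` (logical) and `diagnostics`.
#' @export
evaluate_controlled_oscillation_hf <- function(topo, params,
                                               config = hf_eval_config()) {
  links <- params$links
  res <- osc_success_batch(links, matrix(params$K, ncol = 1),
                           matrix(params$b, ncol = 1), topo$n_genes, config)
  list(success = as.logical(res$success[1]),
       diagnostics = lapply(res$diagnostics, function(v) v[1]))
}

#' Evaluate one Hill parameter set on the adaptation task
#'
#' The system equilibrates at a low input, the input steps up, and the
#' output must show a transient pulse (sensitivity above the floor) that
#' returns close to the pre-stimulus level (adaptation error below
#' `adapt_ratio` times the sensitivity).
#'
#' @inheritParams evaluate_controlled_oscillation_hf
#' @return List with `success` and `diagnostics`.
#' @export
evaluate_adaptation_hf <- function(topo, params, config = hf_eval_config()) {
  links <- params$links
  res <- adapt_success_batch(links, matrix(params$K, ncol = 1),
                             matrix(params$b, ncol = 1), topo$n_genes,
                             config)
  list(success = as.logical(res$success[1]),
       diagnostics = lapply(res$diagnostics, function(v) v[1]))
}

#' Random-parameter robustness screen of a topology
#'
#' Samples `n_samples` Hill parameter sets (all `K` and `b` i.i.d.
#' standard exponential), evaluates each on the task, and counts
#' successes.  A topology is conventionally called successful when at
#' least 2 parameter sets succeed.  Sampling is organised in fixed-size
#' chunks, each seeded by a chunk index derived from the base seed, so a
#' run is reproducible and can be split across workers: a worker
#' processing chunks `k+1, ..., k+m` passes `chunk_offset = k`.
#'
#' @param topo a `topology`.
#' @param task `"controlled_oscillation"` or `"adaptation"`.
#' @param n_samples number of parameter sets.
#' @param seed base seed.
#' @param config an [hf_eval_config()].
#' @param chunk_size parameter sets per seeded chunk.
#' @param chunk_offset index offset of the first chunk (for split runs).
#' @param keep_successes retain up to this many successful parameter sets
#'   in the `successes` attribute of the result.
#' @return Integer success count with attribute `successes` (list of
#'   `hill_params`).
#' @export
robustness_search <- function(topo,
                              task = c("controlled_oscillation", "adaptation"),
                              n_samples = 20000, seed = 1,
                              config = hf_eval_config(),
                              chunk_size = 5000, chunk_offset = 0,
                              keep_successes = 3) {
  task <- match.arg(task)
  stopifnot(n_samples >= 1)
  links <- topology_links(topo)
  act <- links$sign > 0
  total <- 0L
  kept <- list()
  n_chunks <- ceiling(n_samples / chunk_size)
  for (ck in seq_len(n_chunks)) {
    S <- min(chunk_size, n_samples - (ck - 1) * chunk_size)
    draws <- with_local_seed(
      derive_seed(seed, paste0("rs-chunk-", chunk_offset + ck)), {
        K <- matrix(rexp(nrow(links) * S), nrow(links), S)
        b <- matrix(NA_real_, nrow(links), S)
        if (any(act)) b[act, ] <- matrix(rexp(sum(act) * S), sum(act), S)
        list(K = K, b = b)
      })
    res <- if (task == "controlled_oscillation") {
      osc_success_batch(links, draws$K, draws$b, topo$n_genes, config)
    } else {
      adapt_success_batch(links, draws$K, draws$b, topo$n_genes, config)
    }
    hit <- which(res$success)
    total <- total + length(hit)
    for (s in head(hit, max(0, keep_successes - length(kept)))) {
      kept[[length(kept) + 1]] <- structure(
        list(links = links, K = draws$K[, s], b = draws$b[, s],
             n = config$n_hill),
        class = "hill_params")
    }
  }
  structure(total, successes = kept)
}

#' Can a topology achieve the task as a Hill-function model?
#'
#' `TRUE` when the robustness screen finds at least 2 successful
#' parameter sets among `n_samples` random draws.
#'
#' @inheritParams robustness_search
#' @return Logical.
#' @export
hf_transfer_test <- function(topo,
                             task = c("controlled_oscillation", "adaptation"),
                             n_samples = 20000, seed = 1,
                             config = hf_eval_config(), chunk_size = 5000) {
  as.integer(robustness_search(topo, task, n_samples, seed, config,
                               chunk_size = chunk_size)) >= 2L
}

#' Screen a list of topologies
#'
#' Runs [robustness_search()] on each topology and tabulates the success
#' counts; convenience wrapper for scaled-down enumeration screens.
#'
#' @param topologies list of `topology` objects.
#' @param task,n_samples,seed,config,chunk_size as in
#'   [robustness_search()].
#' @return data.frame with `id`, `n_links`, `count`, `successful`.
#' @export
screen_topologies <- function(topologies,
                              task = c("controlled_oscillation", "adaptation"),
                              n_samples = 20000, seed = 1,
                              config = hf_eval_config(), chunk_size = 5000) {
  task <- match.arg(task)
  counts <- vapply(seq_along(topologies), function(k) {
    as.integer(robustness_search(topologies[[k]], task, n_samples,
                                 seed = derive_seed(seed, paste0("topo-", k)),
                                 config = config, chunk_size = chunk_size,
                                 keep_successes = 0))
  }, integer(1))
  data.frame(id = seq_along(topologies),
             n_links = vapply(topologies, function(tp) sum(tp$sign != 0),
                              numeric(1)),
             count = counts,
             successful = counts >= 2L)
}
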