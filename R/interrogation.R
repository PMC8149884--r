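#' Construct a signed network topology
#'
#' A topology is a signed adjacency over (genes + inputs) regulators and
#' gene targets with entries in {-1, 0, +1}; inputs appear only as
#' regulators.
#'
#' @param sign `(n_genes + n_inputs) x n_genes` matrix with entries in
#'   {-1, 0, +1}; rows are regulators (genes first, then inputs), columns
#'   are targets.
#' @param n_genes,n_inputs dimensions (inferred from `sign` when `NULL`
#'   and dimnames are present).
#' @param gene_names,input_names node names; defaults `g1..gn` / `I1..Im`.
#' @return A `topology` object.
#' @export
topology <- function(sign, n_genes = NULL, n_inputs = NULL,
                     gene_names = NULL, input_names = NULL) {
  sign <- as.matrix(sign)
  if (!all(sign %in% c(-1, 0, 1))) {
    stop("topology entries must be in {-1, 0, +1}", call. = FALSE)
  }
  n_genes <- n_genes %||% ncol(sign)
  n_inputs <- n_inputs %||% (nrow(sign) - n_genes)
  stopifnot(nrow(sign) == n_genes + n_inputs, ncol(sign) == n_genes,
            n_inputs >= 0)
  gene_names <- gene_names %||%
    (if (!is.null(colnames(sign))) colnames(sign)
     else paste0("g", seq_len(n_genes)))
  input_names <- input_names %||%
    (if (!is.null(rownames(sign)) && n_inputs > 0)
       rownames(sign)[(n_genes + 1):(n_genes + n_inputs)]
     else if (n_inputs == 1) "I"
     else if (n_inputs > 1) paste0("I", seq_len(n_inputs))
     else character(0))
  dimnames(sign) <- list(c(gene_names, input_names), gene_names)
  structure(list(sign = sign, n_genes = n_genes, n_inputs = n_inputs,
                 gene_names = gene_names, input_names = input_names),
            class = "topology")
}

#' @exportS3Method base::print
print.topology <- function(x, ...) {
  cat(sprintf("<topology: %d genes, %d inputs, %d links>\n",
              x$n_genes, x$n_inputs, sum(x$sign != 0)))
  sym <- matrix(c("-", ".", "+")[x$sign + 2], nrow(x$sign),
                dimnames = dimnames(x$sign))
  print(sym, quote = FALSE)
  invisible(x)
}

#' @exportS3Method base::format
format.topology <- function(x, ...) {
  links <- which(x$sign != 0, arr.ind = TRUE)
  if (nrow(links) == 0) return("(empty)")
  paste(sprintf("%s %s %s", rownames(x$sign)[links[, 1]],
                ifelse(x$sign[links] > 0, "->", "-|"),
                colnames(x$sign)[links[, 2]]), collapse = ", ")
}

#' Link-mutation perturbation of the synthesis output
#'
#' Evaluates the synthesis map twice -- once at the given state and once
#' with regulator `i` scaled by `lam` -- and returns the unperturbed
#' vector with component `j` replaced by its perturbed value.  Only the
#' targeted component differs from the wild-type output; `lam = 0` is a
#' full link knockout, values near 1 give a knockdown derivative.
#'
#' @param synth a synthesis function.
#' @param link length-2 vector `(regulator, target)`; names or indices
#'   (regulator order: genes first, then inputs).
#' @param lam discount factor in `[0, 1]`.
#' @param g,I the state at which to evaluate.
#' @return Synthesis-rate vector with component `j` perturbed.
#' @export
perturbed_f <- function(synth, link, lam, g, I = numeric(0)) {
  stopifnot(lam >= 0, lam <= 1)
  idx <- resolve_link(synth, link)
  f0 <- synth_eval(synth, g, I)
  state <- c(g, I)
  state[idx$i] <- lam * state[idx$i]
  n <- length(g)
  f1 <- synth_eval(synth, state[seq_len(n)], state[-seq_len(n)])
  f0[idx$j] <- f1[idx$j]
  f0
}

resolve_link <- function(synth, link) {
  if (inherits(synth, "topology") || !is.null(synth$gene_names)) {
    regs <- c(synth$gene_names, synth$input_names)
    i <- if (is.character(link[[1]])) match(link[[1]], regs) else as.integer(link[[1]])
    j <- if (is.character(link[[2]])) match(link[[2]], synth$gene_names) else as.integer(link[[2]])
    if (is.na(i) || is.na(j) || i < 1 || i > length(regs) ||
        j < 1 || j > length(synth$gene_names)) {
      stop("invalid link: ", paste(unlist(link), collapse = " -> "),
           call. = FALSE)
    }
    return(list(i = i, j = j))
  }
  list(i = as.integer(link[[1]]), j = as.integer(link[[2]]))
}

#' Knockdown sensitivity scores along a trajectory
#'
#' For every (regulator, target) pair, the score is the trajectory average
#' of \eqn{f_j(\ldots, g_i) - f_j(\ldots, \lambda g_i)}.  Positive scores
#' indicate activation, negative ones inhibition; averaging along
#' wild-type states keeps the evaluation inside the region where the model
#' was trained.
#'
#' @param synth a synthesis function.
#' @param traj a `trajectory`, or a list of trajectories whose states are
#'   pooled.
#' @param lam knockdown factor; values just below 1 give a
#'   derivative-like score (default 0.95), 0 scores full knockouts.
#' @return A `link_scores` object: `(n_genes + n_inputs) x n_genes` score
#'   matrix plus the `lambda` and state-count provenance.
#' @export
delta_matrix <- function(synth, traj, lam = 0.95) {
  stopifnot(lam >= 0, lam <= 1)
  if (inherits(traj, "trajectory")) traj <- list(traj)
  G <- do.call(rbind, lapply(traj, function(tr) tr$values))
  I <- do.call(rbind, lapply(traj, function(tr) tr$inputs))
  if (is.null(G) || nrow(G) == 0) stop("empty trajectory", call. = FALSE)
  n_genes <- ncol(G)
  n_reg <- n_genes + ncol(I)
  X <- cbind(G, I)
  F0 <- synth_eval_batch(synth, G, I)
  values <- matrix(0, n_reg, n_genes)
  if (lam < 1) {
    for (i in seq_len(n_reg)) {
      Xp <- X
      Xp[, i] <- lam * Xp[, i]
      Fi <- synth_eval_batch(synth, Xp[, seq_len(n_genes), drop = FALSE],
                             Xp[, -seq_len(n_genes), drop = FALSE])
      values[i, ] <- colMeans(F0 - Fi)
    }
  }
  gene_names <- if (!is.null(synth$gene_names)) synth$gene_names
                else paste0("g", seq_len(n_genes))
  input_names <- if (!is.null(synth$input_names)) synth$input_names
                 else if (ncol(I) == 1) "I" else paste0("I", seq_len(ncol(I)))
  dimnames(values) <- list(c(gene_names, input_names), gene_names)
  structure(list(values = values, lambda = lam, n_states = nrow(G)),
            class = "link_scores")
}

#' @exportS3Method base::print
print.link_scores <- function(x, ...) {
  cat(sprintf("<link_scores: lambda = %g, averaged over %d states>\n",
              x$lambda, x$n_states))
  print(round(x$values, 4))
  invisible(x)
}

#' Simulate a link-knockdown or knockout mutant
#'
#' Integrates the dynamics with the given link perturbed at every step
#' (regulator scaled by `lam` only when the target's synthesis component
#' is computed).  `lam = 0` simulates a link knockout; comparing the
#' mutant with the wild-type trajectory reads out the link's sign: a
#' mutant increase of the target implies inhibition, a decrease
#' activation.
#'
#' @inheritParams perturbed_f
#' @param condition input-course matrix (or index into `task$conditions`).
#' @param task a `task_spec` providing horizon, dt and initial policy.
#' @param synth_init optional synthesis function whose trained initial
#'   values should be used (defaults to `synth` itself).
#' @param gamma decay rate.
#' @return A `trajectory`.
#' @export
mutant_trajectory <- function(synth, link, lam, condition, task,
                              synth_init = NULL, gamma = 1) {
  if (length(condition) == 1 && is.numeric(condition)) {
    condition <- task$conditions[[condition]]
  }
  idx <- resolve_link(synth, link)
  g0 <- if (inherits(synth, "synthesis_fn")) synth_g0(synth)
        else task$initial_policy$value
  pert <- function(g, I) perturbed_f(synth, c(idx$i, idx$j), lam, g, I)
  simulate_dynamics(pert, g0, condition, task$N_T, gamma = gamma,
                    dt = task$dt)
}

#' Simulate a whole-gene knockout
#'
#' The gene's value is clamped to zero for every synthesis evaluation
#' (knocking out all its outgoing links) and its own synthesis is zeroed,
#' so its level decays from the initial value and stays off.
#'
#' @param synth a synthesis function.
#' @param gene gene name or index to knock out.
#' @param condition input-course matrix (or condition index).
#' @param task a `task_spec`.
#' @param gamma decay rate.
#' @return A `trajectory`.
#' @export
gene_knockout_trajectory <- function(synth, gene, condition, task,
                                     gamma = 1) {
  if (length(condition) == 1 && is.numeric(condition)) {
    condition <- task$conditions[[condition]]
  }
  j <- if (is.character(gene)) match(gene, synth$gene_names) else as.integer(gene)
  if (is.na(j) || j < 1) stop("unknown gene: ", gene, call. = FALSE)
  g0 <- if (inherits(synth, "synthesis_fn")) synth_g0(synth)
        else task$initial_policy$value
  ko <- function(g, I) {
    g[j] <- 0
    f <- synth_eval(synth, g, I)
    f[j] <- 0
    f
  }
  simulate_dynamics(ko, g0, condition, task$N_T, gamma = gamma, dt = task$dt)
}

#' Threshold link scores into a signed topology
#'
#' Scores are normalised by the matrix-wide maximum absolute score; links
#' with normalised magnitude at or below the cutoff become 0, the rest
#' take the sign of their score.
#'
#' @param scores a `link_scores` object (or bare score matrix).
#' @param cutoff non-negative cutoff on the normalised magnitude.
#' @return A `topology`.
#' @export
extract_topology <- function(scores, cutoff = 0.2) {
  stopifnot(cutoff >= 0)
  v <- if (inherits(scores, "link_scores")) scores$values else as.matrix(scores)
  m <- max(abs(v))
  norm <- if (m > 0) abs(v) / m else abs(v)
  sg <- sign(v)
  sg[norm <= cutoff] <- 0
  topology(sg)
}

#' Cutoff maximising the number of distinct topologies
#'
#' With no cutoff, weak spurious links make sparse solutions
#' indistinguishable from denser ones; with too high a cutoff, distinct
#' dense solutions collapse.  Scanning a grid and keeping the cutoff that
#' maximises the number of distinct extracted topologies balances the two
#' (ties broken toward the smallest cutoff).
#'
#' @param score_list list of `link_scores` (or matrices), one per model.
#' @param grid cutoffs to scan (default 50 values in `[0, 1)`).
#' @return List with `cutoff`, `n_distinct` and the per-grid counts.
#' @export
optimal_cutoff <- function(score_list, grid = seq(0, 0.98, length.out = 50)) {
  stopifnot(length(score_list) >= 1, length(grid) >= 1)
  counts <- vapply(grid, function(cut) {
    keys <- vapply(score_list, function(s)
      paste(extract_topology(s, cut)$sign, collapse = ","), character(1))
    length(unique(keys))
  }, numeric(1))
  best <- which.max(counts)  # which.max takes the first (smallest) on ties
  list(cutoff = grid[best], n_distinct = counts[best],
       grid = grid, counts = counts)
}

#' Number of differing links between two topologies
#'
#' @param a,b `topology` objects of matching shape.
#' @return Count of (regulator, target) positions with unequal signs.
#' @export
topology_distance <- function(a, b) {
  if (!all(dim(a$sign) == dim(b$sign))) {
    stop("topology shapes do not match", call. = FALSE)
  }
  sum(a$sign != b$sign)
}

#' Similarity graph over a set of topologies
#'
#' One node per distinct topology; edges connect pairs at link distance 1
#' (differing by a single regulatory link).
#'
#' @param topologies list of `topology` objects.
#' @return An `igraph` graph; vertex attribute `count` holds multiplicity,
#'   `links` the number of links, `label` a human-readable edge list.
#' @export
topology_neighbor_graph <- function(topologies) {
  keys <- vapply(topologies, function(tp) paste(tp$sign, collapse = ","),
                 character(1))
  uniq <- !duplicated(keys)
  utopo <- topologies[uniq]
  ukeys <- keys[uniq]
  counts <- as.numeric(table(factor(keys, levels = ukeys)))
  n <- length(utopo)
  edges <- NULL
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (topology_distance(utopo[[i]], utopo[[j]]) == 1) {
          edges <- rbind(edges, c(i, j))
        }
      }
    }
  }
  gr <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges)) gr <- igraph::add_edges(gr, t(edges))
  igraph::V(gr)$count <- counts
  igraph::V(gr)$links <- vapply(utopo, function(tp) sum(tp$sign != 0),
                                numeric(1))
  igraph::V(gr)$label <- vapply(utopo, format, character(1))
  gr
}

#' Does a topology contain an incoherent feed-forward loop onto the
#' output?
#'
#' An IFF requires a direct input-to-output link and an indirect
#' input-intermediate-output path whose sign products are opposite.
#'
#' @param topo a `topology`.
#' @param input regulator name/index of the input (default the first
#'   input).
#' @param output target gene name/index (default gene 1).
#' @return Logical.
#' @export
contains_iff <- function(topo, input = NULL, output = 1L) {
  s <- topo$sign
  i <- topo$n_genes + 1L
  if (!is.null(input)) {
    i <- if (is.character(input)) match(input, rownames(s)) else as.integer(input)
  }
  j <- if (is.character(output)) match(output, colnames(s)) else as.integer(output)
  direct <- s[i, j]
  if (direct == 0) return(FALSE)
  for (k in seq_len(topo$n_genes)) {
    if (k == j) next
    indirect <- s[i, k] * s[k, j]
    if (indirect != 0 && indirect != direct) return(TRUE)
  }
  FALSE
}

#' Does a topology contain a negative feedback loop through the output?
#'
#' Checks for a two-gene cycle with negative sign product involving the
#' output gene (including output self-inhibition combined with a
#' reachable input), with the input connected to the loop.
#'
#' @inheritParams contains_iff
#' @return Logical.
#' @export
contains_nfb <- function(topo, input = NULL, output = 1L) {
  s <- topo$sign
  i <- topo$n_genes + 1L
  if (!is.null(input)) {
    i <- if (is.character(input)) match(input, rownames(s)) else as.integer(input)
  }
  j <- if (is.character(output)) match(output, colnames(s)) else as.integer(output)
  for (k in seq_len(topo$n_genes)) {
    if (k == j) next
    if (s[j, k] * s[k, j] < 0 && (s[i, j] != 0 || s[i, k] != 0)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Sparsify a trained network by iterative link deletion and retraining
#'
#' Step 0 trains with the initial mask.  Each iteration simulates a
#' knockout mutant for every remaining link, deletes the link whose
#' knockout increases the task loss least (ties broken by lowest
#' regulator-then-target index), retrains with the enlarged mask
#' (warm-started from the current weights), and records the result.  The
#' iteration stops when the retrained loss exceeds
#' `fail_factor x` the step-0 loss -- the network then has too few links
#' to perform the task -- or when no links remain.
#'
#' @param task a trainable `task_spec`.
#' @param config a [train_config()].
#' @param initial_mask optional forbidden links applied before the first
#'   training (as in [apply_structural_mask()]).
#' @param hidden_sizes,architecture passed to [build_synthesis()].
#' @param seed seed for the initial weights.
#' @param lam_score knockdown factor used when distilling each step's
#'   topology.
#' @param cutoff normalised-score cutoff for each step's recorded
#'   topology.  The default 0 signs every remaining link: within
#'   sparsification the link set is already explicit (the mask), so
#'   magnitude thresholding on top of it would hide weak but functional
#'   links.
#' @param retries fresh-initialisation retraining attempts when the
#'   warm-started retrain after a deletion fails the loss threshold.
#' @param fail_factor,flat_factor the failure threshold on the noise-free
#'   simulation loss is `max(fail_factor x step-0 loss, flat_factor x
#'   flat loss)`, where the flat loss is that of a constant-at-initial
#'   trajectory -- the scale of "task not performed at all".  A retrained
#'   network above the threshold has too few links to perform the task.
#' @param phenotype_condition condition used for the recorded phenotype
#'   metrics (default: the task's designated phenotype condition, else the
#'   last one).
#' @return A `sparsify_result`: list of steps, each with `mask` (forbidden
#'   links so far), `n_links`, `topology`, `metrics`, `loss` (training
#'   loss), `loss_free` (noise-free simulation loss used for the failure
#'   test), `success`.
#' @export
sparsify <- function(task, config = train_config(), initial_mask = NULL,
                     hidden_sizes = c(16, 16), architecture = "per_gene",
                     seed = 1, lam_score = 0.95, cutoff = 0,
                     fail_factor = 1.5, flat_factor = 0.3, retries = 2,
                     phenotype_condition = NULL) {
  phenotype_condition <- phenotype_condition %||%
    task$meta$phenotype_condition %||% length(task$conditions)
  synth <- build_synthesis(task$n_genes, task$n_inputs,
                           hidden_sizes = hidden_sizes,
                           architecture = architecture, seed = seed)
  if (!is.null(initial_mask)) synth <- apply_structural_mask(synth, initial_mask)
  res <- tryCatch(train_synthesis(synth, task, config),
                  error = function(e) stop("sparsify: initial training failed: ",
                                           conditionMessage(e), call. = FALSE))
  free_loss <- function(r) task_loss(simulate_task(r$synth, task), task)
  loss0 <- free_loss(res)
  # loss of a do-nothing model: constant output at the initial state
  flat <- lapply(task$conditions, function(cond)
    trajectory(matrix(task$initial_policy$value, task$N_T + 1, task$n_genes,
                      byrow = TRUE), cond, dt = task$dt))
  loss_flat <- task_loss(flat, task)
  threshold <- max(fail_factor * loss0, flat_factor * loss_flat)
  record_step <- function(res) {
    synth <- res$synth
    wt <- simulate_task(synth, task)
    sc <- delta_matrix(synth, wt, lam = lam_score)
    topo <- extract_topology(sc, cutoff)
    topo$sign[synth$mask == 0] <- 0L
    loss_free <- task_loss(wt, task)
    list(mask = which(synth$mask == 0, arr.ind = TRUE),
         n_links = sum(synth$mask != 0),
         topology = topo,
         scores = sc,
         metrics = phenotype_metrics(wt[[phenotype_condition]], task),
         loss = res$best_loss,
         loss_free = loss_free,
         success = loss_free <= threshold)
  }
  # delete one link and retrain (warm start, then fresh restarts); NULL if
  # nothing trains below the threshold
  try_deletion <- function(base, drop_link, iter, cand) {
    synth <- apply_structural_mask(base$synth, drop_link)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("sparsify-", iter, "-", cand))
    best <- tryCatch(train_synthesis(synth, task, cfg),
                     error = function(e) NULL)
    for (a in seq_len(retries)) {
      if (!is.null(best) && free_loss(best) <= threshold) break
      fresh <- build_synthesis(task$n_genes, task$n_inputs,
                               hidden_sizes = hidden_sizes,
                               architecture = architecture,
                               seed = derive_seed(seed,
                                                  paste0("retry-", iter, "-",
                                                         cand, "-", a)))
      fresh$mask <- synth$mask
      cfg$seed <- derive_seed(config$seed,
                              paste0("sparsify-", iter, "-", cand,
                                     "-retry-", a))
      alt <- tryCatch(train_synthesis(fresh, task, cfg),
                      error = function(e) NULL)
      if (!is.null(alt) &&
          (is.null(best) || free_loss(alt) < free_loss(best))) best <- alt
    }
    best
  }
  steps <- list(record_step(res))
  iter <- 1L
  while (sum(res$synth$mask != 0) > 0 && steps[[length(steps)]]$success) {
    synth <- res$synth
    remaining <- which(synth$mask != 0, arr.ind = TRUE)
    remaining <- remaining[order(remaining[, 1], remaining[, 2]), , drop = FALSE]
    ko_loss <- vapply(seq_len(nrow(remaining)), function(r) {
      mut <- lapply(seq_along(task$conditions), function(c_idx)
        mutant_trajectory(synth, remaining[r, ], lam = 0,
                          condition = c_idx, task = task))
      task_loss(mut, task)
    }, numeric(1))
    # candidates from minimal knockout damage upward; the first whose
    # retrained network still performs the task is accepted
    accepted <- NULL
    first_failed <- NULL
    for (r in order(ko_loss)) {
      cand <- try_deletion(res, remaining[r, , drop = FALSE], iter, r)
      if (!is.null(cand) && free_loss(cand) <= threshold) {
        accepted <- cand
        break
      }
      if (is.null(first_failed) && !is.null(cand)) first_failed <- cand
    }
    if (is.null(accepted)) {
      # no deletable link left: record the least-bad failure and stop
      if (!is.null(first_failed)) {
        steps[[length(steps) + 1]] <- record_step(first_failed)
      }
      break
    }
    res <- accepted
    steps[[length(steps) + 1]] <- record_step(res)
    iter <- iter + 1L
  }
  structure(steps, class = "sparsify_result",
            loss0 = loss0, loss_flat = loss_flat, threshold = threshold)
}

#' @exportS3Method base::print
print.sparsify_result <- function(x, ...) {
  cat(sprintf("<sparsify: %d steps, step-0 loss %.4g>\n",
              length(x), attr(x, "loss0")))
  for (k in seq_along(x)) {
    cat(sprintf("  step %d: %2d links, loss %.4g (free %.4g)%s\n", k - 1,
                x[[k]]$n_links, x[[k]]$loss, x[[k]]$loss_free,
                if (x[[k]]$success) "" else "  [failed]"))
  }
  invisible(x)
}

#' Last successful step of a sparsification sequence
#'
#' @param x a `sparsify_result`.
#' @return The step record (list) of the sparsest successful network.
#' @export
terminal_topology <- function(x) {
  ok <- which(vapply(x, function(s) isTRUE(s$success), logical(1)))
  if (length(ok) == 0) stop("no successful sparsification step", call. = FALSE)
  x[[max(ok)]]
}

#' Link scores from knockdown-mutant trajectory divergence
#'
#' Complements [delta_matrix()]: instead of averaging the instantaneous
#' change of the synthesis rate, each link is scored by how the target
#' gene's whole trajectory shifts when the link is knocked down
#' (regulator scaled by `lam` in the target's synthesis at every step),
#' averaged over the task conditions.  A knockdown that lowers the
#' target's course implies activation (positive score), one that raises
#' it implies inhibition.  Links whose instantaneous effect is small but
#' integrates over time (e.g. slow feedback arms) score more strongly
#' here than in the synthesis-rate average.
#'
#' @param synth a synthesis function.
#' @param task a `task_spec`.
#' @param lam knockdown factor (default 0.95).
#' @param conditions condition indices to average over (default all).
#' @return A `link_scores` object.
#' @export
mutant_link_scores <- function(synth, task, lam = 0.95,
                               conditions = seq_along(task$conditions)) {
  n_genes <- task$n_genes
  n_reg <- n_genes + task$n_inputs
  wt <- lapply(conditions, function(ci) {
    g0 <- if (inherits(synth, "synthesis_fn")) synth_g0(synth)
          else task$initial_policy$value
    simulate_dynamics(synth, g0, task$conditions[[ci]], task$N_T,
                      dt = task$dt)
  })
  values <- matrix(0, n_reg, n_genes)
  for (i in seq_len(n_reg)) {
    for (j in seq_len(n_genes)) {
      d <- 0
      for (k in seq_along(conditions)) {
        mut <- mutant_trajectory(synth, c(i, j), lam,
                                 task$conditions[[conditions[k]]], task)
        d <- d + mean(mut$values[, j] - wt[[k]]$values[, j])
      }
      values[i, j] <- -d / length(conditions)
    }
  }
  gene_names <- if (!is.null(synth$gene_names)) synth$gene_names
                else paste0("g", seq_len(n_genes))
  input_names <- if (!is.null(synth$input_names)) synth$input_names
                 else if (task$n_inputs == 1) "I"
                 else paste0("I", seq_len(task$n_inputs))
  dimnames(values) <- list(c(gene_names, input_names), gene_names)
  structure(list(values = values, lambda = lam,
                 n_states = length(conditions) * (task$N_T + 1)),
            class = "link_scores")
}

#' Distilled topology combining synthesis-rate and trajectory evidence
#'
#' A link is kept when its normalised magnitude exceeds the cutoff in
#' either the synthesis-rate knockdown average ([delta_matrix()]) or the
#' mutant-trajectory divergence ([mutant_link_scores()]); signs are taken
#' from whichever score is (relatively) stronger.  This mirrors reading
#' the regulation logic from both the learned rate function and simulated
#' knockdown dynamics.
#'
#' @param synth a trained synthesis function.
#' @param task a `task_spec`.
#' @param lam knockdown factor.
#' @param cutoff normalised-magnitude cutoff.
#' @return A `topology`.
#' @export
distill_topology <- function(synth, task, lam = 0.95, cutoff = 0.2) {
  wt <- simulate_task(synth, task)
  a <- delta_matrix(synth, wt, lam = lam)$values
  b <- mutant_link_scores(synth, task, lam = lam)$values
  na <- a / max(abs(a))
  nb <- b / max(abs(b))
  pick <- abs(nb) > abs(na)
  comb <- na
  comb[pick] <- nb[pick]
  sg <- sign(comb)
  sg[pmax(abs(na), abs(nb)) <= cutoff] <- 0
  topology(sg)
}
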