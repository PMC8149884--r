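#' Build a trainable bounded synthesis function
#'
#' The synthesis map \eqn{f(g, I)} is a small multilayer perceptron with
#' two ReLU hidden layers and a sigmoid output layer, so every component
#' of \eqn{f} lies strictly in (0, 1).  Two architectures are supported:
#' `"shared"` uses one network with input width `n_genes + n_inputs` and
#' output width `n_genes`; `"per_gene"` gives each gene its own network
#' with a single output, making structural link masks correspond to an
#' explicit wiring diagram.
#'
#' Weights are initialised from a small-scale Gaussian (sd 0.1) so the
#' initial map is near-constant and gradients are well behaved.
#'
#' @param n_genes,n_inputs numbers of genes and input signals (>= 1 genes;
#'   inputs may be 0 for autonomous systems).
#' @param hidden_sizes two hidden-layer widths (defaults to `c(16, 16)`,
#'   adequate for tasks with up to ~4 genes; use wider layers, e.g. 64,
#'   for 10-gene systems).
#' @param architecture `"per_gene"` or `"shared"`.
#' @param seed integer seed for weight initialisation.
#' @param init_sd standard deviation of the weight initialisation.
#' @return A `synthesis_fn` object.
#' @export
#' @examples
#' s <- build_synthesis(2, 1, seed = 1)
#' synth_eval(s, c(0.5, 0.5), 0.3)
build_synthesis <- function(n_genes, n_inputs,
                            hidden_sizes = c(16, 16),
                            architecture = c("per_gene", "shared"),
                            seed = 1, init_sd = 0.1) {
  stopifnot(n_genes >= 1, n_inputs >= 0, length(hidden_sizes) == 2,
            all(hidden_sizes >= 1))
  architecture <- match.arg(architecture)
  n_in <- n_genes + n_inputs
  h1 <- hidden_sizes[1]
  h2 <- hidden_sizes[2]
  make_net <- function(n_out) {
    list(W1 = matrix(rnorm(n_in * h1, 0, init_sd), n_in, h1),
         b1 = rnorm(h1, 0, init_sd),
         W2 = matrix(rnorm(h1 * h2, 0, init_sd), h1, h2),
         b2 = rnorm(h2, 0, init_sd),
         W3 = matrix(rnorm(h2 * n_out, 0, init_sd), h2, n_out),
         b3 = rnorm(n_out, 0, init_sd))
  }
  params <- with_local_seed(seed, {
    if (architecture == "shared") make_net(n_genes)
    else lapply(seq_len(n_genes), function(j) make_net(1L))
  })
  gene_names <- paste0("g", seq_len(n_genes))
  input_names <- if (n_inputs > 0) {
    if (n_inputs == 1) "I" else paste0("I", seq_len(n_inputs))
  } else character(0)
  mask <- matrix(1, n_in, n_genes,
                 dimnames = list(c(gene_names, input_names), gene_names))
  structure(list(
    n_genes = n_genes, n_inputs = n_inputs,
    architecture = architecture, hidden_sizes = hidden_sizes,
    params = params, mask = mask,
    init = list(trainable = rep(FALSE, n_genes),
                value = rep(0.5, n_genes),
                theta = rep(0, n_genes)),
    gene_names = gene_names, input_names = input_names,
    seed = seed
  ), class = "synthesis_fn")
}

#' @exportS3Method base::print
print.synthesis_fn <- function(x, ...) {
  nmask <- sum(x$mask == 0)
  cat(sprintf(
    "<synthesis_fn: %d genes, %d inputs, %s MLP %d-%d, %d masked link%s>\n",
    x$n_genes, x$n_inputs, x$architecture,
    x$hidden_sizes[1], x$hidden_sizes[2], nmask, if (nmask == 1) "" else "s"))
  invisible(x)
}

# resolve a regulator name/index to its row in the mask / score matrices
regulator_index <- function(synth, reg) {
  regs <- c(synth$gene_names, synth$input_names)
  if (is.character(reg)) {
    i <- match(reg, regs)
    if (is.na(i)) stop("unknown regulator: ", reg, call. = FALSE)
    return(i)
  }
  i <- as.integer(reg)
  if (i < 1 || i > length(regs)) stop("regulator index out of range", call. = FALSE)
  i
}

gene_index <- function(synth, gene) {
  if (is.character(gene)) {
    j <- match(gene, synth$gene_names)
    if (is.na(j)) stop("unknown target gene: ", gene, call. = FALSE)
    return(j)
  }
  j <- as.integer(gene)
  if (j < 1 || j > synth$n_genes) stop("target gene index out of range", call. = FALSE)
  j
}

#' Forbid regulator-target links structurally
#'
#' A forbidden link `(i, j)` is enforced by zeroing regulator `i`'s value
#' at the input of gene `j`'s synthesis component, equivalent to a
#' permanent full knockout of that link.  The mask persists through
#' training: the masked component is invariant to the regulator's value
#' and no gradient flows through the masked connection.
#'
#' @param synth a `synthesis_fn`.
#' @param forbidden_links links to forbid, as a 2-column matrix or
#'   data.frame of (regulator, target) pairs; entries may be names (e.g.
#'   `"I"`, `"g2"`) or indices into the regulator order
#'   (genes first, then inputs).
#' @param replace if `TRUE`, the new mask replaces the old one instead of
#'   accumulating.
#' @return The masked `synthesis_fn`.
#' @export
apply_structural_mask <- function(synth, forbidden_links, replace = FALSE) {
  stopifnot(inherits(synth, "synthesis_fn"))
  if (replace) synth$mask[] <- 1
  if (is.null(forbidden_links) || (is.data.frame(forbidden_links) &&
                                   nrow(forbidden_links) == 0)) {
    return(synth)
  }
  if (is.data.frame(forbidden_links)) forbidden_links <- as.matrix(forbidden_links)
  if (is.null(dim(forbidden_links))) forbidden_links <- matrix(forbidden_links, ncol = 2)
  for (r in seq_len(nrow(forbidden_links))) {
    i <- regulator_index(synth, forbidden_links[r, 1])
    j <- gene_index(synth, forbidden_links[r, 2])
    synth$mask[i, j] <- 0
  }
  synth
}

#' Evaluate a synthesis function at one state
#'
#' @param synth a `synthesis_fn`, a `hill_model`, or a plain R function
#'   `function(g, I)`.
#' @param g gene-level vector.
#' @param I input vector (may be zero-length for autonomous systems).
#' @return Synthesis-rate vector of length `n_genes`.
#' @export
synth_eval <- function(synth, g, I = numeric(0)) {
  UseMethod("synth_eval")
}

#' @export
synth_eval.function <- function(synth, g, I = numeric(0)) synth(g, I)

#' @export
synth_eval.synthesis_fn <- function(synth, g, I = numeric(0)) {
  X <- matrix(c(g, I), nrow = 1)
  drop(mlp_eval_cpp(synth$params, synth$architecture, synth$mask, X,
                    synth$n_genes))
}

#' Evaluate a synthesis function over a batch of states
#'
#' @param synth as in [synth_eval()].
#' @param G `batch x n_genes` matrix of states.
#' @param I `batch x n_inputs` matrix of inputs.
#' @return `batch x n_genes` matrix of synthesis rates.
#' @export
synth_eval_batch <- function(synth, G, I = NULL) {
  UseMethod("synth_eval_batch")
}

#' @export
synth_eval_batch.synthesis_fn <- function(synth, G, I = NULL) {
  G <- as.matrix(G)
  if (is.null(I)) I <- matrix(0, nrow(G), synth$n_inputs)
  mlp_eval_cpp(synth$params, synth$architecture, synth$mask,
               cbind(G, as.matrix(I)), synth$n_genes)
}

#' @export
synth_eval_batch.default <- function(synth, G, I = NULL) {
  G <- as.matrix(G)
  if (is.null(I)) I <- matrix(0, nrow(G), 0)
  I <- as.matrix(I)
  t(vapply(seq_len(nrow(G)),
           function(r) synth_eval(synth, G[r, ], I[r, ]),
           numeric(ncol(G))))
}

#' Initial state implied by a synthesis function's initial-condition policy
#'
#' Fixed genes take their stored value; trainable genes take
#' `sigmoid(theta)`, which keeps trained initial values inside (0, 1).
#'
#' @param synth a `synthesis_fn`.
#' @return Numeric vector of length `n_genes`.
#' @export
synth_g0 <- function(synth) {
  ifelse(synth$init$trainable, sigmoid(synth$init$theta), synth$init$value)
}

#' Save / load a synthesis function checkpoint
#'
#' Checkpoints are JSON files carrying the architecture, mask,
#' initial-condition policy and all weights at full precision.
#'
#' @param synth a `synthesis_fn`.
#' @param path file path (`.json`).
#' @return `path` invisibly for save; the restored `synthesis_fn` for load.
#' @export
save_synthesis <- function(synth, path) {
  stopifnot(inherits(synth, "synthesis_fn"))
  obj <- unclass(synth)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_synthesis
#' @export
load_synthesis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_net <- function(p, n_in, h1, h2, n_out) {
    list(W1 = matrix(as.numeric(t(p$W1)), n_in, h1, byrow = TRUE),
         b1 = as.numeric(unlist(p$b1)),
         W2 = matrix(as.numeric(t(p$W2)), h1, h2, byrow = TRUE),
         b2 = as.numeric(unlist(p$b2)),
         W3 = matrix(as.numeric(t(p$W3)), h2, n_out, byrow = TRUE),
         b3 = as.numeric(unlist(p$b3)))
  }
  n_in <- obj$n_genes + obj$n_inputs
  h1 <- obj$hidden_sizes[1]
  h2 <- obj$hidden_sizes[2]
  params <- if (obj$architecture == "shared") {
    fix_net(obj$params, n_in, h1, h2, obj$n_genes)
  } else {
    lapply(obj$params, fix_net, n_in = n_in, h1 = h1, h2 = h2, n_out = 1L)
  }
  mask <- matrix(as.numeric(unlist(obj$mask)), n_in, obj$n_genes,
                 dimnames = list(c(obj$gene_names, obj$input_names),
                                 obj$gene_names))
  structure(list(
    n_genes = obj$n_genes, n_inputs = obj$n_inputs,
    architecture = obj$architecture, hidden_sizes = obj$hidden_sizes,
    params = params, mask = mask,
    init = list(trainable = as.logical(obj$init$trainable),
                value = as.numeric(obj$init$value),
                theta = as.numeric(obj$init$theta)),
    gene_names = obj$gene_names, input_names = as.character(obj$input_names %||% character(0)),
    seed = obj$seed
  ), class = "synthesis_fn")
}
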