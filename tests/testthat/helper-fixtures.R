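# shared fixtures, all generated in code

# a bounded random synthesis function (plain R, independent of the MLP)
random_bounded_synth <- function(n_genes, n_inputs, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n_genes * (n_genes + n_inputs)), n_genes)
  c0 <- rnorm(n_genes)
  function(g, I) 1 / (1 + exp(-(A %*% c(g, I) + c0)))
}

# random 3-gene, 1-input Hill ground truth; every gene gets at least one
# activator so its expression does not vanish identically
random_hill_system <- function(seed, n_genes = 3, n_inputs = 1) {
  set.seed(seed)
  repeat {
    s <- matrix(sample(c(-1L, 0L, 1L), (n_genes + n_inputs) * n_genes,
                       replace = TRUE, prob = c(0.3, 0.3, 0.4)),
                n_genes + n_inputs, n_genes)
    if (all(colSums(s > 0) >= 1)) break
  }
  topo <- topology(s, n_genes = n_genes, n_inputs = n_inputs)
  params <- sample_hill_params(topo, seed = seed + 1000)
  hill_model(topo, params)
}

# small trained adaptation model cached across tests in one session
trained_adaptation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      task <- make_adaptation_task()
      synth <- build_synthesis(2, 1, seed = 1)
      cache <<- list(task = task,
                     fit = train_synthesis(synth, task,
                                           train_config(seed = 1)))
    }
    cache
  }
})
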