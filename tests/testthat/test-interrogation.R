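test_that("perturbed_f is the identity at lam = 1 and touches only the
           target component", {
  s <- build_synthesis(3, 1, seed = 1, architecture = "shared")
  g <- c(0.2, 0.5, 0.8)
  f0 <- synth_eval(s, g, 0.4)
  expect_identical(perturbed_f(s, c("g1", "g2"), 1, g, 0.4), f0)
  fp <- perturbed_f(s, c("g1", "g2"), 0.3, g, 0.4)
  expect_identical(fp[c(1, 3)], f0[c(1, 3)])
  expect_false(isTRUE(all.equal(fp[2], f0[2])))
  expect_error(perturbed_f(s, c("gX", "g2"), 0.5, g, 0.4), "invalid link")
})

test_that("lam = 0 perturbation equals the structural mask", {
  s <- build_synthesis(2, 1, seed = 2)
  sm <- apply_structural_mask(s, rbind(c("g1", "g2")))
  set.seed(3)
  for (k in 1:20) {
    g <- runif(2); I <- runif(1)
    expect_equal(perturbed_f(s, c("g1", "g2"), 0, g, I)[2],
                 synth_eval(sm, g, I)[2], tolerance = 1e-12)
  }
})

test_that("delta matrix: masked links score exactly zero, lam = 1 gives all
           zeros", {
  s <- build_synthesis(2, 1, seed = 4)
  s <- apply_structural_mask(s, rbind(c("I", "g2"), c("g1", "g2")))
  traj <- simulate_dynamics(s, c(0.4, 0.5),
                            matrix(0.6, 21, 1), 20)
  sc <- delta_matrix(s, traj, lam = 0.95)
  expect_identical(sc$values["I", "g2"], 0)
  expect_identical(sc$values["g1", "g2"], 0)
  expect_false(any(delta_matrix(s, traj, lam = 1)$values != 0))
  expect_error(delta_matrix(s, list()), "empty")
})

test_that("delta signs match finite-difference partials on monotone Hill
           systems, and absent links score zero", {
  for (k in 1:20) {
    hm <- random_hill_system(seed = 100 + k)
    set.seed(k)
    traj <- simulate_dynamics(hm, runif(3), runif(1, 0.3, 0.9), 30)
    sc <- delta_matrix(hm, traj, lam = 0.95)
    norm <- abs(sc$values) / max(abs(sc$values))
    truth <- hm$topology$sign
    # absent links: f_j does not reference g_i at all
    expect_true(all(sc$values[truth == 0] == 0))
    # links with meaningful magnitude match the ground-truth sign
    strong <- truth != 0 & norm > 0.2
    expect_equal(sign(sc$values[strong]), truth[strong])
    # finite-difference oracle at a handful of states
    idx <- which(truth != 0, arr.ind = TRUE)
    st <- traj$values[15, ]
    I <- traj$inputs[15, ]
    for (r in seq_len(min(3, nrow(idx)))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      x <- c(st, I)
      h <- 1e-6
      xp <- x; xp[i] <- xp[i] + h
      fd <- (synth_eval(hm, xp[1:3], xp[4]) - synth_eval(hm, x[1:3], x[4]))[j] / h
      if (abs(fd) > 1e-8 && x[i] > 1e-6) {
        expect_equal(sign(fd), truth[i, j])
      }
    }
  }
})

test_that("delta/(1-lam) converges to the derivative scaled by the
           regulator level as lam -> 1", {
  hm <- random_hill_system(seed = 77)
  set.seed(77)
  traj <- simulate_dynamics(hm, runif(3), 0.7, 25)
  # oracle: mean over states of g_i * d f_j / d g_i
  G <- traj$values; I <- traj$inputs
  h <- 1e-7
  oracle <- matrix(0, 4, 3)
  for (i in 1:4) {
    for (t in seq_len(nrow(G))) {
      x <- c(G[t, ], I[t, ])
      xp <- x; xp[i] <- xp[i] + h
      d <- (synth_eval(hm, xp[1:3], xp[4]) - synth_eval(hm, x[1:3], x[4])) / h
      oracle[i, ] <- oracle[i, ] + x[i] * d / nrow(G)
    }
  }
  for (lam in c(0.99, 0.999)) {
    sc <- delta_matrix(hm, traj, lam = lam)
    expect_equal(sc$values / (1 - lam), oracle, tolerance = 0.05,
                 ignore_attr = TRUE)
  }
})

test_that("knockout mutants shift the target in the direction opposite to
           the link sign", {
  # ground truth: I activates g1, g1 activates g2, g2 represses g3 (plus
  # activator to keep g3 expressed)
  s <- matrix(0, 4, 3, dimnames = list(c("g1", "g2", "g3", "I"),
                                       c("g1", "g2", "g3")))
  s["I", "g1"] <- 1; s["g1", "g2"] <- 1; s["g2", "g3"] <- -1
  s["I", "g3"] <- 1
  topo <- topology(s, n_genes = 3, n_inputs = 1)
  hm <- hill_model(topo, sample_hill_params(topo, seed = 5))
  task <- task_spec(3, 1, list(matrix(0.8, 31, 1)),
                    data.frame(condition = 1, step = 30, gene = 1,
                               value = 0.5),
                    list(trainable = rep(FALSE, 3), value = rep(0.3, 3)),
                    N_T = 30)
  wt <- simulate_dynamics(hm, rep(0.3, 3), matrix(0.8, 31, 1), 30)
  # identical at lam = 1
  m1 <- mutant_trajectory(hm, c("g1", "g2"), 1, 1, task)
  expect_equal(m1$values, wt$values, tolerance = 1e-12)
  # knocking out an activating link lowers the target's level
  ko <- mutant_trajectory(hm, c("g1", "g2"), 0, 1, task)
  expect_lt(mean(ko$values[-1, 2]), mean(wt$values[-1, 2]))
  # knocking out a repressive link raises the target's level
  ko2 <- mutant_trajectory(hm, c("g2", "g3"), 0, 1, task)
  expect_gt(mean(ko2$values[-1, 3]), mean(wt$values[-1, 3]))
  # a link absent from the ground truth changes nothing
  ko3 <- mutant_trajectory(hm, c("g3", "g1"), 0, 1, task)
  expect_equal(ko3$values, wt$values, tolerance = 1e-12)
})

test_that("gene knockout clamps the gene and removes its influence", {
  s <- matrix(0, 4, 3, dimnames = list(c("g1", "g2", "g3", "I"),
                                       c("g1", "g2", "g3")))
  s["I", "g1"] <- 1; s["g1", "g2"] <- 1; s["I", "g3"] <- 1
  topo <- topology(s, n_genes = 3, n_inputs = 1)
  hm <- hill_model(topo, sample_hill_params(topo, seed = 6))
  task <- task_spec(3, 1, list(matrix(0.8, 21, 1)),
                    data.frame(condition = 1, step = 20, gene = 1,
                               value = 0.5),
                    list(trainable = rep(FALSE, 3), value = rep(0.2, 3)),
                    N_T = 20)
  wt <- simulate_dynamics(hm, rep(0.2, 3), matrix(0.8, 21, 1), 20)
  ko <- gene_knockout_trajectory(hm, "g1", 1, task)
  # knocked-out gene decays and stays off
  expect_equal(ko$values[, 1], 0.2 * 0.8^(0:20), tolerance = 1e-12)
  # downstream target loses its activator
  expect_lt(mean(ko$values[-1, 2]), mean(wt$values[-1, 2]))
  # g3 has no incoming link from g1: unchanged
  expect_equal(ko$values[, 3], wt$values[, 3], tolerance = 1e-12)
})

test_that("extract_topology thresholds normalised scores", {
  sc <- structure(list(values = matrix(c(1, -0.4, 0.1), 3, 1,
                                       dimnames = list(c("g1", "g2", "I"),
                                                       "g1")),
                       lambda = 0.95, n_states = 10),
                  class = "link_scores")
  # shape needs a 2-gene layout for the topology contract; use 3x1 as
  # 1 gene + 2 inputs
  topo <- extract_topology(sc, 0.2)
  expect_equal(unname(topo$sign[, 1]), c(1, -1, 0))
  expect_equal(sum(extract_topology(sc, 1)$sign != 0), 0)
  expect_equal(unname(extract_topology(sc, 0)$sign[, 1]), c(1, -1, 1))
})

test_that("optimal cutoff maximises distinct topologies with ties toward
           the smallest cutoff", {
  base <- matrix(c(1, 0.5, 0, 0.9, 0.3, 0), 3, 2)
  weak <- base
  weak[3, 1] <- 0.1                      # one extra weak link
  grid <- c(0.05, 0.2, 0.5)
  oc <- optimal_cutoff(list(base, weak), grid)
  expect_equal(oc$cutoff, 0.05)
  expect_equal(oc$n_distinct, 2)
  # a single matrix: every cutoff gives one topology; smallest returned
  oc1 <- optimal_cutoff(list(base), grid)
  expect_equal(oc1$n_distinct, 1)
  expect_equal(oc1$cutoff, 0.05)
  # cutoff >= 1 collapses everything to the empty topology
  oc2 <- optimal_cutoff(list(base, weak), c(1, 1.5))
  expect_equal(oc2$n_distinct, 1)
})

test_that("topology distance counts differing links and the neighbour
           graph connects distance-1 pairs", {
  t0 <- topology_min_iff()
  expect_equal(topology_distance(t0, t0), 0)
  t1 <- t0
  t1$sign["g1", "g2"] <- 1
  t1 <- topology(t1$sign, n_genes = 2, n_inputs = 1)
  expect_equal(topology_distance(t0, t1), 1)
  t2 <- t1
  t2$sign["g2", "g2"] <- -1
  t2 <- topology(t2$sign, n_genes = 2, n_inputs = 1)
  gr <- topology_neighbor_graph(list(t0, t1, t2, t0))
  expect_equal(igraph::vcount(gr), 3)
  expect_equal(igraph::ecount(gr), 2)      # t0-t1 and t1-t2
  expect_equal(igraph::V(gr)$count, c(2, 1, 1))
  # three mutually distance-2 topologies -> no edges
  a <- topology(matrix(c(0, 1, -1, 0, 1, 0), 3, 2), 2, 1)
  b <- topology(matrix(c(1, -1, -1, 0, 1, 0), 3, 2), 2, 1)
  d <- topology(matrix(c(0, 1, 1, -1, 1, 0), 3, 2), 2, 1)
  expect_equal(topology_distance(a, b), 2)
  expect_equal(topology_distance(a, d), 2)
  expect_equal(topology_distance(b, d), 4)
  expect_equal(igraph::ecount(topology_neighbor_graph(list(a, b, d))), 0)
  bad <- topology(matrix(0, 4, 2), 2, 2)
  expect_error(topology_distance(t0, bad), "shape")
})

test_that("motif detectors recognise the canonical structures", {
  expect_true(contains_iff(topology_min_iff()))
  expect_false(contains_nfb(topology_min_iff()))
  expect_true(contains_nfb(topology_min_nfb_adapt()))
  expect_false(contains_iff(topology_min_nfb_adapt()))
  empty <- topology(matrix(0, 3, 2), 2, 1)
  expect_false(contains_iff(empty))
  expect_false(contains_nfb(empty))
})
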