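test_that("generated CA rules expose 200 candidate links with the stated
           sign frequencies", {
  rule <- generate_ca_rule(seed = 1)
  expect_equal(dim(rule$topology$sign), c(20, 10))
  expect_length(rule$topology$sign, 200)
  expect_gt(rule$diagnostics$pattern_variance, 0.01)
  # sign frequencies over many pre-rejection draws: Binomial(200, 0.7)
  set.seed(2)
  counts <- replicate(400, {
    sum(sample(c(1L, 0L, -1L), 200, replace = TRUE,
               prob = c(0.35, 0.30, 0.35)) != 0)
  })
  expect_equal(mean(counts), 140, tolerance = 0.02)
  # and the accepted rule's own existing-link count is plausible
  n_exist <- sum(rule$topology$sign != 0)
  expect_gt(n_exist, 100)
  expect_lt(n_exist, 180)
  expect_identical(generate_ca_rule(seed = 1)$topology$sign,
                   rule$topology$sign)
})

test_that("CA lattice symmetries hold to machine precision", {
  rule <- generate_ca_rule(seed = 3)
  n_cells <- 16
  set.seed(4)
  init <- matrix(runif(n_cells * 10), n_cells, 10)
  arr <- simulate_ca(rule, init, 40)
  # uniform initial state stays uniform (h = g)
  u <- matrix(rep(runif(10), each = n_cells), n_cells, 10)
  arr_u <- simulate_ca(rule, u, 40)
  for (t in c(2, 20, 41)) {
    expect_lt(max(abs(sweep(arr_u[t, , ], 2, arr_u[t, 1, ]))), 1e-12)
  }
  # cyclic shift of the initial state shifts the whole trajectory
  sh <- function(m, k) m[c((k + 1):n_cells, 1:k), , drop = FALSE]
  arr_s <- simulate_ca(rule, sh(init, 3), 40)
  expect_lt(max(abs(arr_s[41, , ] - sh(arr[41, , ], 3))), 1e-12)
  # mirror symmetry (reflection of the cell order)
  mir <- function(m) m[n_cells:1, , drop = FALSE]
  arr_m <- simulate_ca(rule, mir(init), 40)
  expect_lt(max(abs(arr_m[41, , ] - mir(arr[41, , ]))), 1e-12)
  expect_error(simulate_ca(rule, init[1:2, ], 5), "3 cells")
})

test_that("temporal down-sampling produces the documented pair counts", {
  rule <- generate_ca_rule(seed = 3)
  set.seed(5)
  init <- matrix(runif(8 * 10), 8, 10)
  arr <- simulate_ca(rule, init, 100)   # 101 frames
  pairs <- downsample_temporal(arr, factor = 10)
  expect_equal(nrow(pairs$g0), 10 * 8)  # 10 pairs per cell
  # pair spacing is exactly `factor` raw steps
  expect_equal(pairs$g0[1, ], arr[1, 1, ])
  expect_equal(pairs$g1[1, ], arr[11, 1, ])
  expect_equal(pairs$h0[1, ], (arr[1, 8, ] + arr[1, 2, ]) / 2)
  # factor 1 gives consecutive frames
  p1 <- downsample_temporal(arr, factor = 1)
  expect_equal(nrow(p1$g0), 100 * 8)
  expect_error(downsample_temporal(arr[1:5, , ], factor = 10), "frames")
})

test_that("link classification counts and confusion totals are exact", {
  set.seed(6)
  signs <- sample(c(rep(-1L, 70), rep(0L, 60), rep(1L, 70)))
  truth <- topology(matrix(signs, 20, 10), n_genes = 10, n_inputs = 10)
  # scores equal to the truth (exactly 60 zeros) -> perfect diagonal
  perfect <- classify_links(truth$sign + 0, truth, discard_fraction = 0.30)
  expect_equal(sum(perfect$confusion), 200)
  expect_equal(sum(perfect$predicted == 0), 60)
  expect_equal(sum(diag(perfect$confusion)), 200)
  # random scores give near-chance off-diagonal structure
  rnd <- classify_links(matrix(rnorm(200), 20, 10), truth)
  expect_equal(sum(rnd$confusion), 200)
  expect_equal(sum(rnd$predicted == 0), 60)
  expect_error(classify_links(matrix(0, 5, 5), truth), "shape")
})

test_that("ROC analysis: perfect separation, chance level and endpoints", {
  set.seed(7)
  truth <- topology(matrix(sample(c(-1L, 0L, 1L), 200, replace = TRUE),
                           20, 10), n_genes = 10, n_inputs = 10)
  perfect <- roc_analysis(truth$sign + 0, truth)
  expect_equal(perfect$auc_activating, 1)
  expect_equal(perfect$auc_inhibiting, 1)
  expect_equal(head(perfect$roc_activating$fpr, 1), 0)
  expect_equal(tail(perfect$roc_activating$tpr, 1), 1)
  # permutation oracle: scores independent of truth -> AUC ~ 0.5
  aucs <- replicate(30, {
    r <- roc_analysis(matrix(rnorm(200), 20, 10), truth)
    c(r$auc_activating, r$auc_inhibiting)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  expect_true(all(abs(aucs - 0.5) < 0.25))
  # monotone non-decreasing curves
  expect_true(all(diff(perfect$roc_activating$tpr) >= 0))
  degenerate <- topology(matrix(1L, 20, 10), 10, 10)
  expect_error(roc_analysis(matrix(rnorm(200), 20, 10), degenerate),
               "inhibiting")
})

test_that("the linear baseline recovers an exactly linear rule", {
  set.seed(8)
  n_genes <- 10
  W <- matrix(rnorm(20 * n_genes, 0, 0.1), 20, n_genes)
  c0 <- rnorm(n_genes, 0.05, 0.01)
  lin_rule <- function(g, h) pmax(0, c(cbind(t(g), t(h)) %*% W) + c0)
  # generate pairs from the linear map over random states
  S <- 400
  g0 <- matrix(runif(S * n_genes), S, n_genes)
  h0 <- matrix(runif(S * n_genes), S, n_genes)
  g1 <- cbind(g0, h0) %*% W + matrix(c0, S, n_genes, byrow = TRUE)
  pairs <- structure(list(g0 = g0, h0 = h0, g1 = g1, factor = 1,
                          n_frames = S + 1, n_cells = 1),
                     class = "ca_pairs")
  fit <- linear_autoregressor_baseline(pairs)
  expect_equal(unname(fit$values), W, tolerance = 1e-8)
  # deterministic
  expect_identical(fit$values, linear_autoregressor_baseline(pairs)$values)
  # rank-deficient design is reported
  bad <- pairs
  bad$h0[] <- bad$g0
  expect_error(linear_autoregressor_baseline(bad), "rank")
})

test_that("scoring the ground-truth rule recovers every existing link's
           sign", {
  rule <- generate_ca_rule(seed = 5)
  set.seed(9)
  init <- matrix(runif(16 * 10), 16, 10)
  arr <- simulate_ca(rule, init, 200)
  pairs <- downsample_temporal(arr, factor = 10)
  sc <- score_ca_links(rule$model, pairs, lam = 0.95)
  expect_equal(dim(sc$values), c(20, 10))
  truth <- rule$topology$sign
  live <- truth != 0 & abs(sc$values) > 1e-12
  expect_equal(sign(sc$values[live]), truth[live])
  expect_true(all(sc$values[truth == 0] == 0))
  # lam = 1 gives zeros
  expect_false(any(score_ca_links(rule$model, pairs, lam = 1)$values != 0))
})
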