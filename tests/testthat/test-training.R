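test_that("training reduces the adaptation loss by a large factor", {
  fit <- trained_adaptation()$fit
  expect_lt(fit$best_loss, 0.3 * fit$initial_loss)
  expect_true(all(is.finite(fit$loss_history)))
  expect_equal(fit$best_loss, min(fit$loss_history))
})

test_that("training is deterministic given the seed", {
  task <- make_adaptation_task(input_levels = 0.8, onset_steps = 5,
                               N_T = 20)
  s <- build_synthesis(2, 1, seed = 4)
  a <- train_synthesis(s, task, train_config(max_iter = 120, seed = 4))
  b <- train_synthesis(s, task, train_config(max_iter = 120, seed = 4))
  expect_identical(a$loss_history, b$loss_history)
  expect_identical(a$synth$params, b$synth$params)
  c <- train_synthesis(s, task, train_config(max_iter = 120, seed = 5))
  expect_false(identical(a$loss_history, c$loss_history))
})

test_that("a task whose only target is the forced initial value needs no
           training", {
  task <- task_spec(2, 1, list(matrix(0.5, 11, 1)),
                    data.frame(condition = 1, step = 0, gene = 1,
                               value = 0.4),
                    list(trainable = c(FALSE, TRUE), value = c(0.4, 0.5)),
                    N_T = 10)
  s <- build_synthesis(2, 1, seed = 1)
  fit <- train_synthesis(s, task, train_config(max_iter = 50, seed = 1,
                                               noise_sd = 0))
  expect_equal(fit$best_loss, 0)
  expect_length(fit$loss_history, 1)
})

test_that("trainable initial values stay in (0, 1) and are learned", {
  # target the unconstrained gene's value at t = 0 via a constraint at
  # step 1 after near-zero dynamics: check theta moved
  task <- make_adaptation_task(N_T = 20)
  s <- build_synthesis(2, 1, seed = 2)
  fit <- train_synthesis(s, task, train_config(max_iter = 300, seed = 2))
  g0 <- synth_g0(fit$synth)
  expect_equal(g0[1], 0.4)            # fixed by policy
  expect_true(g0[2] > 0 && g0[2] < 1) # trainable, bounded
})

test_that("ensembles derive distinct seeds and are reproducible", {
  task <- make_adaptation_task(input_levels = 0.8, onset_steps = 5,
                               N_T = 20)
  cfg <- train_config(max_iter = 80)
  e1 <- train_ensemble(task, 5, base_seed = 3, config = cfg)
  expect_length(e1, 5)
  seeds <- vapply(e1, function(r) r$seed, numeric(1))
  expect_equal(anyDuplicated(seeds), 0L)
  e2 <- train_ensemble(task, 5, base_seed = 3, config = cfg)
  expect_identical(lapply(e1, function(r) r$loss_history),
                   lapply(e2, function(r) r$loss_history))
})

test_that("restart topologies collapse to fewer distinct networks than
           restarts", {
  task <- make_adaptation_task()
  ens <- train_ensemble(task, 8, base_seed = 1, config = train_config())
  keys <- vapply(ens, function(res) {
    paste(distill_topology(res$synth, task, cutoff = 0.2)$sign,
          collapse = ",")
  }, character(1))
  expect_lt(length(unique(keys)), length(ens))
})

test_that("dimension mismatches are rejected", {
  task <- make_adaptation_task(N_T = 20)
  s <- build_synthesis(3, 1, seed = 1)
  expect_error(train_synthesis(s, task), "dimensions")
})
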