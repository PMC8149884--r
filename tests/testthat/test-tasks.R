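test_that("adaptation target starts and ends at the pre-stimulus level and
           peaks where calculus says", {
  task <- make_adaptation_task(onset_steps = 5, input_levels = 0.8,
                               N_T = 80)
  tg <- task$targets[task$targets$condition == 1, ]
  # at onset the difference of exponentials vanishes
  expect_equal(tg$value[tg$step == 5], 0.4)
  # long after onset both exponentials have decayed
  expect_lt(abs(tg$value[tg$step == 80] - 0.4), 0.01)
  # analytic peak time: t* = (ln ts - ln tf) / (1/tf - 1/ts), here on a
  # fine grid so the sampled argmax lands within one step of it
  tf <- 0.4; ts <- 1.6
  t_star <- (log(ts) - log(tf)) / (1 / tf - 1 / ts)
  peak_step <- tg$step[which.max(tg$value)]
  expect_lt(abs((peak_step - 5) * task$dt - t_star), task$dt)
  # peak height equals pre_level + pulse_amplitude
  expect_equal(max(tg$value), 0.4 + 0.5, tolerance = 0.01)
})

test_that("adaptation task validates its target range", {
  expect_error(make_adaptation_task(pre_level = 0.7, pulse_amplitude = 0.5),
               "exceeds")
})

test_that("adaptation conditions cover levels x onsets plus one null", {
  task <- make_adaptation_task(input_levels = c(0, 0.4, 0.8),
                               onset_steps = c(5, 10))
  expect_length(task$conditions, 1 + 2 * 2)
  # null condition target is flat at pre_level
  tg1 <- task$targets[task$targets$condition == 1, ]
  expect_true(all(tg1$value == 0.4))
  # phenotype condition has the largest level and earliest onset
  pc <- task$meta$phenotype_condition
  cond <- task$conditions[[pc]]
  expect_equal(max(cond), 0.8)
  expect_equal(sum(cond == 0), 5)
})

test_that("controlled-oscillation task has three conditions with the stated
           targets", {
  task <- make_controlled_oscillation_task()
  expect_length(task$conditions, 3)
  expect_true(all(task$conditions[[1]] == 0))
  expect_equal(unique(task$conditions[[2]][, 1]), 0.8)
  expect_equal(unique(task$conditions[[3]][, 2]), 0.8)
  tg <- split(task$targets, task$targets$condition)
  expect_true(all(tg[[1]]$value == 0.1))
  expect_equal(min(tg[[2]]$value), 0.2)   # triangular wave hits its range
  expect_equal(max(tg[[2]]$value), 0.8)
  expect_equal(tail(tg[[3]]$value, 1), 0.8)
  expect_true(all(task$targets$gene == 1))
  expect_error(make_controlled_oscillation_task(period = 1), "period")
})

test_that("gap-gene profiles have the documented shape", {
  prof <- synth_gap_gene_profiles(40, seed = 2)
  expect_true(all(diff(prof$morphogens[, "Bcd"]) < 0))
  tor <- prof$morphogens[, "Tor"]
  mid <- 15:25
  expect_gt(tor[1], max(tor[mid]))
  expect_gt(tor[40], max(tor[mid]))
  peaks <- apply(prof$targets, 2, which.max)
  expect_equal(anyDuplicated(peaks), 0L)
  expect_true(all(diff(peaks) > 0))   # bands ordered along the axis
  expect_true(all(prof$morphogens >= 0 & prof$morphogens <= 1))
  expect_true(all(prof$targets >= 0 & prof$targets <= 1))
  expect_identical(prof, synth_gap_gene_profiles(40, seed = 2))
  expect_false(identical(prof$targets,
                         synth_gap_gene_profiles(40, seed = 3)$targets))
})

test_that("gap-gene tasks constrain only the final time point from zero
           initial state", {
  prof <- synth_gap_gene_profiles(12, seed = 1)
  tasks <- make_gap_gene_task(prof, N_T = 30)
  expect_length(tasks, 12)
  for (tk in tasks[c(1, 6, 12)]) {
    expect_equal(tk$n_genes, 4)
    expect_equal(tk$n_inputs, 2)
    expect_true(all(tk$targets$step == 30))
    expect_equal(sort(tk$targets$gene), 1:4)
    expect_equal(tk$initial_policy$value, rep(0, 4))
    expect_false(any(tk$initial_policy$trainable))
  }
  merged <- merge_task_list(tasks)
  expect_length(merged$conditions, 12)
  expect_equal(nrow(merged$targets), 48)
})

test_that("loss is the pooled root-sum-of-squares over constraints", {
  task <- make_adaptation_task(input_levels = c(0.4, 0.8),
                               onset_steps = 5)
  # trajectories matching every target exactly -> loss 0
  exact <- lapply(seq_along(task$conditions), function(ci) {
    v <- matrix(0.5, task$N_T + 1, 2)
    tg <- task$targets[task$targets$condition == ci, ]
    v[tg$step + 1, 1] <- tg$value
    trajectory(v, task$conditions[[ci]])
  })
  expect_equal(task_loss(exact, task), 0)
  # one constraint off by 0.5 -> loss 0.5
  off <- exact
  tg1 <- task$targets[task$targets$condition == 1, ][1, ]
  off[[1]]$values[tg1$step + 1, 1] <- tg1$value + 0.5
  expect_equal(task_loss(off, task), 0.5)
  # brute-force oracle over an explicit constraint loop
  set.seed(1)
  noisy <- lapply(exact, function(tr) {
    tr$values <- tr$values + matrix(runif(length(tr$values), 0, 0.1),
                                    nrow(tr$values))
    tr
  })
  s <- 0
  for (k in seq_len(nrow(task$targets))) {
    tg <- task$targets[k, ]
    s <- s + (noisy[[tg$condition]]$values[tg$step + 1, tg$gene] - tg$value)^2
  }
  expect_equal(task_loss(noisy, task), sqrt(s), tolerance = 1e-12)
  expect_error(task_loss(exact[1], task), "condition")
})

test_that("phenotype metrics recover pulse arithmetic", {
  task <- make_adaptation_task()
  n <- task$N_T
  # constant at pre level
  flat <- trajectory(matrix(0.4, n + 1, 2), task$conditions[[1]])
  pm <- phenotype_metrics(flat, task)
  expect_equal(pm$sensitivity, 0)
  expect_equal(pm$adaptation_error, 0)
  # pulse peaking at 0.9, returning to 0.4
  g1 <- rep(0.4, n + 1)
  g1[10:14] <- c(0.6, 0.9, 0.7, 0.5, 0.45)
  pulse <- trajectory(cbind(g1, 0.5), task$conditions[[1]])
  pm <- phenotype_metrics(pulse, task)
  expect_equal(pm$sensitivity, 0.5)
  expect_equal(pm$adaptation_error, 0)
  # settling at a new level L -> error |L - pre|
  g1 <- 0.4 + (0.7 - 0.4) * (1 - 0.8^(0:n))
  ramp <- trajectory(cbind(g1, 0.5), task$conditions[[1]])
  pm <- phenotype_metrics(ramp, task)
  expect_equal(pm$adaptation_error, abs(g1[n + 1] - 0.4))
  expect_error(phenotype_metrics(flat, task, onset_step = n + 2), "post")
})

test_that("task specs round-trip through YAML", {
  task <- make_adaptation_task(input_levels = c(0, 0.8), onset_steps = 5)
  path <- tempfile(fileext = ".yaml")
  save_task(task, path)
  back <- load_task(path)
  expect_equal(back$n_genes, task$n_genes)
  expect_equal(back$N_T, task$N_T)
  expect_equal(back$conditions, task$conditions, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back$targets$value, task$targets$value, tolerance = 1e-9)
  expect_equal(back$initial_policy, task$initial_policy)
  expect_equal(back$meta$kind, "adaptation")
})

test_that("task validation catches bad inputs", {
  expect_error(task_spec(2, 1, list(matrix(0, 11, 1)),
                         data.frame(condition = 1, step = 1, gene = 1,
                                    value = 1.2),
                         list(trainable = c(FALSE, TRUE),
                              value = c(0.4, 0.5)), N_T = 10),
               "\\[0, 1\\]")
  expect_error(task_spec(2, 1, list(matrix(0, 11, 1)),
                         data.frame(condition = 1, step = 11, gene = 1,
                                    value = 0.5),
                         list(trainable = c(FALSE, TRUE),
                              value = c(0.4, 0.5)), N_T = 10),
               "bounds")
  expect_error(task_spec(2, 1, list(matrix(0, 11, 1)),
                         data.frame(condition = numeric(0),
                                    step = numeric(0), gene = numeric(0),
                                    value = numeric(0)),
                         list(trainable = c(FALSE, TRUE),
                              value = c(0.4, 0.5)), N_T = 10),
               "at least one")
})
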