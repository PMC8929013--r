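test_that("particle decoding maps 10 bits onto the full geometric grid", {
  d <- decode_particle(c(rep(1, 3), rep(0, 10)), 3)
  expect_identical(d$mask, c(1L, 1L, 1L))
  expect_equal(d$C, 2^-16)
  expect_equal(d$gamma, 2^-16)
  d <- decode_particle(c(0, rep(1, 10)), 1)
  expect_equal(d$C, 2^15)
  expect_equal(d$gamma, 2^15)
  expect_error(decode_particle(rep(0, 5), 3), "n_features")

  # bijection: all 1024 hyperparameter patterns give distinct (C, gamma)
  bits <- as.matrix(expand.grid(rep(list(0:1), 10)))
  pairs <- apply(bits, 1, function(b) {
    d <- decode_particle(c(1, b), 1)
    paste(d$C, d$gamma)
  })
  expect_length(unique(pairs), 1024L)
})

test_that("swarm initialization is seeded, sized and clamped", {
  cfg <- bpso_config(n_particles = 3, n_iterations = 5,
                     phase_switch_iteration = 3, random_seed = 42)
  sw <- init_swarm(5, cfg)
  expect_length(sw, 3)
  for (p in sw) {
    expect_length(p$position, 15)
    expect_length(p$velocity, 15)
    expect_true(all(p$position %in% 0:1))
    expect_true(all(abs(p$velocity) <= 6))
    expect_identical(p$pbest_position, p$position)
  }
  expect_identical(init_swarm(5, cfg), sw)
})

test_that("velocity updates have the canonical fixed points and clamp", {
  x <- c(1, 0, 1, 0)
  v0 <- rep(0, 4)
  expect_identical(update_velocity(v0, x, x, x, 0.7, 2, 2, 6), rep(0, 4))
  v <- c(-2, 1, 5, -5)
  expect_identical(update_velocity(v, x, x, x, 1, 0, 0, 6), v)
  set.seed(1)
  big <- update_velocity(rep(6, 50), rep(0, 50), rep(1, 50), rep(1, 50),
                         1, 2, 2, 6)
  expect_true(all(abs(big) <= 6))
})

test_that("position sampling follows the sigmoid transfer function", {
  set.seed(99)
  draws <- replicate(2e4, update_position(c(0, 1, 6, -6)))
  freq <- rowMeans(draws)
  expect_equal(freq[1], 0.5, tolerance = 0.05)
  expect_equal(freq[2], 1 / (1 + exp(-1)), tolerance = 0.02)
  expect_equal(freq[3], 1 / (1 + exp(-6)), tolerance = 0.01)
  expect_lt(freq[4], 0.01)
})

test_that("fitness is CV accuracy: separable clusters score 1, noise ~0.5", {
  set.seed(5)
  n <- 40
  labels <- rep(c(1L, 0L), each = n / 2)
  x <- matrix(rnorm(n * 4, sd = 0.2), n) + labels * 10
  cfg <- bpso_config(n_particles = 2, n_iterations = 2,
                     phase_switch_iteration = 1, cv_folds = 5,
                     random_seed = 3)
  # mask all-ones; C = 2^(21-16) = 32, gamma = 2^(12-16) = 1/16
  pos <- c(1, 1, 1, 1, 1, 0, 1, 0, 1, 0, 1, 1, 0, 0)
  expect_equal(evaluate_fitness(pos, x, labels, cfg), 1.0)

  null_fit <- vapply(1:3, function(s) {
    set.seed(s)
    evaluate_fitness(pos, matrix(rnorm(n * 4), n), sample(labels), cfg)
  }, numeric(1))
  expect_lt(abs(mean(null_fit) - 0.5), 0.15)
  few <- c(1:3, 21:23)  # three samples per class, below cv_folds = 5
  expect_error(evaluate_fitness(pos, x[few, ], labels[few], cfg), "cv_folds")
})

test_that("the swarm search is monotone, reproducible and at least as good
           as the unselected baseline", {
  fx <- generate_feature_fixture(n = 60, n_informative = 4, n_noise = 16,
                                 effect_size = 1, seed = 21)
  cfg <- bpso_config(n_particles = 8, n_iterations = 6,
                     phase_switch_iteration = 4, cv_folds = 5,
                     random_seed = 77)
  sel <- run_bpso(fx$x, fx$labels, cfg)
  expect_s3_class(sel, "selection_result")
  expect_false(is.unsorted(sel$fitness_history))
  expect_length(sel$fitness_history, 6)
  expect_gte(sum(sel$feature_mask), 1)

  # bit-reproducible from the seed
  sel2 <- run_bpso(fx$x, fx$labels, cfg)
  expect_identical(sel$position, sel2$position)
  expect_identical(sel$fitness_history, sel2$fitness_history)

  # the all-ones mask with mid-grid (C, gamma) is in the search space, so the
  # winner cannot score below it on the same folds
  baseline <- evaluate_fitness(
    c(rep(1L, 20), 1L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L),  # C = 1, gamma = 2^-4
    fx$x, fx$labels, cfg)
  expect_gte(sel$best_fitness, baseline)
  expect_error(run_bpso(fx$x, rep(1L, 60), cfg), "degenerate")
})

test_that("selection results round-trip through the text serialization", {
  fx <- generate_feature_fixture(n = 40, n_informative = 2, n_noise = 6,
                                 seed = 3)
  cfg <- bpso_config(n_particles = 4, n_iterations = 2,
                     phase_switch_iteration = 1, cv_folds = 5,
                     random_seed = 9)
  sel <- run_bpso(fx$x, fx$labels, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection(sel, path)
  back <- read_selection(path)
  expect_identical(back$feature_mask, sel$feature_mask)
  expect_equal(back$C, sel$C)
  expect_equal(back$gamma, sel$gamma)
  expect_equal(back$fitness_history, sel$fitness_history)
})
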