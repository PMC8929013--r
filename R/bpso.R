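# Binary particle swarm optimization over a hybrid bit-string: a feature
# selection mask followed by 10 bits indexing the RBF-SVM (C, gamma) pair on
# a geometric grid. Fitness is stratified 10-fold cross-validation accuracy.

#' The geometric (C, gamma) hyperparameter grid
#'
#' Both SVM hyperparameters range over `2^-16 .. 2^15` with common ratio 2:
#' 32 values each, hence 1024 combinations, indexable by 10 bits (5 per
#' parameter).
#'
#' @param exponent_min,exponent_max Inclusive exponent bounds (base 2).
#' @return Object of class `hyperparam_grid`.
#' @export
hyperparam_grid <- function(exponent_min = -16L, exponent_max = 15L) {
  structure(list(base = 2, exponent_min = as.integer(exponent_min),
                 exponent_max = as.integer(exponent_max)),
            class = "hyperparam_grid")
}

bits_to_int <- function(bits) sum(bits * 2^(rev(seq_along(bits)) - 1L))

#' Decode a hybrid particle position
#'
#' The first `n_features` bits are the feature mask; the next 5 bits
#' (most-significant first) give the grid index of `C` and the last 5 that of
#' `gamma`, with value `base^(index + exponent_min)`.
#'
#' @param position 0/1 vector of length `n_features + 10`.
#' @param n_features Number of mask bits.
#' @param grid A [hyperparam_grid()].
#' @return List with `mask` (0/1 integer vector), `C`, `gamma`.
#' @export
decode_particle <- function(position, n_features, grid = hyperparam_grid()) {
  if (length(position) != n_features + 10L)
    stopf("position length %d != n_features + 10 = %d",
          length(position), n_features + 10L)
  mask <- as.integer(position[seq_len(n_features)])
  hyper <- position[n_features + 1:10]
  i_c <- bits_to_int(hyper[1:5])
  i_g <- bits_to_int(hyper[6:10])
  list(mask = mask,
       C = grid$base^(i_c + grid$exponent_min),
       gamma = grid$base^(i_g + grid$exponent_min))
}

#' BPSO configuration
#'
#' Defaults follow the full-scale search settings this predictor was designed
#' around: 80 particles, 300 iterations with the convergence-accelerating
#' phase starting after iteration 200, velocities clamped to `(-6, 6)`, and
#' ten-fold cross-validation fitness. The inertia schedule (0.9 linearly down
#' to 0.4) and `c1 = c2 = 2` are the standard PSO settings; both are exposed
#' because the search is robust to them but not insensitive.
#'
#' @param n_particles Swarm size.
#' @param n_iterations Total iterations.
#' @param phase_switch_iteration Last iteration of the exploratory phase;
#'   later iterations use the global-best attraction rule (`phase2_rule`).
#' @param v_max Velocity clamp (absolute value).
#' @param inertia Scalar, or length-2 vector `(start, end)` for a linear
#'   schedule over the iterations.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param cv_folds Folds for the fitness cross-validation.
#' @param random_seed Seed controlling initialization, stochastic updates and
#'   the (fixed per run) fold partition.
#' @param phase2_rule Function `(position, velocity, gbest)` returning the new
#'   position in the accelerated phase; the default draws each bit toward the
#'   global best with probability `sigmoid(|v|)`, keeping the current bit
#'   otherwise.
#' @return Object of class `bpso_config`.
#' @export
bpso_config <- function(n_particles = 80L, n_iterations = 300L,
                        phase_switch_iteration = 200L, v_max = 6,
                        inertia = c(0.9, 0.4), c1 = 2, c2 = 2,
                        cv_folds = 10L, random_seed = 1L,
                        phase2_rule = phase2_gbest_attraction) {
  if (phase_switch_iteration > n_iterations)
    stopf("phase_switch_iteration (%d) must be <= n_iterations (%d)",
          phase_switch_iteration, n_iterations)
  if (v_max <= 0) stopf("v_max must be positive")
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 phase_switch_iteration = as.integer(phase_switch_iteration),
                 v_max = v_max, inertia = inertia, c1 = c1, c2 = c2,
                 cv_folds = as.integer(cv_folds),
                 random_seed = as.integer(random_seed),
                 phase2_rule = phase2_rule),
            class = "bpso_config")
}

inertia_at <- function(config, iter) {
  w <- config$inertia
  if (length(w) == 1L) return(w)
  if (config$n_iterations == 1L) return(w[1L])
  w[1L] + (w[2L] - w[1L]) * (iter - 1L) / (config$n_iterations - 1L)
}

#' Initialize a swarm
#'
#' Each position bit is an independent Bernoulli(0.5) draw; each velocity
#' component is uniform on `[-v_max, v_max]`; personal bests start at the
#' initial positions (fitness filled in on the first evaluation).
#'
#' @param n_features Number of feature-mask bits (particle length is
#'   `n_features + 10`).
#' @param config A [bpso_config()]; `random_seed` makes the swarm
#'   reproducible.
#' @return List of particles, each a list with `position`, `velocity`,
#'   `pbest_position`, `pbest_fitness` (`-Inf` until evaluated).
#' @export
init_swarm <- function(n_features, config = bpso_config()) {
  stopifnot(n_features >= 1L)
  d <- n_features + 10L
  with_seed(config$random_seed, {
    lapply(seq_len(config$n_particles), function(i) {
      pos <- as.integer(stats::runif(d) < 0.5)
      list(position = pos,
           velocity = stats::runif(d, -config$v_max, config$v_max),
           pbest_position = pos,
           pbest_fitness = -Inf)
    })
  })
}

#' Velocity update (phase-1 rule)
#'
#' `v' = w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` componentwise with
#' `r1, r2 ~ U(0,1)` per component, clamped to `[-v_max, v_max]`.
#'
#' @param velocity,position,pbest,gbest Numeric vectors of equal length.
#' @param inertia Inertia weight `w` for this iteration.
#' @param c1,c2 Acceleration coefficients.
#' @param v_max Clamp.
#' @return New velocity vector.
#' @export
update_velocity <- function(velocity, position, pbest, gbest,
                            inertia, c1, c2, v_max) {
  d <- length(velocity)
  stopifnot(length(position) == d, length(pbest) == d, length(gbest) == d)
  v <- inertia * velocity +
    c1 * stats::runif(d) * (pbest - position) +
    c2 * stats::runif(d) * (gbest - position)
  pmin(pmax(v, -v_max), v_max)
}

#' Position update via the sigmoid transfer function (phase-1 rule)
#'
#' Each bit is set to 1 independently with probability
#' `sigmoid(v) = 1 / (1 + exp(-v))`.
#'
#' @param velocity Numeric vector.
#' @return 0/1 integer vector.
#' @export
update_position <- function(velocity) {
  as.integer(stats::runif(length(velocity)) < sigmoid(velocity))
}

#' Phase-2 position rule: attraction to the global best
#'
#' After the swarm's exploratory phase plateaus, each bit is replaced by the
#' corresponding global-best bit with probability `sigmoid(|v|)` (>= 1/2, and
#' near 1 for saturated velocities) and kept otherwise, collapsing the swarm
#' onto the incumbent solution while residual velocity still permits local
#' exploration.
#'
#' @param position Current 0/1 vector.
#' @param velocity Numeric vector.
#' @param gbest Global-best 0/1 vector.
#' @return 0/1 integer vector.
#' @export
phase2_gbest_attraction <- function(position, velocity, gbest) {
  take <- stats::runif(length(velocity)) < sigmoid(abs(velocity))
  out <- position
  out[take] <- gbest[take]
  as.integer(out)
}

# Repair an all-zero feature mask by setting one uniformly random mask bit;
# an empty mask has no defined fitness.
repair_mask <- function(position, n_features) {
  if (sum(position[seq_len(n_features)]) == 0L)
    position[sample.int(n_features, 1L)] <- 1L
  position
}

# Per-fold training/test splits of one feature matrix. fold assignment comes
# from make_folds(); returns the structure consumed by cv_accuracy().
build_fold_data <- function(x, labels, fold_id) {
  lapply(sort(unique(fold_id)), function(k) {
    test <- fold_id == k
    list(train_x = x[!test, , drop = FALSE], train_y = labels[!test],
         test_x = x[test, , drop = FALSE], test_y = labels[test])
  })
}

# Mean of per-fold accuracies of an RBF-SVM on the masked columns.
cv_accuracy <- function(fold_data, mask, C, gamma) {
  cols <- which(mask == 1L)
  accs <- vapply(fold_data, function(fd) {
    fit <- e1071::svm(x = fd$train_x[, cols, drop = FALSE],
                      y = factor(fd$train_y, levels = c(0L, 1L)),
                      kernel = "radial", cost = C, gamma = gamma,
                      scale = FALSE)
    pred <- stats::predict(fit, fd$test_x[, cols, drop = FALSE])
    mean(as.integer(as.character(pred)) == fd$test_y)
  }, numeric(1))
  mean(accs)
}

#' Fitness of a particle position
#'
#' Decodes the position and returns the mean stratified k-fold
#' cross-validation accuracy of an RBF-SVM with the decoded `(C, gamma)` on
#' the masked feature columns. The fold partition is derived from
#' `config$random_seed`, so every position evaluated under the same config is
#' scored on the same folds.
#'
#' @param position Hybrid 0/1 vector (`ncol(matrix) + 10` bits).
#' @param matrix Feature matrix (rows = sequences).
#' @param labels Binary labels (1 = pseudouridine site).
#' @param config A [bpso_config()].
#' @param grid A [hyperparam_grid()].
#' @return Fitness in `[0, 1]`.
#' @export
evaluate_fitness <- function(position, matrix, labels, config = bpso_config(),
                             grid = hyperparam_grid()) {
  if (min(table(labels)) < config$cv_folds)
    stopf("each class needs at least cv_folds = %d samples", config$cv_folds)
  fold_id <- make_folds(labels, config$cv_folds, config$random_seed)
  fold_data <- build_fold_data(matrix, labels, fold_id)
  position <- with_seed(config$random_seed,
                        repair_mask(position, ncol(matrix)))
  dec <- decode_particle(position, ncol(matrix), grid)
  cv_accuracy(fold_data, dec$mask, dec$C, dec$gamma)
}

#' Run the BPSO feature / hyperparameter search
#'
#' Iterates a swarm over the hybrid bit-string. Up to
#' `phase_switch_iteration` the canonical sigmoid-transfer binary PSO rules
#' apply (velocity update toward personal and global bests, stochastic bit
#' sampling); afterwards positions are updated by `config$phase2_rule`, which
#' by default pulls bits onto the global best to accelerate convergence once
#' the exploratory phase has plateaued. The global best never regresses, so
#' the returned fitness history is non-decreasing. Fully reproducible from
#' `config$random_seed`.
#'
#' @param matrix Feature matrix (rows = sequences, columns = features).
#' @param labels Binary labels, at least `cv_folds` per class.
#' @param config A [bpso_config()].
#' @param grid A [hyperparam_grid()].
#' @param fold_data Optional precomputed per-fold encodings (list of
#'   `train_x/train_y/test_x/test_y`), used when feature values themselves
#'   must be refit per training fold (the label-derived PSKP descriptor);
#'   defaults to slicing `matrix` on a stratified partition.
#' @return Object of class `selection_result`: `feature_mask`, `C`, `gamma`,
#'   `best_fitness`, `fitness_history`, `n_features`, `position`.
#' @export
run_bpso <- function(matrix, labels, config = bpso_config(),
                     grid = hyperparam_grid(), fold_data = NULL) {
  n_features <- ncol(matrix)
  if (length(unique(labels)) < 2L) stopf("labels are degenerate (one class)")
  if (min(table(labels)) < config$cv_folds)
    stopf("each class needs at least cv_folds = %d samples", config$cv_folds)

  fold_id <- make_folds(labels, config$cv_folds, config$random_seed)
  if (is.null(fold_data)) fold_data <- build_fold_data(matrix, labels, fold_id)

  swarm <- init_swarm(n_features, config)
  gbest_pos <- NULL
  gbest_fit <- -Inf
  history <- numeric(config$n_iterations)

  with_seed(config$random_seed + 1L, {
    for (iter in seq_len(config$n_iterations)) {
      if (iter > 1L) {
        w <- inertia_at(config, iter)
        phase2 <- iter > config$phase_switch_iteration
        swarm <- lapply(swarm, function(p) {
          p$velocity <- update_velocity(p$velocity, p$position,
                                        p$pbest_position, gbest_pos,
                                        w, config$c1, config$c2, config$v_max)
          p$position <- if (phase2)
            config$phase2_rule(p$position, p$velocity, gbest_pos)
          else update_position(p$velocity)
          p$position <- repair_mask(p$position, n_features)
          p
        })
      } else {
        swarm <- lapply(swarm, function(p) {
          p$position <- repair_mask(p$position, n_features)
          p$pbest_position <- p$position
          p
        })
      }
      for (i in seq_along(swarm)) {
        dec <- decode_particle(swarm[[i]]$position, n_features, grid)
        fit <- cv_accuracy(fold_data, dec$mask, dec$C, dec$gamma)
        if (fit > swarm[[i]]$pbest_fitness) {
          swarm[[i]]$pbest_fitness <- fit
          swarm[[i]]$pbest_position <- swarm[[i]]$position
        }
        if (fit > gbest_fit) {
          gbest_fit <- fit
          gbest_pos <- swarm[[i]]$position
        }
      }
      history[iter] <- gbest_fit
    }
  })

  dec <- decode_particle(gbest_pos, n_features, grid)
  structure(list(feature_mask = dec$mask, C = dec$C, gamma = dec$gamma,
                 best_fitness = gbest_fit, fitness_history = history,
                 n_features = n_features, position = gbest_pos),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "selection_result: %d/%d features, C = 2^%g, gamma = 2^%g, fitness = %.4f\n",
    sum(x$feature_mask), x$n_features, log2(x$C), log2(x$gamma),
    x$best_fitness))
  invisible(x)
}

#' Serialize / restore a selection result as plain text
#'
#' Key-value file (`mask` as a 0/1 string, `C`, `gamma`, `best_fitness`) plus
#' a two-column TSV (`iteration`, `fitness`) alongside for the fitness curve.
#'
#' @param result A `selection_result`.
#' @param path Output path for the key-value file; the history TSV gets the
#'   suffix `.history.tsv`.
#' @export
write_selection <- function(result, path) {
  lines <- c(paste0("mask\t", paste(result$feature_mask, collapse = "")),
             paste0("C\t", format(result$C, digits = 17)),
             paste0("gamma\t", format(result$gamma, digits = 17)),
             paste0("best_fitness\t", format(result$best_fitness, digits = 17)))
  writeLines(lines, path)
  utils::write.table(
    data.frame(iteration = seq_along(result$fitness_history),
               fitness = result$fitness_history),
    paste0(path, ".history.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  kv <- utils::read.delim(path, header = FALSE,
                          col.names = c("key", "value"),
                          colClasses = "character")
  vals <- stats::setNames(kv$value, kv$key)
  mask <- as.integer(strsplit(vals[["mask"]], "")[[1L]])
  hist_path <- paste0(path, ".history.tsv")
  history <- if (file.exists(hist_path))
    utils::read.delim(hist_path)$fitness else numeric(0)
  structure(list(feature_mask = mask, C = as.numeric(vals[["C"]]),
                 gamma = as.numeric(vals[["gamma"]]),
                 best_fitness = as.numeric(vals[["best_fitness"]]),
                 fitness_history = history, n_features = length(mask),
                 position = NULL),
            class = "selection_result")
}
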