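# Linear-SVM decoding of traversal direction from single-neuron activity
# vectors: per-neuron (self) decoding, cross-neuron generalization, and the
# relation between decoding accuracy and unique encoding.

svm_accuracy <- function(train_x, train_y, test_x, test_y, cost = 1) {
  if (length(unique(train_y)) < 2) return(NA_real_)
  fit <- e1071::svm(x = train_x, y = factor(train_y), kernel = "linear",
                    cost = cost, scale = FALSE)
  mean(as.character(predict(fit, test_x)) == test_y)
}

# traversal x bin rate matrix with direction labels; NA bins filled with 0
trial_feature_matrix <- function(tm, z_score = FALSE) {
  wide <- tm |>
    dplyr::select("trial", "direction", "bin", "rate_hz") |>
    tidyr::pivot_wider(names_from = "bin", values_from = "rate_hz",
                       names_sort = TRUE)
  X <- as.matrix(wide[, -(1:2)])
  X[!is.finite(X)] <- 0
  if (z_score) {
    mu <- mean(X); sdv <- sd(X)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    X <- (X - mu) / sdv
  }
  list(X = X, y = wide$direction, trial = wide$trial)
}

#' Per-neuron direction decoding
#'
#' Trains linear SVMs to predict the traversal direction from the neuron's
#' single-traversal 10-bin activity vectors. For each of `repeats` random
#' stratified 80/20 splits the test accuracy is recorded; the control
#' repeats the procedure with direction labels shuffled before training.
#'
#' @param tm per-traversal rate tibble from [traversal_rate_matrix()].
#' @param repeats random splits (default 20).
#' @param train_fraction training fraction (default 0.8).
#' @param cost SVM regularization constant (default 1).
#' @param min_traversals minimum traversals per direction (default 10).
#' @param seed RNG seed.
#' @return tibble with `accuracy_real`, `accuracy_shuffled`, `n_repeats`,
#'   `n_traversals`.
#' @export
decode_self <- function(tm, repeats = 20, train_fraction = 0.8, cost = 1,
                        min_traversals = 10, seed = 1L) {
  fm <- trial_feature_matrix(tm)
  n_by <- table(fm$y)
  assert_that(length(n_by) == 2 && all(n_by >= min_traversals),
              sprintf("need >= %d traversals per direction", min_traversals))
  split_idx <- function() {
    # stratified: sample within each class so both appear in train and test
    tr <- unlist(lapply(unique(fm$y), function(cl) {
      ii <- which(fm$y == cl)
      sample(ii, max(1, round(train_fraction * length(ii))))
    }))
    tr
  }
  with_seed(seed, {
    acc <- replicate(repeats, {
      tr <- split_idx()
      svm_accuracy(fm$X[tr, , drop = FALSE], fm$y[tr],
                   fm$X[-tr, , drop = FALSE], fm$y[-tr], cost)
    })
    acc_sh <- replicate(repeats, {
      tr <- split_idx()
      y_sh <- sample(fm$y)
      svm_accuracy(fm$X[tr, , drop = FALSE], y_sh[tr],
                   fm$X[-tr, , drop = FALSE], fm$y[-tr], cost)
    })
  })
  tibble(accuracy_real = mean(acc, na.rm = TRUE),
         accuracy_shuffled = mean(acc_sh, na.rm = TRUE),
         n_repeats = repeats, n_traversals = length(fm$y))
}

#' Cross-neuron direction decoding
#'
#' For each test neuron, SVMs are trained on the z-scored activity vectors
#' of `n_train` other neurons of the same pool (15 to-reward and 15
#' to-trigger vectors per training neuron) and evaluated on all of the test
#' neuron's z-scored vectors. Training pools are redrawn `draws` times per
#' size; the control shuffles the training labels.
#'
#' @param tms named list of per-traversal rate tibbles (one per neuron of
#'   the pool, from [traversal_rate_matrix()]).
#' @param n_train training-pool sizes (default 1:10, capped at pool - 1).
#' @param draws random pool draws per size (default 20).
#' @param vectors_per_direction training vectors sampled per direction per
#'   training neuron (default 15).
#' @param cost SVM regularization constant.
#' @param seed RNG seed.
#' @return tibble with `test_unit`, `n_train`, `accuracy_real`,
#'   `accuracy_shuffled`.
#' @export
decode_cross <- function(tms, n_train = 1:10, draws = 20,
                         vectors_per_direction = 15, cost = 1, seed = 1L) {
  assert_that(length(tms) >= 2, "need a pool of at least 2 neurons")
  assert_that(all(n_train >= 1), "n_train must be >= 1")
  fms <- purrr::map(tms, trial_feature_matrix, z_score = TRUE)
  # training neurons must have enough traversals per direction
  eligible <- vapply(fms, function(f) {
    tab <- table(f$y)
    length(tab) == 2 && all(tab >= vectors_per_direction)
  }, logical(1))
  if (any(!eligible))
    message(sprintf(
      "decode_cross: %d neuron(s) lack %d traversals per direction and are excluded from training pools",
      sum(!eligible), vectors_per_direction))
  units <- names(fms)
  n_train <- n_train[n_train < sum(eligible)]
  assert_that(length(n_train) >= 1, "training pool too small")
  out <- list()
  with_seed(seed, {
    for (test_u in units) {
      pool <- setdiff(units[eligible], test_u)
      fm_test <- fms[[test_u]]
      for (k in n_train) {
        accs <- matrix(NA_real_, draws, 2)
        for (d in seq_len(draws)) {
          tr_units <- sample(pool, k)
          train <- purrr::map(tr_units, function(u) {
            f <- fms[[u]]
            idx <- unlist(lapply(c("to_reward", "to_trigger"), function(cl)
              sample(which(f$y == cl), vectors_per_direction)))
            list(X = f$X[idx, , drop = FALSE], y = f$y[idx])
          })
          Xtr <- do.call(rbind, purrr::map(train, "X"))
          ytr <- unlist(purrr::map(train, "y"))
          accs[d, 1] <- svm_accuracy(Xtr, ytr, fm_test$X, fm_test$y, cost)
          accs[d, 2] <- svm_accuracy(Xtr, sample(ytr), fm_test$X,
                                     fm_test$y, cost)
        }
        out[[length(out) + 1]] <- tibble(
          test_unit = test_u, n_train = k,
          accuracy_real = mean(accs[, 1], na.rm = TRUE),
          accuracy_shuffled = mean(accs[, 2], na.rm = TRUE))
      }
    }
  })
  dplyr::bind_rows(out)
}

#' Decoding accuracy vs unique encoding
#'
#' Pearson correlation, per variable, between per-neuron decoding accuracy
#' and the unique contribution (delta r^2) of the variable, with a 95% band
#' from within-neuron shuffles of the delta r^2 values (1000 repeats).
#'
#' @param decoding tibble with `unit_id` and `accuracy_real`.
#' @param delta_tbl tibble with `unit_id`, `variable`, `delta_r2`.
#' @param n_shuffle shuffle repetitions.
#' @param seed RNG seed.
#' @return tibble with `variable`, `r`, `lo`, `hi`, `outside_band`.
#' @export
accuracy_vs_encoding <- function(decoding, delta_tbl, n_shuffle = 1000,
                                 seed = 1L) {
  wide <- delta_tbl |>
    dplyr::select("unit_id", "variable", "delta_r2") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "delta_r2")
  joined <- dplyr::inner_join(decoding, wide, by = "unit_id")
  vars <- setdiff(names(wide), "unit_id")
  M <- as.matrix(joined[, vars])
  acc <- joined$accuracy_real
  safe_cor <- function(a, b) {
    if (sd(b) == 0 || sd(a) == 0) return(NA_real_)
    cor(a, b)
  }
  r_obs <- vapply(vars, function(v) safe_cor(acc, joined[[v]]), numeric(1))
  with_seed(seed, {
    null <- replicate(n_shuffle, {
      Ms <- t(apply(M, 1, sample))
      vapply(seq_along(vars), function(j) safe_cor(acc, Ms[, j]),
             numeric(1))
    })
  })
  null <- matrix(null, nrow = length(vars))
  lo <- apply(null, 1, quantile, 0.025, na.rm = TRUE)
  hi <- apply(null, 1, quantile, 0.975, na.rm = TRUE)
  tibble(variable = vars, r = r_obs, lo = lo, hi = hi,
         outside_band = !is.na(r_obs) & (r_obs < lo | r_obs > hi))
}
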