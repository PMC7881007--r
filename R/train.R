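# parameter tree paths touched by the optimiser
param_paths <- function() {
  cellf <- c("W_fh", "W_fx", "b_f", "W_ch", "W_cx", "b_c")
  c(lapply(cellf, function(f) c("cell_fwd", f)),
    lapply(cellf, function(f) c("cell_rev", f)),
    as.list(c("pK1", "pb1", "pK2", "pb2", "rK1", "rb1", "rK2", "rb2",
              "fcW1", "fcb1", "fcW2", "fcb2")))
}

get_path <- function(x, path) { for (p in path) x <- x[[p]]; x }
set_path <- function(x, path, value) {
  if (length(path) == 1) x[[path]] <- value
  else x[[path[1]]] <- set_path(x[[path[1]]], path[-1], value)
  x
}

adam_init <- function(params) {
  zeros <- lapply(param_paths(), function(p) get_path(params, p) * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  paths <- param_paths()
  for (i in seq_along(paths)) {
    g <- get_path(grads, paths[[i]])
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    w <- get_path(params, paths[[i]])
    params <- set_path(params, paths[[i]], w - lr * mhat / (sqrt(vhat) + eps))
  }
  list(params = params, state = state)
}

#' Random train/test split of windows
#'
#' Shuffles indices with `seed` and splits at `ratio` (default 0.8, i.e. the
#' 4:1 convention). With `stratify`, the split is drawn within each class so
#' both sides keep the overall balance.
#'
#' @param labels integer labels (one per window); their length defines n.
#' @param ratio training fraction.
#' @param seed integer seed.
#' @param stratify split within class (default `TRUE`).
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_windows <- function(labels, ratio = 0.8, seed = 1, stratify = TRUE) {
  n <- length(labels)
  if (n < 5) abort("too few windows to split")
  with_seed_if(seed, {
    if (stratify) {
      tr <- unlist(lapply(unique(labels), function(cl) {
        idx <- which(labels == cl)
        sample(idx, round(ratio * length(idx)))
      }), use.names = FALSE)
    } else {
      tr <- sample(n, round(ratio * n))
    }
    tr <- sort(tr)
    list(train = tr, test = setdiff(seq_len(n), tr))
  })
}

one_hot <- function(y, n_classes = 2) {
  Y <- matrix(0, length(y), n_classes)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  Y
}

#' Train the multi-scale model
#'
#' Minibatch Adam on the mean softmax cross-entropy, with the Bernoulli
#' coupling mask active during training. After each epoch the model is
#' evaluated (mask off) on the held-out set, and the loss/accuracy pair is
#' appended to the run log. Deterministic given `seed`.
#'
#' @param x `n x N x 235` window array (see [windows_to_array()]).
#' @param y integer labels in `{0, 1}`.
#' @param cfg a [model_config()].
#' @param epochs training epochs (default 50).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default from `cfg`, 64).
#' @param seed seed controlling initialisation, shuffling and masks.
#' @param val_x,val_y optional held-out windows for the per-epoch accuracy
#'   column (omitted: that column is `NA`).
#' @param verbose print per-epoch progress.
#' @return object of class `pwc_fit`: trained `params`, `config`, `runlog`
#'   tibble (epoch, train_loss, test_acc), `seed`, `epochs`.
#' @export
train_model <- function(x, y, cfg = model_config(), epochs = 50, lr = 1e-3,
                        batch_size = NULL, seed = 1, val_x = NULL,
                        val_y = NULL, verbose = FALSE) {
  batch_size <- batch_size %||% cfg$batch_size
  n <- dim(x)[1]
  if (length(y) != n) abort("x and y disagree on n")
  with_seed_if(seed, {
    params <- init_model_params(cfg)
    opt <- adam_init(params)
    log_rows <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      losses <- c()
      for (b0 in seq(1, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1, n)]
        Xb <- x[idx, , , drop = FALSE]
        Yb <- one_hot(y[idx], cfg$n_classes)
        fw <- model_forward(params, Xb, cfg, training = TRUE)
        loss <- cross_entropy(Yb, fw$probs)
        if (!is.finite(loss)) abort("NaN/Inf loss: training diverged")
        losses <- c(losses, loss)
        grads <- model_backward(params, fw, Yb)
        if (lr > 0) {
          st <- adam_step(params, grads, opt, lr = lr)
          params <- st$params
          opt <- st$state
        }
      }
      acc <- NA_real_
      if (!is.null(val_x)) {
        pred <- predict_classes(params, val_x, cfg)
        acc <- mean(pred == val_y)
      }
      log_rows[[ep]] <- tibble::tibble(epoch = ep,
                                       train_loss = mean(losses),
                                       test_acc = acc)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  test acc %s", ep, mean(losses),
                        ifelse(is.na(acc), "-", sprintf("%.3f", acc))))
    }
    structure(list(params = params, config = cfg,
                   runlog = dplyr::bind_rows(log_rows),
                   seed = seed, epochs = epochs, lr = lr),
              class = "pwc_fit")
  })
}

predict_classes <- function(params, x, cfg, chunk = 512L) {
  n <- dim(x)[1]
  out <- integer(n)
  for (b0 in seq(1, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1, n)
    fw <- model_forward(params, x[idx, , , drop = FALSE], cfg, training = FALSE)
    out[idx] <- max.col(fw$probs) - 1L
  }
  out
}

#' @export
print.pwc_fit <- function(x, ...) {
  last <- utils::tail(x$runlog, 1)
  cat(sprintf("<pwc_fit> %d epochs, final train loss %.4f, test acc %s\n",
              x$epochs, last$train_loss,
              ifelse(is.na(last$test_acc), "-", sprintf("%.3f", last$test_acc))))
  invisible(x)
}

#' Predict classes and probabilities for new windows
#'
#' @param object a `pwc_fit`.
#' @param newdata `n x N x 235` array or list of `beat_window`s.
#' @param ... unused.
#' @return tibble with `.pred_class`, `.prob_normal`, `.prob_abnormal`.
#' @export
predict.pwc_fit <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.array(newdata)) newdata <- windows_to_array(newdata)$x
  n <- dim(newdata)[1]
  probs <- matrix(0, n, 2)
  for (b0 in seq(1, n, by = 512L)) {
    idx <- b0:min(b0 + 511L, n)
    fw <- model_forward(object$params, newdata[idx, , , drop = FALSE],
                        object$config, training = FALSE)
    probs[idx, ] <- fw$probs
  }
  tibble::tibble(.pred_class = max.col(probs) - 1L,
                 .prob_normal = probs[, 1], .prob_abnormal = probs[, 2])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history
#'
#' @param x a `pwc_fit`.
#' @param ... unused.
#' @return the run-log tibble (epoch, train_loss, test_acc).
#' @export
tidy.pwc_fit <- function(x, ...) x$runlog

#' One-row model summary
#'
#' @param x a `pwc_fit`.
#' @param ... unused.
#' @return tibble with epochs, learning rate, final loss/accuracy and the
#'   total parameter count.
#' @export
glance.pwc_fit <- function(x, ...) {
  last <- utils::tail(x$runlog, 1)
  tibble::tibble(epochs = x$epochs, lr = x$lr,
                 unit_cycles = x$config$unit_cycles,
                 final_train_loss = last$train_loss,
                 final_test_acc = last$test_acc,
                 n_parameters = model_param_count(x$config))
}

#' @export
autoplot.pwc_fit <- function(object, ...) {
  df <- object$runlog
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$train_loss, colour = "train loss")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$test_acc, colour = "test accuracy"),
                       na.rm = TRUE) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}

# EMD + gate + segmentation once per record, reusable across window sizes
record_beats <- function(records, band = c(0.4, 20), threshold = 0.93) {
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    out[[i]] <- tryCatch({
      den <- denoise(rec, band = band)
      keep <- retention_filter(rec$samples, den, threshold)
      if (!keep) list(beats = list(), label = rec$label)
      else {
        seg <- segment_beats(den, rec$fs)
        beats <- lapply(seq_len(nrow(seg)), function(j)
          resample_beat(den[(seg$start[j] + 1):(seg$end[j])]))
        list(beats = beats, label = rec$label)
      }
    }, error = function(e) list(beats = list(), label = rec$label))
  }
  out
}

#' Unit-cycle sweep
#'
#' Re-windows the preprocessed beats for each window size `N`, retrains the
#' model and evaluates on the held-out split, reporting the five indices per
#' `N` (mean and sd over `seeds`).
#'
#' @param records list of `signal_record`s (the raw study material).
#' @param cycles window sizes to try (default 2:6).
#' @param seeds seeds to average over (default 1:3).
#' @param epochs training epochs per run.
#' @param band,threshold preprocessing settings (see [denoise()],
#'   [retention_filter()]).
#' @param lr,ratio training settings.
#' @param csv optional path: writes the per-N mean table (columns
#'   unit_cycles, acc, sen, spe, pre, f1).
#' @param verbose print progress.
#' @return list with `summary` (one row per N: mean and sd columns) and
#'   `runs` (one row per N x seed).
#' @export
unit_cycle_sweep <- function(records, cycles = 2:6, seeds = 1:3, epochs = 15,
                             band = c(0.4, 20), threshold = 0.93, lr = 1e-3,
                             ratio = 0.8, csv = NULL, verbose = FALSE) {
  rb <- record_beats(records, band, threshold)
  runs <- list()
  for (N in cycles) {
    wins <- list()
    for (r in rb) wins <- c(wins, window_beats(r$beats, r$label, n_cycles = N))
    if (length(wins) < 10) abort(sprintf("too few windows at N = %d", N))
    da <- windows_to_array(wins)
    cfg <- model_config(unit_cycles = N)
    for (sd_i in seeds) {
      sp <- split_windows(da$y, ratio = ratio, seed = sd_i)
      fit <- train_model(da$x[sp$train, , , drop = FALSE], da$y[sp$train],
                         cfg, epochs = epochs, lr = lr, seed = sd_i)
      pred <- predict_classes(fit$params, da$x[sp$test, , , drop = FALSE], cfg)
      met <- evaluate_predictions(pred, da$y[sp$test])
      runs[[length(runs) + 1]] <-
        dplyr::bind_cols(tibble::tibble(unit_cycles = N, seed = sd_i,
                                        n_windows = length(wins)), met)
      if (verbose)
        message(sprintf("N=%d seed=%d acc=%.3f", N, sd_i, met$acc))
    }
  }
  runs <- dplyr::bind_rows(runs)
  summary <- runs |>
    dplyr::group_by(.data$unit_cycles) |>
    dplyr::summarise(dplyr::across(c("acc", "sen", "spe", "pre", "f1"),
                                   list(mean = mean, sd = stats::sd)),
                     .groups = "drop")
  if (!is.null(csv)) {
    tab <- summary |>
      dplyr::transmute(unit_cycles = .data$unit_cycles,
                       acc = .data$acc_mean, sen = .data$sen_mean,
                       spe = .data$spe_mean, pre = .data$pre_mean,
                       f1 = .data$f1_mean)
    utils::write.csv(as.data.frame(tab), csv, row.names = FALSE)
  }
  list(summary = summary, runs = runs)
}

#' Plot a unit-cycle sweep
#'
#' @param sweep result of [unit_cycle_sweep()].
#' @return a ggplot of mean accuracy (with +/- 1 sd ribbon) against N.
#' @export
plot_sweep <- function(sweep) {
  df <- sweep$summary
  ggplot2::ggplot(df, ggplot2::aes(.data$unit_cycles, .data$acc_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$acc_mean - .data$acc_sd,
                                      ymax = .data$acc_mean + .data$acc_sd),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "unit cycles N", y = "test accuracy")
}

#' The standard synthetic classification task
#'
#' The package's reference study conditions: a balanced two-class dataset of
#' wrist-pressure-like records (moderate "cnbp" noise, 200 Hz, ~57 beats per
#' record, heart rates 60-90 bpm), preprocessed through EMD denoising, the
#' 0.93 Pearson gate, trough segmentation and 5-beat windowing.
#'
#' @param seed master seed.
#' @param n_per_class records per class (default 40, giving roughly 400+
#'   windows per class at N = 5).
#' @param n_beats beats per record.
#' @param noise a [noise_spec()] (default the `"cnbp"` preset).
#' @param n_cycles beats per window.
#' @return list with `x` (window array), `y` (labels), `provenance`,
#'   `records`.
#' @export
standard_task <- function(seed = 1, n_per_class = 40, n_beats = 57,
                          noise = noise_preset("cnbp"), n_cycles = 5) {
  ds <- make_dataset(n_per_class, n_beats = n_beats, fs = 200,
                     noise = noise, seed = seed)
  pp <- preprocess_records(ds$records, n_cycles = n_cycles)
  da <- windows_to_array(pp$windows)
  list(x = da$x, y = da$y, provenance = pp$provenance, records = ds$records)
}
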