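#' Chronological train/test split indices
#'
#' The first `split` fraction of the windows forms the training partition and
#' the remainder the test partition; test rows are strictly after training
#' rows (no shuffling: the data are a time series).
#'
#' @param n number of rows.
#' @param split training fraction in (0, 1), default 0.9.
#' @return list with integer vectors `train` and `test`.
#' @export
chrono_split <- function(n, split = 0.9) {
  if (split <= 0 || split >= 1) stop("split must lie in (0, 1)", call. = FALSE)
  n_tr <- floor(split * n)
  if (n_tr < 2 || n_tr >= n) stop("split leaves an empty partition", call. = FALSE)
  list(train = seq_len(n_tr), test = (n_tr + 1):n)
}

# Fit one model on a screened, standardized feature table and evaluate on
# the chronological test rows. Shared by both experiments so that every
# model within a comparison sees identical split indices, GRA mask and
# scaler statistics.
fit_and_score <- function(table, model, seed, split = 0.9, top_k = 10,
                          rho = 0.5, lstm_hidden = 100, lstm_lr = 0.005,
                          lstm_epochs = 250, igwo_pack = 10, igwo_iters = 20,
                          igwo_epochs = 300, fitness_epochs = 30,
                          igwo_fitness = "val", prepared = NULL) {
  prep <- if (is.null(prepared)) {
    prepare_cell(table, split = split, top_k = top_k, rho = rho)
  } else prepared

  Xtr <- prep$X[prep$idx$train, , drop = FALSE]
  ytr <- prep$y_std[prep$idx$train]
  Xte <- prep$X[prep$idx$test, , drop = FALSE]
  yte_raw <- table$target[prep$idx$test]

  pred_std <- switch(model,
    "lstm" = {
      m <- mmg_lstm(Xtr, ytr, hidden = lstm_hidden, lr = lstm_lr,
                    epochs = lstm_epochs, seed = seed)
      predict(m, Xte)
    },
    "igwo-lstm" = {
      tuned <- tune_lstm(Xtr, ytr, pack_size = igwo_pack, iters = igwo_iters,
                         seed = seed, fitness = igwo_fitness,
                         fitness_epochs = fitness_epochs, epochs = igwo_epochs)
      predict(tuned$model, Xte)
    },
    "bpnn" = {
      m <- mmg_bpnn(Xtr, ytr, seed = seed)
      predict(m, Xte)
    },
    "igwo-svr" = {
      tuned <- tune_svr(Xtr, ytr, pack_size = igwo_pack, iters = igwo_iters,
                        seed = seed)
      predict(tuned$model, Xte)
    },
    stop("unknown model: ", model, call. = FALSE)
  )
  y_hat <- pred_std * prep$y_stats$sd + prep$y_stats$mean
  evaluate_force(y_hat, yte_raw)
}

# Screen + standardize once per (table, split): the expensive, model-agnostic
# part of a comparison cell.
prepare_cell <- function(table, split = 0.9, top_k = 10, rho = 0.5) {
  idx <- chrono_split(nrow(table$X), split)
  sc <- screen_features(table, rho = rho, top_k = top_k, train_idx = idx$train)
  Xsel <- table$X[, sc$mask, drop = FALSE]
  st <- zscore_fit(Xsel[idx$train, , drop = FALSE])
  X <- zscore_apply(Xsel, st)
  ymu <- mean(table$target[idx$train])
  ysd <- sqrt(mean((table$target[idx$train] - ymu)^2))
  if (ysd <= 0) stop("constant force target on the training rows", call. = FALSE)
  list(X = X, y_std = (table$target - ymu) / ysd,
       y_stats = list(mean = ymu, sd = ysd),
       idx = idx, screen = sc, scaler = st)
}

#' Compare feature combinations F1--F7
#'
#' For each recording, feature combination and seed: build the windowed
#' feature table for the combination's channels, screen features by grey
#' relational grade on the training rows, Z-score with training statistics,
#' train an LSTM with fixed hyper-parameters (hidden 100, learning rate
#' 0.005, 250 epochs by default) and evaluate NRMSE/MAPE/R on the
#' chronological test rows. A failure in one cell is recorded (NA metrics
#' plus the error message) without aborting the experiment.
#'
#' @param recordings list of preprocessed `mmg_recording` objects (or a
#'   single recording).
#' @param combinations subset of `c("F1", ..., "F7")`.
#' @param seeds integer vector of model-initialization seeds.
#' @param spec a [window_spec()] (defaults to the recording's sampling rate).
#' @param split training fraction (default 0.9).
#' @param top_k,rho GRA screening settings.
#' @param hidden,lr,epochs fixed LSTM hyper-parameters.
#' @return an `mmg_experiment` data frame with one row per
#'   (recording, combination, seed): metrics and provenance.
#' @export
run_combination_experiment <- function(recordings,
                                       combinations = paste0("F", 1:7),
                                       seeds = 1:5,
                                       spec = NULL, split = 0.9,
                                       top_k = 10, rho = 0.5,
                                       hidden = 100, lr = 0.005, epochs = 250) {
  if (inherits(recordings, "mmg_recording")) recordings <- list(recordings)
  if (length(combinations) == 0) stop("combinations must be non-empty", call. = FALSE)
  if (length(seeds) == 0) stop("seeds must be non-empty", call. = FALSE)
  rows <- list()
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    wspec <- if (is.null(spec)) window_spec(fs = rec$fs) else spec
    # each channel's features are computed once and sliced per combination;
    # unknown labels surface later as per-cell failures
    chans <- unique(unlist(lapply(combinations, function(cm) {
      if (grepl("^F[1-7]$", cm)) feature_combination(cm) else cm
    })))
    chans <- intersect(chans, names(rec$channels))
    if (length(chans) == 0) {
      stop("no requested channel exists in the recording", call. = FALSE)
    }
    full <- build_feature_table(rec, channels = chans, spec = wspec)
    for (combo in combinations) {
      cell <- tryCatch({
        table <- subset_channels(full, combo)
        prep <- prepare_cell(table, split = split, top_k = top_k, rho = rho)
        lapply(seeds, function(sd) {
          ev <- fit_and_score(table, "lstm", seed = sd, split = split,
                              top_k = top_k, rho = rho, lstm_hidden = hidden,
                              lstm_lr = lr, lstm_epochs = epochs,
                              prepared = prep)
          data.frame(recording = ri, combination = combo, model = "lstm",
                     seed = sd, nrmse = ev$nrmse, mape = ev$mape, r = ev$r,
                     error = NA_character_, stringsAsFactors = FALSE)
        })
      }, error = function(e) {
        lapply(seeds, function(sd) {
          data.frame(recording = ri, combination = combo, model = "lstm",
                     seed = sd, nrmse = NA_real_, mape = NA_real_,
                     r = NA_real_, error = conditionMessage(e),
                     stringsAsFactors = FALSE)
        })
      })
      rows <- c(rows, cell)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(split = split, top_k = top_k, rho = rho,
                              hidden = hidden, lr = lr, epochs = epochs,
                              seeds = seeds)
  class(out) <- c("mmg_experiment", "data.frame")
  out
}

#' Compare estimation models on a fixed feature combination
#'
#' Trains and evaluates the requested models (`bpnn`, `igwo-svr`, `lstm`,
#' `igwo-lstm`) on identical data: within one (recording, seed) cell all
#' models share the same chronological split, GRA mask and scaler statistics
#' (the fairness invariant). The fixed LSTM uses hidden 100 / lr 0.005 /
#' 250 epochs; the IGWO-tuned LSTM searches hidden in [50, 400] and lr in
#' [0.001, 0.01] with a pack of `igwo_pack` wolves for `igwo_iters`
#' iterations and trains the final model for `igwo_epochs` (300) epochs.
#' `fitness_epochs` caps the training length inside each tuning evaluation;
#' reduce it to cut the search cost.
#'
#' @inheritParams run_combination_experiment
#' @param combination the feature combination all models share (default
#'   `"F2"`).
#' @param models subset of `c("bpnn", "igwo-svr", "lstm", "igwo-lstm")`.
#' @param igwo_pack,igwo_iters IGWO budget (defaults 10 and 20).
#' @param igwo_epochs final training epochs of the tuned LSTM (default 300).
#' @param fitness_epochs epochs per tuning evaluation (default 30).
#' @param igwo_fitness `"val"` (default) or `"train"` tuning fitness.
#' @return an `mmg_experiment` data frame, one row per
#'   (recording, model, seed).
#' @export
run_model_comparison <- function(recordings, combination = "F2",
                                 models = c("bpnn", "igwo-svr", "lstm",
                                            "igwo-lstm"),
                                 seeds = 1:5, spec = NULL, split = 0.9,
                                 top_k = 10, rho = 0.5,
                                 hidden = 100, lr = 0.005, epochs = 250,
                                 igwo_pack = 10, igwo_iters = 20,
                                 igwo_epochs = 300, fitness_epochs = 30,
                                 igwo_fitness = "val") {
  if (inherits(recordings, "mmg_recording")) recordings <- list(recordings)
  if (length(models) == 0) stop("models must be non-empty", call. = FALSE)
  rows <- list()
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    wspec <- if (is.null(spec)) window_spec(fs = rec$fs) else spec
    table <- build_feature_table(rec, channels = combination, spec = wspec)
    prep <- prepare_cell(table, split = split, top_k = top_k, rho = rho)
    for (sd in seeds) {
      for (model in models) {
        row <- tryCatch({
          ev <- fit_and_score(table, model, seed = sd, split = split,
                              top_k = top_k, rho = rho, lstm_hidden = hidden,
                              lstm_lr = lr, lstm_epochs = epochs,
                              igwo_pack = igwo_pack, igwo_iters = igwo_iters,
                              igwo_epochs = igwo_epochs,
                              fitness_epochs = fitness_epochs,
                              igwo_fitness = igwo_fitness, prepared = prep)
          data.frame(recording = ri, combination = combination, model = model,
                     seed = sd, nrmse = ev$nrmse, mape = ev$mape, r = ev$r,
                     error = NA_character_, stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(recording = ri, combination = combination, model = model,
                     seed = sd, nrmse = NA_real_, mape = NA_real_,
                     r = NA_real_, error = conditionMessage(e),
                     stringsAsFactors = FALSE)
        })
        rows <- c(rows, list(row))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(combination = combination, models = models,
                              split = split, top_k = top_k, rho = rho,
                              igwo_pack = igwo_pack, igwo_iters = igwo_iters,
                              igwo_epochs = igwo_epochs,
                              fitness_epochs = fitness_epochs, seeds = seeds)
  class(out) <- c("mmg_experiment", "data.frame")
  out
}

#' Aggregate an experiment into a mean +/- SD table
#'
#' Rows are feature combinations or models (whichever the experiment varied);
#' columns are the mean and standard deviation of NRMSE, MAPE and R over all
#' (recording, seed) runs. The SD of a single run is 0 and flagged in the
#' `n_runs` column.
#'
#' @param report an `mmg_experiment`.
#' @param by `"combination"` or `"model"` (default: whichever varies).
#' @return a data frame with one row per group.
#' @export
report_to_table <- function(report, by = NULL) {
  stopifnot(inherits(report, "mmg_experiment"))
  if (nrow(report) == 0) stop("empty report", call. = FALSE)
  if (is.null(by)) {
    by <- if (length(unique(report$combination)) > 1) "combination" else "model"
  }
  groups <- split(as.data.frame(report), report[[by]])
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    ok <- !is.na(d$nrmse)
    agg <- function(v) {
      if (!any(ok)) return(c(NA_real_, NA_real_))
      c(mean(v[ok]), if (sum(ok) > 1) stats::sd(v[ok]) else 0)
    }
    nr <- agg(d$nrmse); mp <- agg(d$mape); rr <- agg(d$r)
    data.frame(group = g, n_runs = sum(ok),
               nrmse_mean = nr[1], nrmse_sd = nr[2],
               mape_mean = mp[1], mape_sd = mp[2],
               r_mean = rr[1], r_sd = rr[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- by
  out
}

#' Write an aggregated experiment table to CSV and JSON
#'
#' @param table a data frame from [report_to_table()].
#' @param dir output directory (created if missing).
#' @param name file stem (default "report").
#' @return named character vector of the written paths, invisibly.
#' @export
write_report <- function(table, dir, name = "report") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  js <- file.path(dir, paste0(name, ".json"))
  utils::write.csv(table, csv, row.names = FALSE)
  jsonlite::write_json(table, js, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE)
  invisible(c(csv = csv, json = js))
}

#' @export
print.mmg_experiment <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("MMG experiment: %d runs (%d failed)\n",
              nrow(x), sum(!is.na(x$error))))
  print(report_to_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}
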