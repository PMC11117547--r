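#' Hyper-parameter search space
#'
#' Axis-aligned box with per-dimension names, bounds and types. Integer
#' dimensions are kept continuous inside the optimizer and rounded only when
#' a position is decoded for evaluation.
#'
#' @param names character vector of dimension names.
#' @param lower,upper numeric bounds, `lower < upper` elementwise.
#' @param integer logical vector: round this dimension on evaluation.
#' @return an object of class `search_space`.
#' @examples
#' lstm_search_space()
#' @export
search_space <- function(names, lower, upper, integer = FALSE) {
  k <- length(names)
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  integer <- rep_len(integer, k)
  if (any(lower >= upper)) stop("require lower < upper", call. = FALSE)
  structure(list(names = names, lower = lower, upper = upper,
                 integer = integer, k = k), class = "search_space")
}

#' Default LSTM hyper-parameter space
#'
#' Hidden layer size in [50, 400] (integer) and initial learning rate in
#' [0.001, 0.01].
#'
#' @return a [search_space()].
#' @export
lstm_search_space <- function() {
  search_space(c("hidden", "lr"), lower = c(50, 0.001), upper = c(400, 0.01),
               integer = c(TRUE, FALSE))
}

#' Default SVR hyper-parameter space
#'
#' Penalty `C` in [0.1, 100] (searched on a log scale when `log_C = TRUE`)
#' and RBF width `sigma` in [0.1, 10].
#'
#' @param log_C search `C` on a log10 scale.
#' @return a [search_space()] with a `log` attribute consumed by
#'   [decode_position()].
#' @export
svr_search_space <- function(log_C = TRUE) {
  if (log_C) {
    sp <- search_space(c("log10C", "sigma"), lower = c(-1, 0.1),
                       upper = c(2, 10))
    attr(sp, "log_dims") <- "log10C"
    sp
  } else {
    search_space(c("C", "sigma"), lower = c(0.1, 0.1), upper = c(100, 10))
  }
}

#' Decode an optimizer position into named hyper-parameters
#'
#' Clamps to the bounds, rounds integer dimensions and exponentiates
#' log-scale dimensions (names starting `log10`).
#'
#' @param position numeric vector in search-space coordinates.
#' @param space a [search_space()].
#' @return named list of decoded values.
#' @export
decode_position <- function(position, space) {
  stopifnot(inherits(space, "search_space"))
  p <- pmin(pmax(position, space$lower), space$upper)
  out <- as.list(p)
  names(out) <- space$names
  for (j in seq_len(space$k)) {
    if (space$integer[j]) out[[j]] <- as.integer(round(out[[j]]))
    if (startsWith(space$names[j], "log10")) {
      names(out)[j] <- sub("^log10", "", space$names[j])
      out[[j]] <- 10^out[[j]]
    }
  }
  out
}

# Shared engine for the canonical grey wolf optimizer and its improved
# variant. The three improvements are independently toggleable; with all of
# them off the code path (and hence the RNG stream) is identical to the
# canonical algorithm, so igwo(...) with flags off reproduces gwo(...)
# bit for bit at the same seed.
gwo_engine <- function(fitness, space, pack_size, iters, seed,
                       chaotic_init = FALSE, cosine_a = FALSE, greedy = FALSE) {
  stopifnot(inherits(space, "search_space"))
  if (pack_size < 4) stop("pack_size must be >= 4", call. = FALSE)
  if (iters < 1) stop("iters must be >= 1", call. = FALSE)
  k <- space$k
  lo <- space$lower; up <- space$upper
  set.seed(seed)

  evals <- 0L
  eval_fit <- function(pos) {
    val <- fitness(pos)
    evals <<- evals + 1L
    if (!is.numeric(val) || length(val) != 1) {
      stop("fitness must return a single number", call. = FALSE)
    }
    val
  }

  # initial pack
  if (chaotic_init) {
    # tent-map chaotic sequence per dimension, seeded from one uniform draw
    u <- stats::runif(k)
    X <- matrix(0, pack_size, k)
    for (j in seq_len(k)) {
      z <- u[j]
      for (i in seq_len(pack_size)) {
        z <- if (z < 0.5) 2 * z else 2 * (1 - z)
        # keep the orbit away from the fixed points
        if (z < 1e-6 || z > 1 - 1e-6) z <- stats::runif(1)
        X[i, j] <- lo[j] + z * (up[j] - lo[j])
      }
    }
  } else {
    X <- matrix(stats::runif(pack_size * k, rep(lo, each = pack_size),
                             rep(up, each = pack_size)), pack_size, k)
  }

  fit <- numeric(pack_size)
  for (i in seq_len(pack_size)) {
    fit[i] <- eval_fit(X[i, ])
    if (!is.finite(fit[i])) {
      # re-sample a wolf whose fitness is non-finite
      X[i, ] <- lo + stats::runif(k) * (up - lo)
      fit[i] <- eval_fit(X[i, ])
      if (!is.finite(fit[i])) fit[i] <- Inf
    }
  }

  ord <- order(fit)
  alpha <- X[ord[1], ]; beta <- X[ord[2], ]; delta <- X[ord[3], ]
  f_alpha <- fit[ord[1]]; f_beta <- fit[ord[2]]; f_delta <- fit[ord[3]]
  trace <- numeric(iters + 1)
  trace[1] <- f_alpha
  fit_history <- matrix(NA_real_, iters + 1, pack_size)
  fit_history[1, ] <- fit

  for (t in seq_len(iters)) {
    a <- if (cosine_a) 2 * cos(pi * t / (2 * iters)) else 2 - 2 * t / iters
    for (i in seq_len(pack_size)) {
      xnew <- numeric(k)
      leaders <- list(alpha, beta, delta)
      acc <- 0
      for (L in leaders) {
        r1 <- stats::runif(k); r2 <- stats::runif(k)
        A <- 2 * a * r1 - a
        C <- 2 * r2
        D <- abs(C * L - X[i, ])
        acc <- acc + (L - A * D)
      }
      xnew <- acc / 3
      xnew <- pmin(pmax(xnew, lo), up)
      fnew <- eval_fit(xnew)
      if (!is.finite(fnew)) {
        xnew <- lo + stats::runif(k) * (up - lo)
        fnew <- eval_fit(xnew)
        if (!is.finite(fnew)) fnew <- Inf
      }
      if (greedy && fnew > fit[i]) {
        # keep the old position: per-wolf fitness is non-increasing
      } else {
        X[i, ] <- xnew
        fit[i] <- fnew
      }
      if (fit[i] < f_alpha) {
        delta <- beta; f_delta <- f_beta
        beta <- alpha; f_beta <- f_alpha
        alpha <- X[i, ]; f_alpha <- fit[i]
      } else if (fit[i] < f_beta) {
        delta <- beta; f_delta <- f_beta
        beta <- X[i, ]; f_beta <- fit[i]
      } else if (fit[i] < f_delta) {
        delta <- X[i, ]; f_delta <- fit[i]
      }
    }
    trace[t + 1] <- f_alpha
    fit_history[t + 1, ] <- fit
  }

  structure(list(best = alpha, best_fitness = f_alpha, trace = trace,
                 evaluations = evals, pack = X, pack_fitness = fit,
                 fit_history = fit_history,
                 leaders = list(alpha = alpha, beta = beta, delta = delta),
                 leader_fitness = c(alpha = f_alpha, beta = f_beta,
                                    delta = f_delta),
                 space = space, seed = seed,
                 variant = c(chaotic_init = chaotic_init, cosine_a = cosine_a,
                             greedy = greedy)),
            class = "gwo_result")
}

#' Grey wolf optimizer
#'
#' Canonical GWO minimization: a pack of candidate solutions is guided by its
#' three best members (alpha, beta, delta). At iteration t with convergence
#' factor `a(t)` decreasing linearly from 2 to 0, each wolf moves to the mean
#' of three leader-encircling positions `X_L - A_L |C_L X_L - X|` with
#' `A = 2 a r1 - a`, `C = 2 r2`, clamped to the bounds. Non-finite fitness
#' values cause the wolf to be re-sampled within bounds. Deterministic given
#' `seed` when `fitness` is deterministic.
#'
#' @param fitness function mapping a numeric position (in search-space
#'   coordinates) to a scalar to minimize.
#' @param space a [search_space()].
#' @param pack_size number of wolves (>= 4, default 10).
#' @param iters number of iterations (default 20).
#' @param seed integer seed.
#' @return an object of class `gwo_result`: `best`, `best_fitness`, `trace`
#'   (best-so-far fitness, length `iters + 1` including the initial pack),
#'   `evaluations`, `fit_history` (per-wolf fitness per iteration), final
#'   pack state.
#' @seealso [igwo()]
#' @export
gwo <- function(fitness, space, pack_size = 10, iters = 20, seed = 1L) {
  gwo_engine(fitness, space, pack_size, iters, seed)
}

#' Improved grey wolf optimizer
#'
#' [gwo()] augmented with three independently toggleable improvements
#' addressing the canonical algorithm's slow early convergence and late-stage
#' stagnation: tent-map chaotic initialization (better initial coverage), a
#' nonlinear cosine convergence factor `a(t) = 2 cos(pi t / (2 iters))`
#' (longer exploration phase), and greedy per-wolf selection (a wolf only
#' accepts a move that improves its fitness). With all flags off the result
#' is bit-identical to [gwo()] at the same seed.
#'
#' @inheritParams gwo
#' @param chaotic_init,cosine_a,greedy enable the respective improvement.
#' @return a `gwo_result`.
#' @export
igwo <- function(fitness, space, pack_size = 10, iters = 20, seed = 1L,
                 chaotic_init = TRUE, cosine_a = TRUE, greedy = TRUE) {
  gwo_engine(fitness, space, pack_size, iters, seed,
             chaotic_init = chaotic_init, cosine_a = cosine_a, greedy = greedy)
}

#' @export
print.gwo_result <- function(x, ...) {
  v <- x$variant
  lab <- if (any(v)) paste0("IGWO(", paste(names(v)[v], collapse = ","), ")") else "GWO"
  cat(sprintf("%s: best fitness %.6g after %d evaluations\n",
              lab, x$best_fitness, x$evaluations))
  best <- decode_position(x$best, x$space)
  cat("  best position:", paste(sprintf("%s = %.4g", names(best),
                                        unlist(best)), collapse = ", "), "\n")
  invisible(x)
}

#' Tune LSTM hyper-parameters with the improved grey wolf optimizer
#'
#' Searches the hyper-parameter box (by default hidden units in [50, 400] and
#' learning rate in [0.001, 0.01]) by minimizing the RMSE of an LSTM trained
#' at the decoded position. With `fitness = "train"` the fitness is the
#' training-output RMSE; `fitness = "val"` holds out the last 20% of the
#' training rows and scores on them, which avoids the capacity-maximizing
#' degeneracy of pure training fitness and is the recommended mode. Every
#' evaluation trains from the same weight-initialization seed so wolves are
#' compared fairly; training divergence is penalized with `+Inf` fitness.
#'
#' @param x,y standardized training features (`T x D`) and targets.
#' @param space a [search_space()]; default [lstm_search_space()].
#' @param pack_size,iters,seed optimizer budget and seed.
#' @param fitness `"train"` or `"val"`.
#' @param fitness_epochs training epochs used inside each fitness evaluation
#'   (default 300; lower it to cut the search cost).
#' @param epochs max epochs of the final model trained at the tuned
#'   configuration (default 300).
#' @param clip gradient clipping norm.
#' @param optimizer `"igwo"` (default) or `"gwo"`.
#' @return list with `config` (named list: hidden, lr, epochs, seed),
#'   `model` (the final `mmg_lstm` retrained on all of `x`), and `result`
#'   (the `gwo_result`).
#' @export
tune_lstm <- function(x, y, space = lstm_search_space(), pack_size = 10,
                      iters = 20, seed = 1L, fitness = c("train", "val"),
                      fitness_epochs = 300, epochs = 300, clip = 1,
                      optimizer = c("igwo", "gwo")) {
  fitness <- match.arg(fitness)
  optimizer <- match.arg(optimizer)
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (fitness == "val") {
    n_tr <- max(2, floor(0.8 * n))
    itr <- seq_len(n_tr); ival <- (n_tr + 1):n
  }
  fit_fun <- function(pos) {
    hp <- decode_position(pos, space)
    out <- tryCatch({
      if (fitness == "train") {
        m <- mmg_lstm(x, y, hidden = hp$hidden, lr = hp$lr,
                      epochs = fitness_epochs, seed = seed, clip = clip)
        m$final_rmse
      } else {
        m <- mmg_lstm(x[itr, , drop = FALSE], y[itr], hidden = hp$hidden,
                      lr = hp$lr, epochs = fitness_epochs, seed = seed,
                      clip = clip)
        pv <- predict(m, x[ival, , drop = FALSE])
        sqrt(mean((pv - y[ival])^2))
      }
    }, error = function(e) Inf)
    out
  }
  opt_fun <- if (optimizer == "igwo") igwo else gwo
  res <- opt_fun(fit_fun, space, pack_size = pack_size, iters = iters,
                 seed = seed)
  hp <- decode_position(res$best, space)
  model <- mmg_lstm(x, y, hidden = hp$hidden, lr = hp$lr, epochs = epochs,
                    seed = seed, clip = clip)
  list(config = list(hidden = hp$hidden, lr = hp$lr, epochs = epochs,
                     seed = seed),
       model = model, result = res)
}

#' Tune SVR hyper-parameters with the improved grey wolf optimizer
#'
#' Searches `(C, sigma)` (C on a log scale by default) by minimizing the
#' RMSE of an epsilon-SVR at the decoded position, with the same
#' train/validation fitness modes as [tune_lstm()].
#'
#' @inheritParams tune_lstm
#' @param space a [search_space()]; default [svr_search_space()].
#' @param epsilon epsilon-tube half width of every fitted SVR.
#' @return list with `config` (C, sigma, epsilon), `model` (final
#'   `mmg_svr`), `result`.
#' @export
tune_svr <- function(x, y, space = svr_search_space(), pack_size = 10,
                     iters = 20, seed = 1L, fitness = c("val", "train"),
                     epsilon = 0.1, optimizer = c("igwo", "gwo")) {
  fitness <- match.arg(fitness)
  optimizer <- match.arg(optimizer)
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  n_tr <- max(2, floor(0.8 * n))
  itr <- seq_len(n_tr); ival <- (n_tr + 1):n
  fit_fun <- function(pos) {
    hp <- decode_position(pos, space)
    tryCatch({
      if (fitness == "train") {
        m <- mmg_svr(x, y, C = hp$C, sigma = hp$sigma, epsilon = epsilon)
        sqrt(mean((m$fitted - y)^2))
      } else {
        m <- mmg_svr(x[itr, , drop = FALSE], y[itr], C = hp$C,
                     sigma = hp$sigma, epsilon = epsilon)
        pv <- predict(m, x[ival, , drop = FALSE])
        sqrt(mean((pv - y[ival])^2))
      }
    }, error = function(e) Inf)
  }
  opt_fun <- if (optimizer == "igwo") igwo else gwo
  res <- opt_fun(fit_fun, space, pack_size = pack_size, iters = iters,
                 seed = seed)
  hp <- decode_position(res$best, space)
  model <- mmg_svr(x, y, C = hp$C, sigma = hp$sigma, epsilon = epsilon)
  list(config = list(C = hp$C, sigma = hp$sigma, epsilon = epsilon),
       model = model, result = res)
}
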