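#' Hyperparameters of the single-hidden-layer estimator network
#'
#' The admissible box: 2-20 hidden neurons, learning rate 0.0005-1, and
#' 500-1000 training epochs. The network is trained with full-batch
#' Levenberg-Marquardt updates; LM has no classical learning rate, so the
#' learning rate is mapped to the initial damping factor `mu0 = 1 /
#' learning_rate` (large rates start near Gauss-Newton, small rates near
#' gradient descent).
#'
#' @param n_hidden Hidden-layer width (integer in \[2, 20\]).
#' @param learning_rate In \[0.0005, 1\].
#' @param epochs Maximum training epochs (integer in \[500, 1000\]).
#' @return Object of class `ann_hyperparams`.
#' @export
ann_hyperparams <- function(n_hidden = 10L, learning_rate = 0.01,
                            epochs = 500L) {
  box <- ann_box()
  n_hidden <- as.integer(round(n_hidden))
  epochs <- as.integer(round(epochs))
  if (n_hidden < box$n_hidden[1] || n_hidden > box$n_hidden[2]) {
    stop("n_hidden outside [", box$n_hidden[1], ", ", box$n_hidden[2], "]")
  }
  if (learning_rate < box$learning_rate[1] || learning_rate > box$learning_rate[2]) {
    stop("learning_rate outside its admissible range")
  }
  if (epochs < box$epochs[1] || epochs > box$epochs[2]) {
    stop("epochs outside [", box$epochs[1], ", ", box$epochs[2], "]")
  }
  structure(list(n_hidden = n_hidden, learning_rate = learning_rate,
                 epochs = epochs), class = "ann_hyperparams")
}

#' The hyperparameter search box
#' @return Named list of `c(min, max)` per hyperparameter.
#' @export
ann_box <- function() {
  list(n_hidden = c(2L, 20L), learning_rate = c(0.0005, 1),
       epochs = c(500L, 1000L))
}

ann_unpack <- function(theta, p, h) {
  W1 <- matrix(theta[seq_len(h * p)], h, p)
  b1 <- theta[h * p + seq_len(h)]
  W2 <- theta[h * p + h + seq_len(h)]
  b2 <- theta[h * p + 2 * h + 1]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

ann_forward <- function(Xs, pars) {
  Z <- tanh(sweep(Xs %*% t(pars$W1), 2, pars$b1, "+"))
  list(Z = Z, yhat = as.numeric(Z %*% pars$W2 + pars$b2))
}

#' Train a single-hidden-layer network with Levenberg-Marquardt updates
#'
#' Hyperbolic-tangent hidden units, linear output. Inputs and the target
#' are standardised internally; the stored scalers make predictions return
#' on the original scale. Training is full-batch LM with adaptive damping:
#' a step is accepted when it reduces the sum of squared residuals,
#' otherwise the damping is increased (never a crash on singular normal
#' equations). Stops at the minimum-gradient threshold, the epoch cap, or
#' when damping saturates; the stop reason is recorded. Deterministic for a
#' fixed seed.
#'
#' @param X n x p feature matrix.
#' @param y Length-n target.
#' @param hp An [ann_hyperparams()].
#' @param seed Integer seed (weight initialisation).
#' @param grad_tol Minimum-gradient stopping threshold on the infinity norm
#'   of the loss gradient (standardised scale).
#' @return Object of class `ann_model` with the affine maps, scalers,
#'   `train_mse` (original scale), `epochs_run`, `stop_reason`,
#'   `fitted` values and the hyperparameters.
#' @export
train_ann <- function(X, y, hp = ann_hyperparams(), seed = 1L,
                      grad_tol = 1e-7) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X); h <- hp$n_hidden
  if (n <= h) stop("need more samples than hidden units")
  centre <- colMeans(X)
  scl <- apply(X, 2, stats::sd); scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, centre, "-"), 2, scl, "/")
  y_c <- mean(y); y_s <- stats::sd(y); if (!is.finite(y_s) || y_s < 1e-12) y_s <- 1
  ys <- (y - y_c) / y_s
  local_rng_seed(child_seed(seed, "ann-init"))
  theta <- c(stats::rnorm(h * p, 0, 1 / sqrt(p)), rep(0, h),
             stats::rnorm(h, 0, 1 / sqrt(h)), 0)
  k <- length(theta)
  mu <- 1 / hp$learning_rate
  loss <- function(theta) {
    fw <- ann_forward(Xs, ann_unpack(theta, p, h))
    sum((fw$yhat - ys)^2)
  }
  cur <- loss(theta)
  if (!is.finite(cur)) stop("non-finite loss at epoch 0")
  stop_reason <- "max_epochs"
  epoch <- 0L
  while (epoch < hp$epochs) {
    epoch <- epoch + 1L
    pars <- ann_unpack(theta, p, h)
    fw <- ann_forward(Xs, pars)
    r <- fw$yhat - ys
    dZ <- 1 - fw$Z^2 # n x h
    # Jacobian of predictions wrt theta: [W1 (h x p, column-major) | b1 |
    # W2 | b2], built blockwise without per-neuron loops
    G <- sweep(dZ, 2, pars$W2, "*") # n x h, dyhat/d(pre-activation_j)
    J <- cbind(G[, rep(seq_len(h), p), drop = FALSE] *
                 Xs[, rep(seq_len(p), each = h), drop = FALSE], # W1
               G, # b1
               fw$Z, # W2
               1) # b2
    g <- as.numeric(crossprod(J, r))
    if (max(abs(g)) / n < grad_tol) {
      stop_reason <- "min_gradient"
      break
    }
    # LM step; when parameters outnumber samples use the dual (n x n) form
    # of the damped normal equations (push-through identity), which is
    # algebraically identical and much cheaper
    dual <- k > n
    JtJ <- if (dual) tcrossprod(J) else crossprod(J)
    accepted <- FALSE
    for (tries in 1:30) {
      step <- try(if (dual) {
        -as.numeric(crossprod(J, solve(JtJ + diag(mu, n), r)))
      } else {
        solve(JtJ + diag(mu, k), -g)
      }, silent = TRUE)
      if (!inherits(step, "try-error")) {
        cand <- theta + as.numeric(step)
        new <- loss(cand)
        if (!is.finite(new)) stop("non-finite loss at epoch ", epoch)
        if (new < cur) {
          theta <- cand; cur <- new
          mu <- max(mu / 10, 1e-12)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
      if (mu > 1e12) break
    }
    if (!accepted) {
      stop_reason <- "damping_limit"
      break
    }
  }
  pars <- ann_unpack(theta, p, h)
  fitted_s <- ann_forward(Xs, pars)$yhat
  fitted <- fitted_s * y_s + y_c
  structure(list(
    W1 = pars$W1, b1 = pars$b1, W2 = pars$W2, b2 = pars$b2,
    input_scaler = list(centre = centre, scale = scl),
    target_scaler = list(centre = y_c, scale = y_s),
    hp = hp, seed = as.integer(seed),
    epochs_run = epoch, stop_reason = stop_reason,
    train_mse = mean((fitted - y)^2),
    fitted = fitted, n_features = p
  ), class = "ann_model")
}

#' Predict from a trained estimator network
#'
#' @param model An [train_ann()] model.
#' @param X Feature matrix with the same columns as at training time.
#' @return Numeric predictions on the original target scale.
#' @export
predict_ann <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop(sprintf("feature count mismatch: model expects %d, got %d",
                 model$n_features, ncol(X)))
  }
  Xs <- sweep(sweep(X, 2, model$input_scaler$centre, "-"),
              2, model$input_scaler$scale, "/")
  fw <- ann_forward(Xs, model)
  fw$yhat * model$target_scaler$scale + model$target_scaler$centre
}

#' @export
predict.ann_model <- function(object, newdata, ...) predict_ann(object, newdata)

#' @method tidy ann_model
#' @export
tidy.ann_model <- function(x, ...) {
  tibble::tibble(
    term = c("n_hidden", "learning_rate", "epochs"),
    value = c(x$hp$n_hidden, x$hp$learning_rate, x$hp$epochs)
  )
}

#' @method glance ann_model
#' @export
glance.ann_model <- function(x, ...) {
  tibble::tibble(train_mse = x$train_mse, epochs_run = x$epochs_run,
                 stop_reason = x$stop_reason, n_hidden = x$hp$n_hidden)
}

#' Worst-fold cross-validation objective
#'
#' Partitions the pooled samples into `k` near-equal random folds (seeded),
#' trains on the complement of each fold, and returns the *maximum* of the
#' per-fold mean squared errors together with the per-fold results. A
#' conservative objective: the hyperparameters are judged by their worst
#' validation fold, not the average.
#'
#' @param X,y Pooled training samples.
#' @param hp An [ann_hyperparams()].
#' @param seed Integer seed (fold assignment and network initialisation).
#' @param k Number of folds (default 5).
#' @param grad_tol Passed to [train_ann()].
#' @param sample_max Optional seeded row subsample applied before folding
#'   (a tuning-budget control; `Inf` disables it).
#' @return List with `f_obj` (the scalar objective) and `folds`, a tibble
#'   with fold index `k`, size `n`, `fold_mse`, and list-columns `y_est`,
#'   `y_true`.
#' @export
cv_objective <- function(X, y, hp, seed = 1L, k = 5L, grad_tol = 1e-7,
                         sample_max = Inf) {
  X <- as.matrix(X)
  if (is.finite(sample_max) && nrow(X) > sample_max) {
    local_rng_seed(child_seed(seed, "cv-sub"))
    keep <- sort(sample.int(nrow(X), sample_max))
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- nrow(X)
  if (n < k) stop("need at least ", k, " samples for ", k, "-fold CV")
  local_rng_seed(child_seed(seed, "cv-folds"))
  fold <- sample(rep(seq_len(k), length.out = n))
  res <- purrr::map_dfr(seq_len(k), function(kk) {
    test <- fold == kk
    model <- train_ann(X[!test, , drop = FALSE], y[!test], hp,
                       seed = child_seed(seed, "cv-train", kk),
                       grad_tol = grad_tol)
    y_est <- predict_ann(model, X[test, , drop = FALSE])
    tibble::tibble(k = kk, n = sum(test),
                   fold_mse = mean((y_est - y[test])^2),
                   y_est = list(y_est), y_true = list(y[test]))
  })
  list(f_obj = max(res$fold_mse), folds = res)
}

# scale hyperparameter coordinates to [0,1]^3 (log scale for the rate)
hp_to_unit <- function(hmat) {
  box <- ann_box()
  cbind(
    (hmat[, 1] - box$n_hidden[1]) / diff(range(box$n_hidden)),
    (log(hmat[, 2]) - log(box$learning_rate[1])) /
      (log(box$learning_rate[2]) - log(box$learning_rate[1])),
    (hmat[, 3] - box$epochs[1]) / diff(range(box$epochs))
  )
}

unit_to_hp <- function(u) {
  box <- ann_box()
  ann_hyperparams(
    n_hidden = round(box$n_hidden[1] + u[1] * diff(range(box$n_hidden))),
    learning_rate = exp(log(box$learning_rate[1]) +
                          u[2] * (log(box$learning_rate[2]) - log(box$learning_rate[1]))),
    epochs = round(box$epochs[1] + u[3] * diff(range(box$epochs)))
  )
}

#' Tune network hyperparameters by model-based sequential search
#'
#' Minimises the worst-fold objective ([cv_objective()]) over the
#' hyperparameter box. The search is seeded model-based sequential
#' optimisation: a space-filling initial design (Latin hypercube when the
#' `lhs` package is available, otherwise seeded uniform sampling as the
#' random-search fallback) consumes 60% of the budget, after which a
#' Gaussian-kernel radial-basis surrogate with a distance-based exploration
#' bonus proposes the remaining evaluations (lower-confidence-bound
#' acquisition over a random candidate pool). Every evaluated point is
#' logged. Deterministic for a fixed seed.
#'
#' @param X,y Pooled training samples.
#' @param budget Total number of objective evaluations (>= 10).
#' @param seed Integer seed.
#' @param k CV folds.
#' @param grad_tol Passed to [train_ann()].
#' @param sample_max Passed to [cv_objective()] (tuning-phase row cap).
#' @return List with `hp` (the best [ann_hyperparams()]), `f_obj`, and
#'   `log` (tibble of every evaluation: hyperparameters + objective).
#' @export
tune_hyperparameters <- function(X, y, budget = 30L, seed = 1L, k = 5L,
                                 grad_tol = 1e-7, sample_max = Inf) {
  if (budget < 10) stop("tuning budget must be at least 10 evaluations")
  local_rng_seed(child_seed(seed, "tune"))
  n_init <- max(ceiling(0.6 * budget), 4L)
  U <- if (requireNamespace("lhs", quietly = TRUE)) {
    lhs::randomLHS(n_init, 3)
  } else {
    matrix(stats::runif(n_init * 3), n_init, 3)
  }
  evals <- list()
  eval_point <- function(u) {
    hp <- unit_to_hp(pmin(pmax(u, 0), 1))
    cv <- cv_objective(X, y, hp, seed = child_seed(seed, "tune-eval",
                                                   length(evals) + 1),
                       k = k, grad_tol = grad_tol, sample_max = sample_max)
    list(u = pmin(pmax(u, 0), 1), hp = hp, f = cv$f_obj)
  }
  for (i in seq_len(n_init)) evals[[length(evals) + 1]] <- eval_point(U[i, ])
  while (length(evals) < budget) {
    Ue <- do.call(rbind, lapply(evals, `[[`, "u"))
    fe <- vapply(evals, `[[`, numeric(1), "f")
    fz <- (fe - mean(fe)) / max(stats::sd(fe), 1e-12)
    cand <- matrix(stats::runif(200 * 3), 200, 3)
    d2 <- outer(rowSums(cand^2), rowSums(Ue^2), "+") - 2 * cand %*% t(Ue)
    Kc <- exp(-d2 / (2 * 0.2^2))
    wsum <- rowSums(Kc) + 1e-12
    pred <- as.numeric(Kc %*% fz) / wsum
    mind <- sqrt(pmax(apply(d2, 1, min), 0))
    score <- pred - 1.5 * mind # lower confidence bound
    evals[[length(evals) + 1]] <- eval_point(cand[which.min(score), ])
  }
  log <- purrr::map_dfr(evals, function(e) {
    tibble::tibble(n_hidden = e$hp$n_hidden,
                   learning_rate = e$hp$learning_rate,
                   epochs = e$hp$epochs, f_obj = e$f)
  })
  best <- which.min(log$f_obj)
  list(hp = evals[[best]]$hp, f_obj = log$f_obj[best], log = log)
}
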