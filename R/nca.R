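#' Regression neighbourhood component analysis objective
#'
#' Evaluates the leave-one-out NCA regression objective and its
#' intermediates. Point `j` is picked as the reference neighbour of point
#' `i` with probability proportional to an exponential kernel
#' `k(z) = exp(-z / sigma)` of the weighted distance
#' `d_w(x_i, x_j) = sum_r w_r^2 |x_ir - x_jr|`; the per-point loss is the
#' expected absolute deviation of the neighbour's response,
#' `l_i = sum_{j != i} p_ij |y_i - y_j|`, and the objective is
#' `F(w) = mean(l_i) + lambda * sum_r w_r^2`.
#'
#' @param w Feature weight vector (enters squared; sign-free).
#' @param X n x p feature matrix.
#' @param y Length-n response.
#' @param sigma Kernel width (> 0).
#' @param lambda Regularisation parameter (>= 0).
#' @return List of class `nca_breakdown`: `d_w` (n x n weighted distances),
#'   `p_ij` (neighbour probabilities, zero diagonal), `l_i`, `objective`.
#' @export
nca_objective <- function(w, X, y, sigma = 1, lambda = 0) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("NCA needs at least 2 points (leave-one-out undefined)")
  stopifnot(length(y) == n, length(w) == ncol(X), sigma > 0, lambda >= 0,
            all(is.finite(X)), all(is.finite(y)), all(is.finite(w)))
  D <- nca_distances(w, X)
  # row-wise soft-min normalisation, numerically stabilised
  K <- -D / sigma
  diag(K) <- -Inf
  K <- exp(K - apply(K, 1, max))
  P <- K / rowSums(K)
  L <- abs(outer(y, y, "-"))
  l_i <- rowSums(P * L)
  structure(list(d_w = D, p_ij = P, l_i = l_i,
                 objective = mean(l_i) + lambda * sum(w^2)),
            class = "nca_breakdown")
}

# pairwise weighted L1 distances with weights w^2
nca_distances <- function(w, X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (r in seq_len(ncol(X))) {
    D <- D + w[r]^2 * abs(outer(X[, r], X[, r], "-"))
  }
  D
}

#' Analytic gradient of the NCA regression objective
#'
#' Differentiates the objective of [nca_objective()] with respect to the
#' weight vector; verified against central finite differences in the test
#' suite.
#'
#' @inheritParams nca_objective
#' @return Length-p gradient vector.
#' @export
nca_gradient <- function(w, X, y, sigma = 1, lambda = 0) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("NCA needs at least 2 points (leave-one-out undefined)")
  bd <- nca_objective(w, X, y, sigma, lambda)
  P <- bd$p_ij
  L <- abs(outer(y, y, "-"))
  PL <- P * L
  l_i <- bd$l_i
  grad <- numeric(ncol(X))
  for (r in seq_len(ncol(X))) {
    Dr <- abs(outer(X[, r], X[, r], "-"))
    # d l_i / d w_r = (2 w_r / sigma) * [ l_i * sum_j p_ij D_ijr
    #                                      - sum_j p_ij L_ij D_ijr ]
    term <- l_i * rowSums(P * Dr) - rowSums(PL * Dr)
    grad[r] <- (2 * w[r] / sigma) * mean(term)
  }
  grad + 2 * lambda * w
}

#' Fit regression NCA feature weights
#'
#' Standardises the features internally (location/scale), then minimises
#' the leave-one-out objective with a quasi-Newton (BFGS) search using the
#' analytic gradient. Weights enter the model squared, so the
#' parameterisation is box-free. Deterministic for a fixed seed (the seed
#' only perturbs the all-ones initial point infinitesimally to break exact
#' symmetry between duplicated features).
#'
#' @param X n x p feature matrix (data frame or matrix; column names are
#'   kept as feature names).
#' @param y Length-n response.
#' @param lambda Regularisation parameter; default `1/n`.
#' @param sigma Kernel width applied after standardisation. The default
#'   (`NULL`) sets it to the mean pairwise weighted distance at the initial
#'   all-ones weights, so the kernel operates on the scale of the actual
#'   distances regardless of the feature count; a fixed small width would
#'   collapse the neighbour distribution onto the single nearest point.
#' @param seed Integer seed.
#' @param maxit BFGS iteration cap.
#' @param sample_max If the number of rows exceeds this, a seeded random
#'   subsample of rows is used for fitting (the objective is O(n^2 p));
#'   `Inf` disables subsampling.
#' @return Object of class `nca_model`: `w` (raw weights), `w2` (squared
#'   weights, the feature importances), `sigma`, `lambda`, `standardiser`
#'   (per-feature centre/scale), `objective`, `converged`, `feature_names`.
#' @export
fit_nca <- function(X, y, lambda = NULL, sigma = NULL, seed = 1L,
                    maxit = 150L, sample_max = Inf) {
  X <- as.matrix(X)
  n0 <- nrow(X)
  if (n0 < 2) stop("NCA needs at least 2 points")
  if (is.null(lambda)) lambda <- 1 / n0
  feature_names <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  centre <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, centre, "-"), 2, scale, "/")
  local_rng_seed(child_seed(seed, "nca"))
  if (n0 > sample_max) {
    keep <- sort(sample.int(n0, sample_max))
    Xs_fit <- Xs[keep, , drop = FALSE]
    y_fit <- y[keep]
  } else {
    Xs_fit <- Xs
    y_fit <- y
  }
  w0 <- rep(1, ncol(X)) + stats::rnorm(ncol(X), 0, 1e-4)
  # cache the per-feature absolute-difference matrices once; objective and
  # gradient then reduce to weighted sums over the cache
  Dr_list <- lapply(seq_len(ncol(X)), function(r) {
    abs(outer(Xs_fit[, r], Xs_fit[, r], "-"))
  })
  L <- abs(outer(y_fit, y_fit, "-"))
  nf <- nrow(Xs_fit)
  if (is.null(sigma)) {
    D0 <- Reduce(`+`, Map(function(Dr, w) w^2 * Dr, Dr_list, w0))
    sigma <- sum(D0) / (nf * (nf - 1))
  }
  Dflat <- do.call(cbind, lapply(Dr_list, as.numeric)) # n^2 x p
  row_id <- rep(seq_len(nf), nf)
  fg <- function(w) {
    D <- matrix(Dflat %*% w^2, nf, nf)
    K <- -D / sigma
    diag(K) <- -Inf
    K <- exp(K - apply(K, 1, max))
    P <- K / rowSums(K)
    PL <- P * L
    l_i <- rowSums(PL)
    obj <- mean(l_i) + lambda * sum(w^2)
    # batched rowSums(P * Dr) and rowSums(PL * Dr) over all features
    S1 <- rowsum(as.numeric(P) * Dflat, row_id, reorder = FALSE) # n x p
    S2 <- rowsum(as.numeric(PL) * Dflat, row_id, reorder = FALSE)
    grad <- (2 * w / sigma) * colMeans(l_i * S1 - S2) + 2 * lambda * w
    list(objective = obj, gradient = grad)
  }
  fit <- stats::optim(w0, fn = function(w) fg(w)$objective,
                      gr = function(w) fg(w)$gradient,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  structure(list(
    w = fit$par, w2 = fit$par^2,
    sigma = sigma, lambda = lambda,
    standardiser = list(centre = centre, scale = scale),
    objective = fit$value,
    converged = fit$convergence == 0,
    feature_names = feature_names,
    n_fit = nrow(Xs_fit)
  ), class = "nca_model")
}

#' Select features by the 1%-of-maximum weight rule
#'
#' Retains the features whose squared weight exceeds `fraction` times the
#' largest squared weight (the squared weight is the quantity that enters
#' the weighted distance and the penalty, so the rule is applied to it).
#'
#' @param model An [fit_nca()] model.
#' @param fraction Threshold fraction of the maximum squared weight
#'   (default 0.01).
#' @return Integer vector of selected feature indices, ascending.
#' @export
select_features <- function(model, fraction = 0.01) {
  stopifnot(inherits(model, "nca_model"))
  w2 <- model$w2
  if (all(w2 == 0)) stop("all NCA weights are zero; nothing to select")
  sort(which(w2 > fraction * max(w2)))
}

#' @method tidy nca_model
#' @export
tidy.nca_model <- function(x, fraction = 0.01, ...) {
  sel <- select_features(x, fraction)
  tibble::tibble(
    feature = x$feature_names,
    weight = x$w,
    weight_sq = x$w2,
    selected = seq_along(x$w) %in% sel
  )
}

#' @method glance nca_model
#' @export
glance.nca_model <- function(x, ...) {
  tibble::tibble(objective = x$objective, sigma = x$sigma,
                 lambda = x$lambda, n_fit = x$n_fit,
                 n_features = length(x$w), converged = x$converged)
}

#' @export
print.nca_model <- function(x, ...) {
  cat(sprintf("<nca_model> %d features, objective %.4g, %s\n",
              length(x$w), x$objective,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
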