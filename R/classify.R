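# Classifiers compared in the evaluation harness: ELM, hierarchical ELM,
# PSO-tuned hierarchical ELM, and KNN/SVM baselines under one
# train/predict contract. All stochastic trainers are deterministic under
# their seed.

fm_parts <- function(X, y = NULL) {
  if (inherits(X, "feature_matrix")) list(x = X$values, y = X$labels)
  else list(x = as.matrix(X), y = as.character(y))
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2)
    abort_fatigue("training data must contain at least 2 classes",
                  "fatigueEEG_training_error")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

activation_fun <- function(name) {
  switch(name, sigmoid = sigmoid, relu = function(z) pmax(z, 0),
         stop_param(sprintf("unknown activation '%s'", name)))
}

# z-score parameters from the training matrix; zero-variance columns get
# unit scale so they map to a constant.
scaler_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv)
}
scaler_apply <- function(sc, x) sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")

one_hot <- function(y, classes) {
  Tm <- matrix(0, nrow = length(y), ncol = length(classes))
  Tm[cbind(seq_along(y), match(y, classes))] <- 1
  Tm
}

ridge_solve <- function(H, Tm, C) {
  L <- ncol(H)
  solve(crossprod(H) + diag(C, L), crossprod(H, Tm))
}

#' Train an extreme learning machine
#'
#' Single hidden layer with fixed random weights: `W, b ~ Uniform(-1, 1)`
#' drawn from `seed`, hidden activations `H = g(XW + b)`, and output
#' weights solving the ridge-regularized least squares
#' `min |H beta - T|^2 + C |beta|^2` against one-hot labels. Features are
#' z-scored using training statistics stored in the model.
#'
#' @param X A [feature_matrix()], or a numeric matrix with `y` given.
#' @param y Labels (ignored when `X` is a feature matrix).
#' @param n_hidden Hidden layer width.
#' @param C Ridge penalty (>= 0; larger shrinks `beta` toward 0).
#' @param activation `"sigmoid"` or `"relu"`.
#' @param seed Integer seed for the random hidden layer.
#' @return An `elm_model`.
#' @export
elm_train <- function(X, y = NULL, n_hidden = 100, C = 1e-3,
                      activation = c("sigmoid", "relu"), seed = 1) {
  activation <- match.arg(activation)
  if (!is_count(n_hidden) || n_hidden < 1) stop_param("n_hidden must be >= 1")
  if (!is_scalar_num(C) || C < 0) stop_param("C must be >= 0")
  p <- fm_parts(X, y)
  check_two_classes(p$y)
  classes <- sort(unique(p$y))
  sc <- scaler_fit(p$x)
  xs <- scaler_apply(sc, p$x)
  set.seed(derive_seed(seed, "elm"))
  W <- matrix(stats::runif(ncol(xs) * n_hidden, -1, 1), ncol = n_hidden)
  b <- stats::runif(n_hidden, -1, 1)
  g <- activation_fun(activation)
  H <- g(sweep(xs %*% W, 2, b, "+"))
  beta <- ridge_solve(H, one_hot(p$y, classes), C)
  structure(list(W = W, b = b, beta = beta, activation = activation,
                 classes = classes, scaler = sc, C = C, seed = seed),
            class = "elm_model")
}

#' @export
predict.elm_model <- function(object, X, ...) {
  x <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  if (nrow(x) == 0) return(character(0))
  if (ncol(x) != nrow(object$W))
    stop_param("feature dimension does not match the trained model")
  g <- activation_fun(object$activation)
  H <- g(sweep(scaler_apply(object$scaler, x) %*% object$W, 2, object$b, "+"))
  object$classes[max.col(H %*% object$beta, ties.method = "first")]
}

# l1-regularized least squares |H beta - Z|^2 + tau |beta|_1 by FISTA with
# a fixed iteration budget; deterministic.
fista_l1 <- function(H, Z, tau, iters = 40) {
  HtH <- crossprod(H)
  HtZ <- crossprod(H, Z)
  L <- 2 * norm(HtH, "2") + 1e-12
  beta <- matrix(0, ncol(H), ncol(Z))
  yk <- beta; tk <- 1
  for (it in seq_len(iters)) {
    grad <- 2 * (HtH %*% yk - HtZ)
    z <- yk - grad / L
    beta_new <- sign(z) * pmax(abs(z) - tau / L, 0)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    yk <- beta_new + ((tk - 1) / t_new) * (beta_new - beta)
    beta <- beta_new; tk <- t_new
  }
  beta
}

#' Train a hierarchical ELM
#'
#' Stacked ELM sparse autoencoders followed by an ELM classifier. Each
#' autoencoder projects its input through a random hidden layer and learns
#' l1-regularized output weights that reconstruct the input; the transposed
#' weights encode the next layer's features. The final encoding feeds a
#' standard ridge ELM.
#'
#' @inheritParams elm_train
#' @param layer_sizes Autoencoder widths, e.g. `c(100, 100)`.
#' @param n_hidden Width of the final ELM classifier layer.
#' @param C Ridge penalty of the final ELM.
#' @param l1 Relative l1 penalty of the autoencoder weights.
#' @return A `helm_model`.
#' @export
helm_train <- function(X, y = NULL, layer_sizes = c(100, 100), n_hidden = 500,
                       C = 1e-3, l1 = 1e-3, seed = 1) {
  if (length(layer_sizes) < 1 || !all(vapply(layer_sizes, is_count, TRUE)) ||
      any(layer_sizes < 1))
    stop_param("layer_sizes must be positive integers")
  p <- fm_parts(X, y)
  check_two_classes(p$y)
  sc <- scaler_fit(p$x)
  Z <- scaler_apply(sc, p$x)
  layers <- vector("list", length(layer_sizes))
  for (l in seq_along(layer_sizes)) {
    Lw <- layer_sizes[l]
    set.seed(derive_seed(seed, "helm-ae", l))
    Wl <- matrix(stats::runif(ncol(Z) * Lw, -1, 1), ncol = Lw)
    bl <- stats::runif(Lw, -1, 1)
    H <- sigmoid(sweep(Z %*% Wl, 2, bl, "+"))
    tau <- l1 * max(abs(crossprod(H, Z)))
    beta_ae <- fista_l1(H, Z, tau)           # Lw x d, reconstructs Z from H
    enc <- Z %*% t(beta_ae)                  # n x Lw projection
    s <- max(abs(enc)); if (s < 1e-12) s <- 1
    Z <- sigmoid(enc / s)
    layers[[l]] <- list(beta = beta_ae, scale = s)
  }
  final <- elm_train(Z, p$y, n_hidden = n_hidden, C = C,
                     seed = derive_seed(seed, "helm-final"))
  structure(list(layers = layers, final = final, scaler = sc,
                 layer_sizes = layer_sizes, seed = seed),
            class = "helm_model")
}

helm_encode <- function(object, x) {
  Z <- scaler_apply(object$scaler, x)
  for (l in object$layers)
    Z <- sigmoid((Z %*% t(l$beta)) / l$scale)
  Z
}

#' @export
predict.helm_model <- function(object, X, ...) {
  x <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  if (nrow(x) == 0) return(character(0))
  if (ncol(x) != length(object$scaler$mu))
    stop_param("feature dimension does not match the trained model")
  predict(object$final, helm_encode(object, x))
}

#' PSO configuration
#'
#' Canonical particle swarm: velocity update
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, position clipped to
#' the search box, velocity clamped to a fraction of each range.
#'
#' @param swarm_size Number of particles (>= 2).
#' @param iterations Update sweeps after initialization.
#' @param inertia Inertia weight `w` in (0, 1.5).
#' @param c1,c2 Cognitive and social acceleration constants.
#' @param bounds Matrix with rows `lo`/`hi`, one column per dimension (or
#'   list of `c(lo, hi)`).
#' @param v_clamp Velocity clamp as a fraction of each dimension's range.
#' @param seed Integer seed.
#' @param fitness_folds Cross-validation folds used when the config drives
#'   hyperparameter search.
#' @return A `pso_config`.
#' @export
pso_config <- function(swarm_size = 15, iterations = 30, inertia = 0.7,
                       c1 = 1.5, c2 = 1.5, bounds, v_clamp = 0.2, seed = 1,
                       fitness_folds = 3) {
  if (!is_count(swarm_size) || swarm_size < 2) stop_param("swarm_size must be >= 2")
  if (!is_count(iterations) || iterations < 1) stop_param("iterations must be >= 1")
  if (!is_scalar_num(inertia) || inertia <= 0 || inertia >= 1.5)
    stop_param("inertia must lie in (0, 1.5)")
  if (is.list(bounds)) bounds <- vapply(bounds, function(b) c(b[1], b[2]), c(0, 0))
  if (!is.matrix(bounds) || nrow(bounds) != 2 || any(bounds[1, ] >= bounds[2, ]))
    stop_param("bounds must give lo < hi per dimension")
  structure(list(swarm_size = swarm_size, iterations = iterations,
                 inertia = inertia, c1 = c1, c2 = c2, bounds = bounds,
                 v_clamp = v_clamp, seed = seed, fitness_folds = fitness_folds),
            class = "pso_config")
}

#' Particle swarm optimization (maximization)
#'
#' @param fitness Function mapping a position vector to a scalar score;
#'   non-finite scores are treated as `-Inf` with a warning.
#' @param cfg A [pso_config()].
#' @return List with `best_position`, `best_score`, and `trace` (gbest
#'   score per iteration, non-decreasing by construction).
#' @export
pso_optimize <- function(fitness, cfg) {
  stopifnot(inherits(cfg, "pso_config"))
  lo <- cfg$bounds[1, ]; hi <- cfg$bounds[2, ]
  d <- length(lo); n <- cfg$swarm_size
  rng <- hi - lo
  vmax <- cfg$v_clamp * rng
  set.seed(derive_seed(cfg$seed, "pso"))
  pos <- matrix(stats::runif(n * d, lo, hi), nrow = n, byrow = TRUE)
  vel <- matrix(stats::runif(n * d, -vmax, vmax), nrow = n, byrow = TRUE)
  warned <- FALSE
  eval_fit <- function(x) {
    s <- fitness(x)
    if (!is_scalar_num(s)) {
      if (!warned) {
        warning("non-finite fitness treated as -Inf")
        warned <<- TRUE
      }
      s <- -Inf
    }
    s
  }
  pbest <- pos
  pbest_score <- apply(pos, 1, eval_fit)
  g <- which.max(pbest_score)
  gbest <- pbest[g, ]; gbest_score <- pbest_score[g]
  trace <- numeric(cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    r1 <- matrix(stats::runif(n * d), n); r2 <- matrix(stats::runif(n * d), n)
    vel <- cfg$inertia * vel + cfg$c1 * r1 * (pbest - pos) +
      cfg$c2 * r2 * (sweep(-pos, 2, gbest, "+"))
    vel <- pmin(pmax(vel, matrix(-vmax, n, d, byrow = TRUE)),
                matrix(vmax, n, d, byrow = TRUE))
    pos <- pos + vel
    pos <- pmin(pmax(pos, matrix(lo, n, d, byrow = TRUE)),
                matrix(hi, n, d, byrow = TRUE))
    scores <- apply(pos, 1, eval_fit)
    better <- scores > pbest_score
    pbest[better, ] <- pos[better, , drop = FALSE]
    pbest_score[better] <- scores[better]
    g <- which.max(pbest_score)
    if (pbest_score[g] > gbest_score) {
      gbest <- pbest[g, ]; gbest_score <- pbest_score[g]
    }
    trace[it] <- gbest_score
  }
  list(best_position = gbest, best_score = gbest_score, trace = trace)
}

# Stratified k-fold assignment, deterministic under seed.
stratified_folds <- function(y, k, seed) {
  set.seed(derive_seed(seed, "folds"))
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

cv_accuracy <- function(x, y, k, seed, train_fun) {
  fold <- stratified_folds(y, k, seed)
  accs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || !any(!tr)) return(NA_real_)
    model <- train_fun(x[tr, , drop = FALSE], y[tr])
    mean(predict(model, x[!tr, , drop = FALSE]) == y[!tr]) * 100
  }, 0)
  mean(accs, na.rm = TRUE)
}

#' Default search space for PSO-tuned hierarchical ELM
#'
#' Columns: autoencoder widths 1 and 2, final ELM width, `log10(C)`.
#'
#' @return A 2 x 4 bounds matrix (rows lo, hi).
#' @export
pso_helm_bounds <- function() {
  b <- cbind(layer1 = c(20, 300), layer2 = c(20, 300),
             n_hidden = c(100, 1000), log10C = c(-4, 4))
  rownames(b) <- c("lo", "hi")
  b
}

#' Train a PSO-optimized hierarchical ELM
#'
#' Particle swarm search over hyperparameters (two autoencoder widths, the
#' final ELM width, and `log10` of the ridge penalty); fitness is mean
#' stratified k-fold cross-validation accuracy on the training data only.
#' Integer hyperparameters are rounded at evaluation time. The returned
#' model is retrained on all training rows at the best position.
#'
#' @inheritParams elm_train
#' @param cfg A [pso_config()]; its `bounds` default to
#'   [pso_helm_bounds()].
#' @return A `helm_model` with attribute `pso` (best position, score,
#'   trace).
#' @export
pso_helm_train <- function(X, y = NULL, cfg = NULL) {
  if (is.null(cfg)) cfg <- pso_config(bounds = pso_helm_bounds())
  p <- fm_parts(X, y)
  check_two_classes(p$y)
  if (min(table(p$y)) < cfg$fitness_folds)
    abort_fatigue("too few rows per class for the fitness cross-validation",
                  "fatigueEEG_training_error")
  decode <- function(pos) {
    list(layers = c(max(1, round(pos[1])), max(1, round(pos[2]))),
         n_hidden = max(1, round(pos[3])), C = 10^pos[4])
  }
  fitness <- function(pos) {
    hp <- decode(pos)
    cv_accuracy(p$x, p$y, cfg$fitness_folds, cfg$seed, function(x, y)
      helm_train(x, y, layer_sizes = hp$layers, n_hidden = hp$n_hidden,
                 C = hp$C, seed = derive_seed(cfg$seed, "pso-helm-fit")))
  }
  opt <- pso_optimize(fitness, cfg)
  hp <- decode(opt$best_position)
  model <- helm_train(p$x, p$y, layer_sizes = hp$layers,
                      n_hidden = hp$n_hidden, C = hp$C,
                      seed = derive_seed(cfg$seed, "pso-helm-final"))
  attr(model, "pso") <- opt
  model
}

#' K-nearest-neighbour baseline
#'
#' Stores the training rows; prediction is Euclidean KNN via
#' \code{class::knn} on z-scored features.
#'
#' @inheritParams elm_train
#' @param k Neighbourhood size.
#' @return A `knn_model`.
#' @export
knn_train <- function(X, y = NULL, k = 5) {
  p <- fm_parts(X, y)
  check_two_classes(p$y)
  sc <- scaler_fit(p$x)
  structure(list(x = scaler_apply(sc, p$x), y = p$y, k = k, scaler = sc),
            class = "knn_model")
}

#' @export
predict.knn_model <- function(object, X, ...) {
  x <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  if (nrow(x) == 0) return(character(0))
  if (ncol(x) != ncol(object$x))
    stop_param("feature dimension does not match the trained model")
  as.character(class::knn(object$x, scaler_apply(object$scaler, x),
                          cl = factor(object$y), k = object$k, use.all = TRUE))
}

#' RBF-kernel SVM baseline
#'
#' Thin wrapper over \code{e1071::svm} with feature scaling.
#'
#' @inheritParams elm_train
#' @param cost SVM cost parameter.
#' @param gamma RBF kernel width (`NULL` = e1071 default `1/d`).
#' @return An `svm_model_fe`.
#' @export
svm_train <- function(X, y = NULL, cost = 1, gamma = NULL) {
  p <- fm_parts(X, y)
  check_two_classes(p$y)
  args <- list(x = p$x, y = factor(p$y), kernel = "radial", cost = cost,
               scale = apply(p$x, 2, stats::sd) > 1e-12)
  if (!is.null(gamma)) args$gamma <- gamma
  structure(list(fit = do.call(e1071::svm, args), d = ncol(p$x)),
            class = "svm_model_fe")
}

#' @export
predict.svm_model_fe <- function(object, X, ...) {
  x <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  if (nrow(x) == 0) return(character(0))
  if (ncol(x) != object$d)
    stop_param("feature dimension does not match the trained model")
  as.character(predict(object$fit, x))
}
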