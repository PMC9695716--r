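#' Gaussian radial basis function
#'
#' k(x, c) = exp(-||x - c||^2 / (2 sigma^2)): the kernel value depends only
#' on the squared Euclidean distance between the feature vectors, is 1 at
#' zero distance and decays towards 0.
#'
#' @param x,c numeric feature vectors of equal length.
#' @param sigma kernel width (> 0).
#' @return kernel value in (0, 1].
#' @export
gaussian_rbf <- function(x, c, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  if (length(x) != length(c)) stop("feature dimension mismatch")
  exp(-sum((x - c)^2) / (2 * sigma^2))
}

#' RBF activation matrix
#'
#' Entry (i, j) is the Gaussian RBF kernel between sample i and center j.
#'
#' @param X n x d numeric matrix of samples (rows).
#' @param centers c x d numeric matrix of centers (rows); non-empty.
#' @param sigma kernel width (> 0).
#' @return n x c activation matrix with entries in (0, 1].
#' @export
rbf_activations <- function(X, centers, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  X <- as.matrix(X); centers <- as.matrix(centers)
  if (nrow(centers) == 0) stop("centers must be non-empty")
  if (ncol(X) != ncol(centers)) stop("feature dimension mismatch")
  xx <- rowSums(X^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, "+") - 2 * X %*% t(centers)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' Univariate partial least-squares fit (NIPALS)
#'
#' PLS1 by NIPALS deflation: predictors and response are centered, then
#' each latent direction is the (unit-normalized) covariance of the
#' deflated predictors with the deflated response; scores are extracted
#' and both blocks are deflated. The regression coefficients mapping the
#' centered predictor block to the centered response are
#' B = W (P'W)^{-1} q. Successive score vectors are mutually orthogonal.
#'
#' @param H n x c numeric predictor matrix (e.g. RBF activations).
#' @param y numeric response of length n; must have non-zero variance.
#' @param n_latent number of latent variables, in 1..min(n-1, c).
#' @return a `pls_fit` list: `h_mean`, `y_mean`, `weights` (W),
#'   `loadings` (P), `q`, `coefficients` (B), `scores` (T),
#'   `n_latent` (possibly reduced if the predictor block is exhausted),
#'   `fitted`.
#' @export
pls_fit <- function(H, y, n_latent) {
  H <- as.matrix(H); y <- as.numeric(y)
  n <- nrow(H); c <- ncol(H)
  if (n < 2) stop("need at least 2 samples")
  if (stats::var(y) < .Machine$double.eps) stop("response has zero variance")
  if (n_latent < 1 || n_latent > min(n - 1, c))
    stop("n_latent out of range 1..min(n-1, ncol(H))")
  h_mean <- colMeans(H); y_mean <- mean(y)
  E <- sweep(H, 2, h_mean)
  f <- y - y_mean
  W <- matrix(0, c, n_latent); P <- matrix(0, c, n_latent)
  Tm <- matrix(0, n, n_latent); q <- numeric(n_latent)
  a_used <- 0L
  for (a in seq_len(n_latent)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break           # predictor block exhausted
    w <- w / nw
    t <- as.vector(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    p <- as.vector(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; q[a] <- qa
    a_used <- a
  }
  if (a_used == 0L) stop("no usable latent direction found")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  B <- W %*% solve(crossprod(P, W), q)
  fitted <- y_mean + as.vector(sweep(H, 2, h_mean) %*% B)
  structure(list(h_mean = h_mean, y_mean = y_mean, weights = W,
                 loadings = P, q = q, coefficients = as.vector(B),
                 scores = Tm, n_latent = a_used, fitted = fitted),
            class = "pls_fit")
}

pls_predict <- function(fit, H) {
  fit$y_mean + as.vector(sweep(as.matrix(H), 2, fit$h_mean) %*%
                           fit$coefficients)
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mean = mu, sd = sd)
}

standardize_apply <- function(X, scaler) {
  sweep(sweep(as.matrix(X), 2, scaler$mean), 2, scaler$sd, "/")
}

#' Fit the hybrid RBF + PLS regressor with fixed hyperparameters
#'
#' Features are standardized, centers are placed by seeded k-means on the
#' standardized features (or supplied directly), the Gaussian-RBF
#' activation matrix is formed, and a PLS regression maps activations to
#' the response. [ga_optimize()] wraps this fit with hyperparameter search.
#'
#' @param X n x d feature matrix (or data.frame of numeric columns).
#' @param y numeric response (g/kg).
#' @param sigma RBF width on the standardized feature scale (> 0).
#' @param n_centers number of RBF centers (k-means k); capped at the
#'   number of distinct training rows.
#' @param n_latent number of PLS latent variables; capped at
#'   min(n-1, n_centers).
#' @param seed integer seed for the k-means placement.
#' @param centers optional explicit center matrix on the standardized
#'   scale (overrides k-means).
#' @return an `rbf_pls_model` with fields `centers`, `sigma`, `n_latent`,
#'   `x_scaler`, `pls`, `features`, `train_meta`.
#' @export
fit_rbf_pls <- function(X, y, sigma, n_centers, n_latent, seed = 1L,
                        centers = NULL) {
  X <- as.matrix(X)
  scaler <- standardize_fit(X)
  Xs <- standardize_apply(X, scaler)
  if (is.null(centers)) {
    n_centers <- max(1L, min(as.integer(n_centers), nrow(unique(Xs))))
    set.seed(seed)
    centers <- if (n_centers >= nrow(unique(Xs))) unique(Xs) else
      stats::kmeans(Xs, centers = n_centers, nstart = 5,
                    iter.max = 50)$centers
  }
  centers <- as.matrix(centers)
  n_latent <- max(1L, min(as.integer(n_latent), nrow(Xs) - 1L,
                          nrow(centers)))
  H <- rbf_activations(Xs, centers, sigma)
  # extreme widths can flatten the activations to numerical constancy;
  # fall back to the intercept-only fit so a search can still score it
  fit <- tryCatch(pls_fit(H, y, n_latent), error = function(e)
    structure(list(h_mean = colMeans(H), y_mean = mean(y),
                   weights = NULL, loadings = NULL, q = numeric(0),
                   coefficients = rep(0, ncol(H)),
                   scores = NULL, n_latent = 0L,
                   fitted = rep(mean(y), nrow(H))),
              class = "pls_fit"))
  structure(list(centers = centers, sigma = sigma, n_latent = fit$n_latent,
                 x_scaler = scaler, pls = fit,
                 features = colnames(X),
                 train_meta = list(seed = seed, n = nrow(Xs))),
            class = "rbf_pls_model")
}

#' Predict nitrogen content with a fitted RBF-PLS model
#'
#' @param object an `rbf_pls_model`.
#' @param newdata matrix or data.frame with the training feature columns.
#' @param ... unused.
#' @return numeric predictions (g/kg).
#' @export
predict.rbf_pls_model <- function(object, newdata, ...) {
  X <- as.matrix(extract_feature_matrix(newdata, object$features))
  Xs <- standardize_apply(X, object$x_scaler)
  H <- rbf_activations(Xs, object$centers, object$sigma)
  pls_predict(object$pls, H)
}

extract_feature_matrix <- function(data, features) {
  if (is.matrix(data)) {
    if (!is.null(features) && !is.null(colnames(data)) &&
        all(features %in% colnames(data)))
      return(data[, features, drop = FALSE])
    return(data)
  }
  if (!is.null(features)) {
    missing <- setdiff(features, names(data))
    if (length(missing))
      stop("missing feature columns: ", paste(missing, collapse = ", "))
    return(as.matrix(data[, features, drop = FALSE]))
  }
  as.matrix(data)
}

#' Absolute-error fitness
#'
#' F = k * sum |y_i - o_i|, the scaled sum of absolute prediction errors
#' minimized by the genetic procedure; smaller is better.
#'
#' @param y actual values.
#' @param o predicted values (same length).
#' @param k positive scale coefficient (default 1; rescales fitness
#'   monotonically and cannot change the selection ordering).
#' @return non-negative fitness value.
#' @export
fitness <- function(y, o, k = 1) {
  if (length(y) != length(o)) stop("length mismatch")
  if (k <= 0) stop("k must be positive")
  k * sum(abs(y - o))
}

#' Roulette-wheel selection with inverse-fitness weights
#'
#' Selection probability is proportional to 1 / (F_i + eps), so smaller
#' fitness (smaller error) means higher selection probability.
#'
#' @param fitnesses non-negative fitness values; non-empty.
#' @param eps guard against division by zero (default 1e-12).
#' @return a single selected index; consumes one uniform draw from the
#'   current RNG stream.
#' @export
roulette_select <- function(fitnesses, eps = 1e-12) {
  if (length(fitnesses) == 0) stop("empty fitness list")
  if (any(fitnesses < 0)) stop("fitnesses must be non-negative")
  w <- 1 / (fitnesses + eps)
  p <- cumsum(w) / sum(w)
  findInterval(stats::runif(1), p) + 1L
}

#' Genetic-procedure configuration
#'
#' Knobs of the hyperparameter search: population size, generations,
#' crossover/mutation probabilities, the fitness scale k, cross-validation
#' folds, elitism, and per-gene search bounds for (log sigma, number of
#' centers, number of latent variables).
#'
#' @param population_size individuals per generation (>= 2).
#' @param n_generations generations to evolve (0 = score the initial
#'   population only).
#' @param crossover_prob probability of arithmetic-blend crossover.
#' @param mutation_prob per-gene probability of Gaussian perturbation.
#' @param mutation_decay multiplicative per-generation decay of the
#'   mutation scale (annealing): early generations explore, late
#'   generations fine-tune. 1 disables annealing.
#' @param fitness_coeff the fitness scale k (> 0).
#' @param n_folds cross-validation folds used to score a genome.
#' @param elitism number of best genomes copied unchanged (>= 1 keeps the
#'   best-per-generation fitness non-increasing).
#' @param seed integer seed driving the whole evolution.
#' @param bounds named list of c(lo, hi) for `log_sigma`, `n_centers`,
#'   `n_latent`.
#' @return a `ga_config` list.
#' @export
ga_config <- function(population_size = 30L, n_generations = 50L,
                      crossover_prob = 0.7, mutation_prob = 0.1,
                      mutation_decay = 0.85,
                      fitness_coeff = 1, n_folds = 5L, elitism = 1L,
                      seed = 1L,
                      bounds = list(log_sigma = c(log(0.05), log(10)),
                                    n_centers = c(4, 25),
                                    n_latent = c(1, 10))) {
  if (population_size < 2) stop("population_size must be >= 2")
  if (crossover_prob < 0 || crossover_prob > 1 ||
      mutation_prob < 0 || mutation_prob > 1)
    stop("probabilities must lie in [0, 1]")
  if (fitness_coeff <= 0) stop("fitness_coeff must be positive")
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 mutation_decay = mutation_decay,
                 fitness_coeff = fitness_coeff,
                 n_folds = as.integer(n_folds),
                 elitism = as.integer(elitism),
                 seed = as.integer(seed), bounds = bounds),
            class = "ga_config")
}

#' Cross-validated fitness of one hyperparameter setting
#'
#' Scores (sigma, n_centers, n_latent) by K-fold cross-validation: the
#' model is refit on each training part and predicts its held-out part;
#' the fitness is k times the sum of absolute held-out errors. Fold
#' assignment is seeded so all settings are compared on identical folds.
#'
#' @param X feature matrix; @param y response.
#' @param sigma,n_centers,n_latent hyperparameters to score.
#' @param config a [ga_config()] (supplies k, folds and seed).
#' @param centers optional fixed center matrix (standardized scale).
#' @return the cross-validated fitness (smaller is better).
#' @export
cv_rbf_fitness <- function(X, y, sigma, n_centers, n_latent, config,
                           centers = NULL) {
  X <- as.matrix(X); n <- nrow(X)
  k_folds <- min(config$n_folds, n)
  set.seed(config$seed + 7919L)
  fold <- sample(rep(seq_len(k_folds), length.out = n))
  preds <- numeric(n)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    m <- fit_rbf_pls(X[tr, , drop = FALSE], y[tr], sigma = sigma,
                     n_centers = n_centers, n_latent = n_latent,
                     seed = config$seed, centers = centers)
    preds[!tr] <- predict(m, X[!tr, , drop = FALSE])
  }
  fitness(y, preds, k = config$fitness_coeff)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

decode_genome <- function(g, bounds) {
  nc <- as.integer(round(clamp(g[2], bounds$n_centers[1],
                               bounds$n_centers[2])))
  nl <- as.integer(round(clamp(g[3], bounds$n_latent[1],
                               bounds$n_latent[2])))
  if (nl > nc) nl <- nc        # repair infeasible pairing
  list(sigma = exp(clamp(g[1], bounds$log_sigma[1], bounds$log_sigma[2])),
       n_centers = nc, n_latent = nl)
}

#' Tune and fit the RBF-PLS model by a genetic procedure
#'
#' Evolves genomes (log sigma, number of centers, number of latent
#' variables) for `config$n_generations` generations. Each genome is
#' scored by the cross-validated absolute-error fitness; parents are drawn
#' by inverse-fitness roulette; crossover is an arithmetic blend, mutation
#' a Gaussian perturbation (10% of the gene's range), and elitism copies
#' the best genomes unchanged, so the best-per-generation fitness never
#' increases. The returned model is refit on all training data with the
#' best genome. Deterministic given `config$seed`.
#'
#' @param train data.frame with feature columns and the response column.
#' @param config a [ga_config()].
#' @param features names of the feature columns.
#' @param response name of the response column.
#' @param fixed optional named list pinning genes (`log_sigma`,
#'   `n_centers`, `n_latent`) and/or supplying a fixed `centers` matrix;
#'   pinned genes are not evolved.
#' @return an `rbf_pls_model`; `train_meta` records the config, the
#'   best genome, its cross-validated fitness and the best-per-generation
#'   fitness history.
#' @export
ga_optimize <- function(train, config = ga_config(),
                        features = c("area_cm2", "g_mean", "g_var"),
                        response = "nitrogen_gkg", fixed = list()) {
  X <- extract_feature_matrix(train, features)
  y <- train[[response]]
  if (nrow(X) < 10) stop("need at least 10 training rows")
  b <- config$bounds
  b$n_centers[2] <- min(b$n_centers[2], nrow(X) - 2)
  b$n_latent[2] <- min(b$n_latent[2], b$n_centers[2])
  gene_fixed <- c(log_sigma = "log_sigma" %in% names(fixed),
                  n_centers = "n_centers" %in% names(fixed),
                  n_latent = "n_latent" %in% names(fixed))
  fixed_vals <- c(fixed$log_sigma %||% NA, fixed$n_centers %||% NA,
                  fixed$n_latent %||% NA)
  lo <- c(b$log_sigma[1], b$n_centers[1], b$n_latent[1])
  hi <- c(b$log_sigma[2], b$n_centers[2], b$n_latent[2])
  rng <- hi - lo

  score <- function(g) {
    d <- decode_genome(g, b)
    cv_rbf_fitness(X, y, d$sigma, d$n_centers, d$n_latent, config,
                   centers = fixed$centers %||% NULL)
  }
  apply_fixed <- function(g) { g[gene_fixed] <- fixed_vals[gene_fixed]; g }

  set.seed(config$seed)
  # Latin-hypercube initialization: each gene stratified across its range
  # so narrow fitness basins are sampled by some member of the population
  np <- config$population_size
  strata <- vapply(1:3, function(g)
    (sample(np) - stats::runif(np)) / np, numeric(np))
  pop <- lapply(seq_len(np), function(i)
    apply_fixed(lo + strata[i, ] * rng))
  fit_vals <- vapply(pop, score, numeric(1))
  best_hist <- min(fit_vals)

  for (gen in seq_len(config$n_generations)) {
    ord <- order(fit_vals)
    elite <- pop[ord[seq_len(config$elitism)]]
    newpop <- elite
    while (length(newpop) < config$population_size) {
      p1 <- pop[[roulette_select(fit_vals)]]
      p2 <- pop[[roulette_select(fit_vals)]]
      if (stats::runif(1) < config$crossover_prob) {
        a <- stats::runif(1)
        child <- a * p1 + (1 - a) * p2
      } else child <- p1
      mut <- stats::runif(3) < config$mutation_prob
      # half the mutations anneal towards fine-tuning, half keep the full
      # scale so the search never loses global reach
      fine <- stats::runif(3) < 0.5
      mut_sd <- 0.1 * rng *
        ifelse(fine, config$mutation_decay^(gen - 1), 1)
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, mut_sd[mut])
      newpop[[length(newpop) + 1L]] <- apply_fixed(clamp(child, lo, hi))
    }
    pop <- newpop
    fit_vals <- vapply(pop, score, numeric(1))
    best_hist <- c(best_hist, min(fit_vals))
  }

  best <- pop[[which.min(fit_vals)]]
  d <- decode_genome(best, b)
  model <- fit_rbf_pls(X, y, sigma = d$sigma, n_centers = d$n_centers,
                       n_latent = d$n_latent, seed = config$seed,
                       centers = fixed$centers %||% NULL)
  model$features <- features
  model$train_meta <- list(seed = config$seed, ga_config = config,
                           best_genome = best, decoded = d,
                           cv_fitness = min(fit_vals),
                           best_per_generation = best_hist)
  model
}

#' Fit a baseline nitrogen regressor
#'
#' Two baselines accompany the hybrid model: `"grl"`, ordinary
#' least-squares multiple linear regression of nitrogen on the features
#' plus an intercept; and `"grm"`, Gaussian-kernel general regression
#' (Nadaraya-Watson: a kernel-weighted convex combination of training
#' targets) with its bandwidth chosen by leave-one-out cross-validation
#' over a log-spaced grid on the standardized feature scale.
#'
#' @param train data.frame with feature and response columns.
#' @param kind `"grl"` or `"grm"`.
#' @param features,response column names.
#' @param bandwidth_grid candidate bandwidths for `"grm"`.
#' @return a `grl_model` or `grm_model` with a `predict` method.
#' @export
fit_baseline <- function(train, kind = c("grl", "grm"),
                         features = c("area_cm2", "g_mean", "g_var"),
                         response = "nitrogen_gkg",
                         bandwidth_grid = exp(seq(log(0.05), log(5),
                                                  length.out = 25))) {
  kind <- match.arg(kind)
  X <- extract_feature_matrix(train, features)
  y <- train[[response]]
  if (kind == "grl") {
    if (nrow(X) < ncol(X) + 2) stop("too few rows for linear regression")
    df <- data.frame(X, check.names = FALSE)
    df$.y <- y
    fit <- stats::lm(.y ~ ., data = df)
    return(structure(list(fit = fit, features = features),
                     class = "grl_model"))
  }
  scaler <- standardize_fit(X)
  Xs <- standardize_apply(X, scaler)
  D2 <- as.matrix(stats::dist(Xs))^2
  best <- Inf; best_h <- bandwidth_grid[1]
  for (h in bandwidth_grid) {
    Wm <- exp(-D2 / (2 * h^2)); diag(Wm) <- 0
    sw <- rowSums(Wm)
    ok <- sw > 1e-300
    pred <- y
    pred[ok] <- (Wm %*% y)[ok] / sw[ok]
    err <- sqrt(mean((y - pred)^2))
    if (err < best) { best <- err; best_h <- h }
  }
  structure(list(Xs = Xs, y = y, scaler = scaler, bandwidth = best_h,
                 loo_rmse = best, features = features),
            class = "grm_model")
}

#' @export
predict.grl_model <- function(object, newdata, ...) {
  X <- extract_feature_matrix(newdata, object$features)
  unname(stats::predict(object$fit,
                        newdata = data.frame(X, check.names = FALSE)))
}

#' @export
predict.grm_model <- function(object, newdata, ...) {
  X <- extract_feature_matrix(newdata, object$features)
  Xs <- standardize_apply(X, object$scaler)
  xx <- rowSums(Xs^2); cc <- rowSums(object$Xs^2)
  D2 <- pmax(outer(xx, cc, "+") - 2 * Xs %*% t(object$Xs), 0)
  Wm <- exp(-D2 / (2 * object$bandwidth^2))
  sw <- rowSums(Wm)
  pred <- numeric(nrow(Xs))
  ok <- sw > 1e-300
  pred[ok] <- (Wm %*% object$y)[ok] / sw[ok]
  if (any(!ok)) {            # kernel underflow: fall back to nearest target
    nn <- apply(D2[!ok, , drop = FALSE], 1, which.min)
    pred[!ok] <- object$y[nn]
  }
  pred
}

#' Serialize an RBF-PLS model to canonical JSON
#'
#' Arrays are written row-major at full precision; the same model always
#' produces byte-identical files, so seeded training runs can be audited
#' by file comparison.
#'
#' @param model an `rbf_pls_model`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_model <- function(model, path) {
  obj <- list(schema = "leafnitro-rbfpls-1",
              features = model$features,
              sigma = model$sigma,
              n_latent = model$n_latent,
              x_scaler = list(mean = unname(model$x_scaler$mean),
                              sd = unname(model$x_scaler$sd)),
              centers = apply(unname(as.matrix(model$centers)), 1, c,
                              simplify = FALSE),
              pls = list(h_mean = unname(model$pls$h_mean),
                         y_mean = model$pls$y_mean,
                         coefficients = unname(model$pls$coefficients)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an RBF-PLS model written by [write_model()]
#'
#' @param path JSON file path.
#' @return an `rbf_pls_model` usable with [predict.rbf_pls_model()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "leafnitro-rbfpls-1"))
    stop("unrecognized model schema: ", obj$schema)
  centers <- if (is.list(obj$centers))
    do.call(rbind, lapply(obj$centers, as.numeric))
  else as.matrix(obj$centers)
  structure(list(centers = centers, sigma = obj$sigma,
                 n_latent = obj$n_latent,
                 x_scaler = list(mean = obj$x_scaler$mean,
                                 sd = obj$x_scaler$sd),
                 pls = list(h_mean = obj$pls$h_mean,
                            y_mean = obj$pls$y_mean,
                            coefficients = obj$pls$coefficients),
                 features = obj$features,
                 train_meta = list()),
            class = "rbf_pls_model")
}
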