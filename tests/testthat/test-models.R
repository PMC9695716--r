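test_that("the Gaussian kernel matches its closed form and guards", {
  expect_equal(gaussian_rbf(c(1, 2), c(1, 2), 0.7), 1.0)
  # ||x - c||^2 = 2 sigma^2 forces exp(-1)
  s <- 0.9
  x <- c(0, 0); c0 <- c(sqrt(2) * s, 0)
  expect_equal(gaussian_rbf(x, c0, s), exp(-1))
  expect_error(gaussian_rbf(1, 1, 0), "sigma")
  expect_error(gaussian_rbf(c(1, 2), 3, 1), "dimension")

  set.seed(2)
  for (i in 1:100) {
    x <- rnorm(4); c1 <- rnorm(4); s <- runif(1, 0.1, 3)
    d2 <- 0
    for (k in 1:4) d2 <- d2 + (x[k] - c1[k])^2
    expect_equal(gaussian_rbf(x, c1, s), exp(-d2 / (2 * s^2)),
                 tolerance = 1e-12)
  }
})

test_that("activation matrices agree with the double-loop oracle", {
  set.seed(3)
  X <- matrix(rnorm(15 * 3), 15, 3)
  C <- X[1:6, ]
  s <- 0.8
  H <- rbf_activations(X, C, s)
  expect_equal(diag(H[1:6, ]), rep(1, 6))
  brute <- matrix(0, 15, 6)
  for (i in 1:15) for (j in 1:6)
    brute[i, j] <- gaussian_rbf(X[i, ], C[j, ], s)
  expect_equal(H, brute, tolerance = 1e-12)
  expect_true(all(H > 0 & H <= 1))
  # flat-kernel limit
  expect_true(all(rbf_activations(X, C, 1e6) > 1 - 1e-6))
})

test_that("full-rank PLS reproduces the least-squares fit with orthogonal scores", {
  set.seed(5)
  H <- matrix(rnorm(25 * 8), 25, 8)
  y <- rnorm(25)
  f <- pls_fit(H, y, 8)
  Hc <- scale(H, scale = FALSE)
  ls <- mean(y) + Hc %*% qr.coef(qr(Hc), y - mean(y))
  expect_lt(max(abs(f$fitted - ls)), 1e-8)
  G <- crossprod(f$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("one latent variable suffices for a target linear in one column", {
  # mutually orthogonal mean-zero predictors: the covariance direction is
  # then exactly the generating column
  set.seed(6)
  M <- scale(matrix(rnorm(30 * 5), 30, 5), scale = FALSE)
  H <- qr.Q(qr(M))
  y <- 2.5 * H[, 3] + 1
  f <- pls_fit(H, y, 1)
  expect_lt(max(abs(f$fitted - y)), 1e-8)
})

test_that("PLS rejects degenerate inputs", {
  H <- matrix(rnorm(20), 10, 2)
  expect_error(pls_fit(H, rep(3, 10), 1), "zero variance")
  expect_error(pls_fit(H, rnorm(10), 5), "out of range")
  expect_error(pls_fit(H, rnorm(10), 0), "out of range")
})

test_that("RBF-PLS prediction recovers constructed targets and is row-independent", {
  set.seed(7)
  X <- matrix(rnorm(40 * 3), 40, 3)
  ctr <- scale(X)[1:8, ]
  beta <- rnorm(8)
  Xs <- scale(X)
  y <- as.vector(rbf_activations(Xs, ctr, 1.2) %*% beta)
  m <- fit_rbf_pls(X, y, sigma = 1.2, n_centers = 8, n_latent = 8,
                   centers = ctr)
  expect_lt(max(abs(predict(m, X) - y)), 1e-6)
  # permuting rows permutes predictions identically
  p <- sample(40)
  expect_equal(predict(m, X[p, ]), predict(m, X)[p])
})

test_that("a constant target yields a constant predictor", {
  set.seed(8)
  X <- matrix(rnorm(30), 10, 3)
  m <- fit_rbf_pls(X, rep(4.2, 10), sigma = 1, n_centers = 4, n_latent = 2)
  expect_equal(predict(m, matrix(rnorm(15), 5, 3)), rep(4.2, 5),
               tolerance = 1e-9)
})

test_that("predictions are invariant to affine rescaling of a feature", {
  d <- sim_pair(60, 20, seed = 15)
  m1 <- fit_rbf_pls(d$train[, 3:5], d$train$nitrogen_gkg,
                    sigma = 1, n_centers = 10, n_latent = 5, seed = 2)
  tr2 <- d$train; te2 <- d$test
  tr2$g_mean <- 10 * tr2$g_mean - 300
  te2$g_mean <- 10 * te2$g_mean - 300
  m2 <- fit_rbf_pls(tr2[, 3:5], tr2$nitrogen_gkg,
                    sigma = 1, n_centers = 10, n_latent = 5, seed = 2)
  expect_equal(predict(m1, d$test[, 3:5]), predict(m2, te2[, 3:5]),
               tolerance = 1e-8)
})

test_that("absolute-error fitness matches hand arithmetic and the loop oracle", {
  expect_equal(fitness(c(1, 2), c(1, 2)), 0)
  expect_equal(fitness(c(1, 2), c(2, 4), k = 1), 3.0)
  set.seed(9)
  for (i in 1:100) {
    y <- rnorm(12); o <- rnorm(12); k <- runif(1, 0.5, 2)
    brute <- 0
    for (j in 1:12) brute <- brute + abs(y[j] - o[j])
    expect_equal(fitness(y, o, k), k * brute, tolerance = 1e-12)
  }
  expect_error(fitness(1:3, 1:2), "length")
})

test_that("roulette selection follows inverse-fitness probabilities", {
  expect_error(roulette_select(numeric(0)), "empty")
  set.seed(10)
  expect_true(all(replicate(50, roulette_select(5)) == 1L))

  set.seed(11)
  draws <- replicate(1e4, roulette_select(c(1, 1)))
  expect_lt(abs(mean(draws == 1) - 0.5), 0.02)

  set.seed(12)
  draws <- replicate(1e4, roulette_select(c(1, 3)))
  expect_lt(abs(mean(draws == 1) - 0.75), 0.02)
})

test_that("the genetic search is elitist and seeded", {
  d <- sim_pair(40, 10, seed = 21)
  cfg <- ga_config(population_size = 8, n_generations = 5, seed = 3,
                   bounds = list(log_sigma = c(log(0.1), log(5)),
                                 n_centers = c(4, 12),
                                 n_latent = c(1, 6)))
  m <- ga_optimize(d$train, cfg)
  hist <- m$train_meta$best_per_generation
  expect_length(hist, 6)
  expect_true(all(diff(hist) <= 1e-12))

  m2 <- ga_optimize(d$train, cfg)
  expect_identical(m$train_meta$best_genome, m2$train_meta$best_genome)
  expect_equal(predict(m, d$test), predict(m2, d$test))

  # zero generations returns the best of the initial population
  cfg0 <- ga_config(population_size = 6, n_generations = 0, seed = 4)
  m0 <- ga_optimize(d$train, cfg0)
  expect_length(m0$train_meta$best_per_generation, 1)
})

test_that("a one-gene search recovers the generating kernel width", {
  set.seed(105)
  X <- matrix(runif(150, -2, 2), 150, 1)
  Xs <- scale(X)
  ctr <- matrix(seq(-1.4, 1.4, length.out = 8), 8, 1)
  beta <- c(2, -1, 1.5, -0.5, 1, -1.2, 0.8, 0.6)
  y <- as.vector(rbf_activations(Xs, ctr, 0.5) %*% beta)
  df <- data.frame(x = X[, 1], y = y)
  cfg <- ga_config(population_size = 30, n_generations = 25, seed = 6,
                   bounds = list(log_sigma = c(log(0.05), log(5)),
                                 n_centers = c(8, 8), n_latent = c(8, 8)))
  m <- ga_optimize(df, cfg, features = "x", response = "y",
                   fixed = list(n_centers = 8, n_latent = 8, centers = ctr))
  expect_gte(m$sigma, 0.35)
  expect_lte(m$sigma, 0.7)

  grid <- exp(seq(log(0.05), log(5), length.out = 200))
  gv <- vapply(grid, function(s)
    cv_rbf_fitness(X, y, s, 8, 8, cfg, centers = ctr), numeric(1))
  expect_lte(m$train_meta$cv_fitness, 1.05 * min(gv))
})

test_that("the linear baseline solves the normal equations", {
  d <- sim_pair(50, 10, seed = 31)
  tr <- d$train
  # exactly linear noiseless target -> zero residuals
  tr_lin <- tr
  tr_lin$nitrogen_gkg <- 5 + 0.1 * tr$area_cm2 - 0.02 * tr$g_mean +
    0.001 * tr$g_var
  g <- fit_baseline(tr_lin, "grl")
  expect_lt(max(abs(predict(g, tr_lin) - tr_lin$nitrogen_gkg)), 1e-8)

  g2 <- fit_baseline(tr, "grl")
  Xd <- cbind(1, as.matrix(tr[, c("area_cm2", "g_mean", "g_var")]))
  beta <- solve(crossprod(Xd), crossprod(Xd, tr$nitrogen_gkg))
  expect_equal(unname(coef(g2$fit)), as.vector(beta), tolerance = 1e-8)
  # residual orthogonality to the design
  r <- tr$nitrogen_gkg - predict(g2, tr)
  expect_lt(max(abs(crossprod(Xd, r))), 1e-6)
})

test_that("general regression interpolates as the bandwidth shrinks", {
  d <- sim_pair(30, 5, seed = 41)
  g <- fit_baseline(d$train, "grm")
  # prediction is a convex combination of training targets
  p <- predict(g, d$test)
  expect_true(all(p >= min(d$train$nitrogen_gkg) - 1e-9))
  expect_true(all(p <= max(d$train$nitrogen_gkg) + 1e-9))
  # tiny bandwidth -> training point converges to its own target
  g$bandwidth <- 1e-3
  expect_equal(predict(g, d$train[3, ]), d$train$nitrogen_gkg[3],
               tolerance = 1e-6)
})

test_that("model serialization is canonical and round-trips predictions", {
  d <- sim_pair(40, 10, seed = 51)
  m <- fit_rbf_pls(d$train[, 3:5], d$train$nitrogen_gkg,
                   sigma = 1.1, n_centers = 8, n_latent = 4, seed = 5)
  m$features <- c("area_cm2", "g_mean", "g_var")
  td <- withr::local_tempdir()
  p1 <- file.path(td, "m1.json"); p2 <- file.path(td, "m2.json")
  write_model(m, p1); write_model(m, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  m2 <- read_model(p1)
  expect_equal(predict(m2, d$test), predict(m, d$test), tolerance = 1e-12)
})
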