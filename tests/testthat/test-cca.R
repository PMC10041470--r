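test_that("first canonical correlation matches closed forms", {
  set.seed(1)
  # 1-D case: canonical correlation equals |Pearson r|
  x <- rnorm(200); y <- -0.6 * x + rnorm(200)
  fit <- suppressWarnings(fitCcaFold(matrix(x), matrix(y)))
  expect_equal(fit$r, abs(cor(x, y)), tolerance = 1e-10)
  # X = Y single column -> r = 1
  fit2 <- suppressWarnings(fitCcaFold(matrix(x), matrix(x)))
  expect_equal(fit2$r, 1, tolerance = 1e-8)
})

test_that("canonical correlation matches the eigenvalue oracle and cancor", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 120
    X <- matrix(rnorm(n * 3), n)
    Y <- cbind(0.5 * X[, 1] + rnorm(n), rnorm(n))
    fit <- suppressWarnings(fitCcaFold(X, Y))
    expect_equal(fit$r, cca_eigen_oracle(X, Y), tolerance = 1e-8)
    cc <- cancor(X, Y)
    expect_equal(fit$r, cc$cor[1], tolerance = 1e-8)
  }
})

test_that("singular covariance falls back to a logged ridge", {
  set.seed(3)
  x <- rnorm(60)
  X <- cbind(x, x)          # perfectly collinear
  Y <- matrix(0.4 * x + rnorm(60))
  fit <- suppressWarnings(fitCcaFold(X, Y))
  expect_true(fit$jitter)
  expect_true(is.finite(fit$r))
})

test_that("fold residualization removes a planted covariate effect", {
  set.seed(11)
  n <- 1000
  age <- rnorm(n)
  data <- cbind(a = 2 * age + rnorm(n), b = rnorm(n))
  fold <- rep(1:5, length.out = n)
  res <- residualizeCovariates(data, cbind(age = age), fold)
  expect_lt(abs(cor(res[fold == 1, "a"], age[fold == 1])), 0.1)
  # zero-variance covariate dropped with a warning; residuals centred
  expect_warning(r2 <- residualizeCovariates(data, cbind(z = rep(1, n), age)),
                 "zero-variance")
  expect_lt(abs(mean(r2[, "a"])), 1e-10)
})

test_that("cross-validated r recovers a planted association and pools folds", {
  set.seed(21)
  n <- 400
  u <- rnorm(n)
  X <- sapply(1:4, function(i) 0.8 * u + 0.6 * rnorm(n))
  Y <- sapply(1:3, function(i) 0.8 * (0.5 * u + sqrt(0.75) * rnorm(n)) +
                0.6 * rnorm(n))
  res <- crossValidateCca(X, Y, k_folds = 10, seed = 2)
  expect_equal(sort(unique(res@fold_assignment)), 1:10)
  expect_gt(res@cross_fold_r, 0.2)
  # leave-one-out boundary on a tiny fixture
  res_loo <- suppressWarnings(
    crossValidateCca(X[1:30, ], Y[1:30, ], k_folds = 10, seed = 1))
  expect_equal(length(res_loo@variate_x), 30)
  expect_error(crossValidateCca(X[1:10, ], Y[1:10, ], k_folds = 5, seed = 1),
               "fewer than 3")
})

test_that("cross-fold r is invariant to column rescaling", {
  set.seed(31)
  n <- 200
  X <- matrix(rnorm(n * 3), n)
  Y <- cbind(0.5 * X[, 1] + rnorm(n), rnorm(n))
  r1 <- crossValidateCca(X, Y, k_folds = 5, seed = 7)@cross_fold_r
  X2 <- sweep(X, 2, c(100, 0.01, 5), "*")
  Y2 <- sweep(Y, 2, c(3, 1000), "*")
  r2 <- crossValidateCca(X2, Y2, k_folds = 5, seed = 7)@cross_fold_r
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("permutation p has its theoretical floor and detects identity", {
  u <- rnorm(60)
  p <- permutationTest(u, u, n_perm = 199, seed = 1)
  expect_equal(p, 1 / 200)
  # observed larger than every permuted r on shifted copies
  v <- u + rnorm(60, sd = 0.01)
  expect_equal(permutationTest(u, v, n_perm = 199, seed = 2), 1 / 200)
})

test_that("permutation p is valid under independence", {
  set.seed(5)
  ps <- replicate(60, {
    u <- rnorm(40); v <- rnorm(40)
    suppressWarnings(
      permutationTest(u, v, n_perm = 99, seed = sample.int(1e6, 1)))
  })
  expect_gt(mean(ps), 0.35)   # roughly uniform, no systematic inflation
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("bootstrap loadings cover planted structure and flag noise", {
  set.seed(9)
  n <- 400
  u <- rnorm(n)
  X <- cbind(v1 = u + 0.3 * rnorm(n), noise = rnorm(n))
  Y <- cbind(w1 = 0.7 * u + rnorm(n))
  res <- crossValidateCca(X, Y, k_folds = 5, seed = 3)
  res <- bootstrapReliability(X, Y, res, n_boot = 400, ci_level = 0.999,
                              seed = 4)
  ld <- res@loadings
  v1_row <- ld[ld$variable == "v1", ]
  noise_row <- ld[ld$variable == "noise", ]
  expect_true(v1_row$robust)
  expect_false(noise_row$robust)
  expect_true(all(ld$lower <= ld$upper))
  # a variable identical to its variate loads at ~1
  X2 <- cbind(v = res@variate_x)
  res2 <- new("CvMultivariateResult", fold_assignment = res@fold_assignment,
              weights_x = matrix(1), weights_y = res@weights_y,
              variate_x = res@variate_x, variate_y = res@variate_y,
              cross_fold_r = res@cross_fold_r, perm_p = NA_real_,
              loadings = NULL, std_coefs = NULL)
  res2 <- bootstrapReliability(X2, Y, res2, n_boot = 200, seed = 5)
  expect_gt(res2@loadings$lower[1], 0.99)
})
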