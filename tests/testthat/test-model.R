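test_that("separable toy data is classified perfectly", {
  X <- rbind(cbind(c(-2, -2, -3, -3), c(-2, -3, -2, -3)),
             cbind(c(2, 2, 3, 3), c(2, 3, 2, 3)))
  y <- c(rep(-1L, 4), rep(1L, 4))
  m <- svm_train(X, y, gamma = 0.5)
  expect_equal(svm_predict(m, X), y)
})

test_that("identical feature rows for both classes neither crash nor separate", {
  X <- matrix(rep(1:5, each = 8), ncol = 5)
  y <- rep(c(1L, -1L), 4)
  m <- svm_train(X, y)
  acc <- mean(svm_predict(m, X) == y)
  expect_gte(acc, 0.4); expect_lte(acc, 0.6)
})

test_that("well-separated Gaussian classes give near-perfect held-out accuracy", {
  # 5-sigma mean separation: closed-form Bayes error ~ pnorm(-2.5) per axis,
  # essentially zero in 5 dimensions
  train <- gaussian_dataset(60, 60, sep = 5, seed = 31)
  test <- gaussian_dataset(40, 40, sep = 5, seed = 32)
  m <- svm_train(train, gamma = 0.1)
  expect_gt(mean(svm_predict(m, test$X) == test$y), 0.95)
})

test_that("a hand-built dual expansion is evaluated exactly", {
  # two support vectors with fixed alpha_i y_i, bias and gamma
  model <- structure(list(SV = rbind(c(0, 0), c(1, 1)),
                          coefs = c(0.7, -0.4), rho = -0.1, orient = 1,
                          gamma = 0.3, C = 1, tolerance = 1e-3,
                          epsilon = 1e-12,
                          scaler = list(center = c(0, 0), scale = c(1, 1)),
                          dim = 2), class = "succ_svm")
  x <- c(0.5, -0.25)
  expected <- 0.7 * exp(-0.3 * sum((c(0, 0) - x)^2)) +
    (-0.4) * exp(-0.3 * sum((c(1, 1) - x)^2)) - (-0.1)
  expect_equal(svm_decision(model, x), expected, tolerance = 1e-12)
  expect_equal(svm_predict(model, x), 1L)

  # gamma -> 0 limit: kernel -> 1, decision -> sum(alpha_i y_i) + beta
  model$gamma <- 1e-15
  expect_equal(svm_decision(model, x), 0.7 - 0.4 + 0.1, tolerance = 1e-9)

  expect_error(svm_decision(model, c(1, 2, 3)), "features")
})

test_that("explicit dual-expansion evaluation agrees with the libsvm solver", {
  train <- gaussian_dataset(50, 50, sep = 2, seed = 33)
  m <- svm_train(train, C = 1, gamma = 0.01)
  set.seed(34)
  Xnew <- matrix(rnorm(100 * 5, mean = 1), ncol = 5)
  ours <- svm_decision(m, Xnew)
  # the solver's own decision values, via its internal prediction path
  Xs <- sweep(sweep(Xnew, 2, m$scaler$center), 2, m$scaler$scale, "/")
  refit <- e1071::svm(sweep(sweep(train$X, 2, m$scaler$center), 2,
                            m$scaler$scale, "/"),
                      factor(train$y, levels = c(-1, 1)),
                      type = "C-classification", kernel = "radial",
                      cost = 1, gamma = 0.01, scale = FALSE)
  ref <- attr(predict(refit, Xs, decision.values = TRUE), "decision.values")
  ref <- as.vector(ref)
  if (cor(ours, ref) < 0) ref <- -ref      # libsvm's sign is class-order bound
  expect_lt(max(abs(ours - ref)), 1e-8)
  expect_equal(svm_predict(m, Xnew), ifelse(ours >= 0, 1L, -1L))
})

test_that("decision sign convention maps +1 to the positive class regardless of row order", {
  base <- gaussian_dataset(30, 30, sep = 4, seed = 35)
  flipped <- dataset_subset(base, rev(seq_along(base$y)))
  m1 <- svm_train(base, gamma = 0.1)
  m2 <- svm_train(flipped, gamma = 0.1)
  expect_gt(mean(svm_decision(m1, base$X[base$y == 1L, ]) > 0), 0.9)
  expect_gt(mean(svm_decision(m2, base$X[base$y == 1L, ]) > 0), 0.9)
})

test_that("training is deterministic and scale-invariant through the z-scorer", {
  d <- gaussian_dataset(40, 40, sep = 2, seed = 36)
  m1 <- svm_train(d); m2 <- svm_train(d)
  expect_equal(m1$SV, m2$SV)
  expect_equal(svm_decision(m1, d$X), svm_decision(m2, d$X), tolerance = 1e-6)

  # multiplying a raw feature column by 1000 must not change predictions
  d2 <- d; d2$X[, 3] <- d2$X[, 3] * 1000
  m3 <- svm_train(d2)
  expect_equal(svm_predict(m3, d2$X), svm_predict(m1, d$X))
})

test_that("degenerate training inputs raise errors", {
  X <- matrix(rnorm(20), ncol = 2)
  expect_error(svm_train(X, rep(1L, 10)), "single class")
  Xn <- X; Xn[1, 1] <- NA
  expect_error(svm_train(Xn, rep(c(1L, -1L), 5)), "missing")
  expect_error(svm_train(X, c(rep(0L, 5), rep(1L, 5))), "labels")
})

test_that("models survive a JSON serialisation round trip", {
  d <- gaussian_dataset(30, 30, sep = 3, seed = 37)
  m <- svm_train(d)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(svm_decision(m2, d$X), svm_decision(m, d$X), tolerance = 1e-10)
  expect_error(read_model(withr::local_tempfile(lines = "{\"format\":\"x\"}")),
               "format")
})
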