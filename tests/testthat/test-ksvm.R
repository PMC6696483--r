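test_that("kernel closed forms match hand computations", {
  kg <- kernel_params("grbf", sigma2 = 1)
  expect_equal(kernel_value(kg, c(3, -2), c(3, -2)), 1)
  expect_equal(kernel_value(kg, c(0, 0), c(1, 1)), exp(-1))

  kp <- kernel_params("polynomial", d = 1, beta0 = 0)
  zr <- c(1.5, -2); zs <- c(0.5, 3)
  expect_equal(kernel_value(kp, zr, zs), sum(zr * zs))  # linear special case

  kp2 <- kernel_params("polynomial", d = 3, beta0 = 2)
  expect_equal(kernel_value(kp2, zr, zs), (sum(zr * zs) + 2)^3)

  kt <- kernel_params("perceptron", beta0 = 0.5, beta1 = 1)
  expect_equal(kernel_value(kt, zr, zs), tanh(0.5 * sum(zr * zs) + 1))

  expect_error(kernel_value(kg, c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(kernel_value(kg, c(NA, 1), c(0, 0)), "non-finite")
  expect_error(kernel_params("grbf", sigma2 = 0), "sigma2")
  expect_error(kernel_params("polynomial", d = 0), "d >= 1")
})

test_that("Mercer kernel matrices are symmetric PSD with the expected diagonal", {
  set.seed(42)
  Z <- matrix(rnorm(10), 5, 2)
  for (k in list(kernel_params("grbf", sigma2 = 0.7),
                 kernel_params("polynomial", d = 2, beta0 = 1))) {
    K <- kernel_matrix(k, Z)
    expect_equal(K, t(K))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) >= -1e-8 * max(ev))
  }
  Kg <- kernel_matrix(kernel_params("grbf"), Z)
  expect_equal(diag(Kg), rep(1, 5))
  expect_equal(kernel_matrix(kernel_params("grbf"), matrix(2, 1, 1)),
               matrix(1, 1, 1))
})

test_that("degree-2 polynomial kernel equals an explicit feature embedding", {
  b0 <- 1.7
  k <- kernel_params("polynomial", d = 2, beta0 = b0)
  phi <- function(z) c(z[1]^2, z[2]^2, sqrt(2) * z[1] * z[2],
                       sqrt(2 * b0) * z[1], sqrt(2 * b0) * z[2], b0)
  set.seed(3)
  for (i in 1:20) {
    zr <- rnorm(2); zs <- rnorm(2)
    expect_equal(kernel_value(k, zr, zs), sum(phi(zr) * phi(zs)),
                 tolerance = 1e-12)
  }
})

test_that("the two-point problem has the known closed-form dual solution", {
  K <- matrix(c(1, -1, -1, 1), 2)  # linear kernel on z = +1, z = -1
  y <- c(1, -1)
  sol <- solve_dual(K, y, C = 10, tol = 1e-8)
  expect_equal(sol$lambda, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sol$b, 0, tolerance = 1e-6)
  expect_equal(sol$objective, -0.5, tolerance = 1e-6)

  m <- svm_train(matrix(c(1, -1), 2, 1), y,
                 kernel_params("polynomial", d = 1, beta0 = 0, C = 10))
  expect_equal(decision_value(m, 0), 0, tolerance = 1e-6)
  expect_equal(decision_value(m, 1), 1, tolerance = 1e-6)
  expect_equal(decision_value(m, -1), -1, tolerance = 1e-6)
})

test_that("SMO matches the brute-force QP oracle on 100 seeded instances", {
  worst <- 0
  for (s in 1:100) {
    set.seed(s)
    n <- sample(6:20, 1)
    J <- sample(1:3, 1)
    Z <- matrix(rnorm(n * J), n)
    y <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    C <- sample(c(0.5, 1, 10), 1)
    k <- kernel_params("grbf", sigma2 = runif(1, 0.3, 3), C = C)
    K <- kernel_matrix(k, Z)
    sol <- solve_dual(K, y, C = C, tol = 1e-8)
    orc <- qp_dual_oracle(K, y, C)
    worst <- max(worst, abs(sol$objective - orc$objective))
    expect_lt(abs(sol$objective - orc$objective), 1e-6)
  }
  expect_lt(worst, 1e-6)
})

test_that("accepted dual solutions satisfy the box and equality constraints", {
  for (s in 1:20) {
    task <- make_binary_task(n_per = 10, J = 2, gap = runif(1, 1, 5), seed = s)
    C <- sample(c(0.5, 1, 5), 1)
    k <- kernel_params("grbf", sigma2 = 1, C = C)
    sol <- solve_dual(kernel_matrix(k, task$Z), task$y, C = C, tol = 1e-6)
    expect_true(all(sol$lambda >= -1e-12 & sol$lambda <= C + 1e-12))
    expect_lt(abs(sum(sol$lambda * task$y)), 1e-6)
  }
})

test_that("free support vectors sit on the margin and separable fits are exact", {
  task <- make_binary_task(n_per = 15, J = 2, gap = 6, seed = 2)
  k <- kernel_params("grbf", sigma2 = 2, C = 1000)  # effectively hard margin
  m <- svm_train(task$Z, task$y, k, tol = 1e-8)
  f <- decision_value(m, task$Z)
  expect_equal(mcr(sign(f), task$y), 0)  # separable limit: training MCR 0
  # KKT margin condition: |f| = 1 at free support vectors
  free <- m$lambda > 1e-6 & m$lambda < k$C - 1e-6
  expect_true(any(free))
  fsv <- decision_value(m, m$support_vectors)
  expect_equal(unname(abs(fsv[free])), rep(1, sum(free)), tolerance = 1e-4)
  expect_error(solve_dual(matrix(1, 2, 2), c(1, 1), 1), "both classes")
})

test_that("linear-kernel decisions agree with an independent primal linear SVM", {
  task <- make_binary_task(n_per = 12, J = 3, gap = 3, seed = 8)
  k <- kernel_params("polynomial", d = 1, beta0 = 0, C = 1)
  m <- svm_train(task$Z, task$y, k, tol = 1e-8)
  f_ours <- decision_value(m, task$Z)
  sv <- e1071::svm(task$Z, factor(task$y), kernel = "linear", cost = 1,
                   scale = FALSE)
  f_ref <- attr(predict(sv, task$Z, decision.values = TRUE),
                "decision.values")[, 1]
  s <- sign(sum(f_ours * f_ref))  # e1071's sign depends on factor order
  expect_equal(f_ours, s * f_ref, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("decision values are invariant to splitting a support vector's mass", {
  task <- make_binary_task(n_per = 8, J = 2, gap = 4, seed = 5)
  k <- kernel_params("grbf", sigma2 = 1.5, C = 1)
  m <- svm_train(task$Z, task$y, k, tol = 1e-8)
  # duplicate the first support vector, halving its dual mass
  m2 <- m
  m2$support_vectors <- rbind(m$support_vectors, m$support_vectors[1, ])
  m2$dual_coeffs <- c(m$dual_coeffs, m$dual_coeffs[1] / 2)
  m2$dual_coeffs[1] <- m$dual_coeffs[1] / 2
  m2$lambda <- c(m2$lambda, m2$lambda[1] / 2); m2$lambda[1] <- m2$lambda[1] / 2
  grid <- matrix(rnorm(40), 20, 2)
  expect_equal(decision_value(m, grid), decision_value(m2, grid),
               tolerance = 1e-6)
})

test_that("a model with no support vectors predicts its bias everywhere", {
  m <- structure(list(support_vectors = matrix(0, 0, 2), dual_coeffs = numeric(0),
                      lambda = numeric(0), bias = -0.3,
                      kernel = kernel_params("grbf"), positive_class = 1L,
                      n_train = 0L), class = "binary_svm")
  expect_equal(decision_value(m, matrix(rnorm(10), 5, 2)), rep(-0.3, 5))
})
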