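test_that("a separable 1-D problem trains perfectly with a boundary between the classes", {
  x <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c(-1, -1, 1, 1)
  m <- svm_train(x, y, kernel = "linear", C = 10, standardize = FALSE)
  expect_equal(svm_predict(m, x), y)
  dec <- svm_decision(m, matrix(seq(-1, 1, by = 0.01), ncol = 1))
  crossing <- which(diff(sign(dec)) != 0)
  expect_gt(length(crossing), 0)   # boundary strictly inside (-1, 1)
})

test_that("XOR needs the RBF kernel", {
  x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(-1, -1, 1, 1)
  m_lin <- svm_train(x, y, kernel = "linear", C = 10)
  expect_lte(mean(svm_predict(m_lin, x) == y), 0.75)
  m_rbf <- svm_train(x, y, kernel = "rbf", C = 10, gamma = 1)
  expect_equal(mean(svm_predict(m_rbf, x) == y), 1)
})

test_that("every fit satisfies dual feasibility (KKT)", {
  set.seed(30)
  for (i in 1:10) {
    n <- sample(6:16, 1)
    x <- matrix(rnorm(2 * n), n)
    y <- rep(c(-1, 1), length.out = n)
    x[y == 1, 1] <- x[y == 1, 1] + runif(1, 0, 2)
    cfg <- default_svm_grid()[sample(1:12, 1), ]
    m <- svm_train(x, y, kernel = as.character(cfg$kernel), C = cfg$C,
                   gamma = ifelse(is.na(cfg$gamma), 1, cfg$gamma))
    k <- check_kkt(m)
    expect_true(k$ok)
    expect_true(all(m$lambda >= -1e-9 & m$lambda <= m$C + 1e-6))
  }
})

test_that("decision values agree with an independent QP oracle on small instances", {
  set.seed(31)
  cases <- list(list(kernel = "linear", C = 1, gamma = 1),
                list(kernel = "linear", C = 10, gamma = 1),
                list(kernel = "rbf", C = 1, gamma = 1),
                list(kernel = "rbf", C = 10, gamma = 0.1))
  for (cs in cases) {
    n <- 10
    x <- matrix(rnorm(2 * n), n)
    y <- rep(c(-1, 1), each = n / 2)
    x[y == 1, ] <- x[y == 1, ] + 1.5
    m <- svm_train(x, y, kernel = cs$kernel, C = cs$C, gamma = cs$gamma)
    o <- svm_qp_oracle(x, y, kernel = cs$kernel, C = cs$C, gamma = cs$gamma)
    grid <- matrix(rnorm(2 * 8), 8) + 0.75
    expect_lt(max(abs(svm_decision(m, grid) - o$decision(grid))), 1e-3)
  }
})

test_that("duplicating every training point leaves the boundary unchanged", {
  set.seed(32)
  x <- rbind(matrix(rnorm(10, -2, 0.3), 5), matrix(rnorm(10, 2, 0.3), 5))
  y <- rep(c(-1, 1), each = 5)
  m1 <- svm_train(x, y, kernel = "linear", C = 10, standardize = FALSE)
  m2 <- svm_train(rbind(x, x), c(y, y), kernel = "linear", C = 10,
                  standardize = FALSE)
  probe <- matrix(rnorm(20), 10)
  expect_lt(max(abs(svm_decision(m1, probe) - svm_decision(m2, probe))), 1e-3)
})

test_that("an exact-zero decision maps to drowsy with a warning", {
  expect_warning(lab <- drowsyhrv:::.decision_to_label(c(-0.5, 0, 0.5)),
                 "fail-safe")
  expect_equal(lab, c(-1, 1, 1))
})

test_that("single-class input and dimension mismatches are errors", {
  x <- matrix(rnorm(10), 5)
  expect_error(svm_train(x, rep(1, 5)), "single-class")
  m <- svm_train(rbind(x, x + 3), rep(c(-1, 1), each = 5))
  expect_error(svm_decision(m, matrix(1, 1, 3)), "dimension mismatch")
})

test_that("LOO on a linearly separable set is perfect across the grid's best cell", {
  set.seed(33)
  x <- cbind(c(rnorm(10, -3, 0.5), rnorm(10, 3, 0.5)), rnorm(20))
  y <- rep(c(-1, 1), each = 10)
  lv <- loo_validate(x, y)
  expect_equal(nrow(lv$results), 12)   # 3 linear + 9 rbf cells
  expect_true(any(lv$results$kernel == "rbf" & lv$results$gamma == 0.1 &
                    lv$results$C == 1))
  expect_equal(lv$best$accuracy, 1)
  expect_equal(lv$best$sensitivity, 1)
  expect_equal(lv$best$specificity, 1)
})

test_that("LOO under permuted labels hovers at chance", {
  set.seed(34)
  x <- matrix(rnorm(40), 20)
  one_cell <- data.frame(kernel = "rbf", C = 1, gamma = 1)
  accs <- replicate(20, {
    y <- sample(rep(c(-1, 1), each = 10))
    loo_validate(x, y, grid = one_cell)$best$accuracy
  })
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("metrics follow their defining identities", {
  m <- classification_metrics(10, 10, 0, 0)
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity), c(1, 1, 1))
  m2 <- classification_metrics(0, 10, 0, 10)
  expect_equal(c(m2$accuracy, m2$sensitivity, m2$specificity), c(0.5, 0, 1))
  m3 <- classification_metrics(5, 5, 5, 5)
  expect_equal(c(m3$accuracy, m3$sensitivity, m3$specificity), c(0.5, 0.5, 0.5))
  m4 <- classification_metrics(9, 9, 1, 1)
  expect_equal(c(m4$accuracy, m4$sensitivity, m4$specificity), c(0.9, 0.9, 0.9))
  expect_error(classification_metrics(0, 0, 0, 0), "zero")
  m5 <- classification_metrics(0, 5, 5, 0)
  expect_true(is.na(m5$sensitivity))
})
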