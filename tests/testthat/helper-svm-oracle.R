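# Independent small-instance SVM oracle: solves the soft-margin dual
#   min 1/2 a' (yy' * K) a - 1'a   s.t.  y'a = 0,  0 <= a <= C
# with kernlab's interior-point QP solver, then recovers the bias from the
# free support vectors. Used only to cross-check svm_train(); shares no code
# with the implementation under test.

oracle_kernel <- function(a, b, kernel, gamma) {
  if (kernel == "linear") return(a %*% t(b))
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  exp(-gamma * pmax(d2, 0))
}

svm_qp_oracle <- function(x, y, kernel = "linear", C = 1, gamma = 1,
                          standardize = TRUE) {
  x <- as.matrix(x)
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd); scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  n <- nrow(x)
  K <- oracle_kernel(x, x, kernel, gamma)
  H <- (y %*% t(y)) * K
  sol <- kernlab::ipop(c = rep(-1, n), H = H, A = matrix(y, 1), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0, sigf = 9,
                       maxiter = 1000)
  alpha <- kernlab::primal(sol)
  free <- which(alpha > 1e-5 * C & alpha < C * (1 - 1e-5))
  if (!length(free)) free <- which(alpha > 1e-5 * C)
  bias <- mean(y[free] - (K[free, , drop = FALSE] %*% (alpha * y)))
  decision <- function(newx) {
    newx <- sweep(sweep(as.matrix(newx), 2, ctr), 2, scl, "/")
    as.numeric(oracle_kernel(newx, x, kernel, gamma) %*% (alpha * y) + bias)
  }
  list(alpha = alpha, bias = bias, decision = decision)
}
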