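random_spd <- function(p) crossprod(matrix(rnorm(p * p), p)) + diag(p)

test_that("Riemannian distance matches closed forms and is affine invariant", {
  expect_equal(riemannian_distance(matrix(4), matrix(1)), log(4),
               tolerance = 1e-12)
  expect_equal(riemannian_distance(matrix(2), matrix(2)), 0)
  set.seed(41)
  for (i in 1:5) {
    P <- random_spd(4); Q <- random_spd(4)
    A <- matrix(rnorm(16), 4)
    expect_equal(riemannian_distance(P, Q),
                 riemannian_distance(t(A) %*% P %*% A, t(A) %*% Q %*% A),
                 tolerance = 1e-8)
  }
  expect_error(riemannian_distance(matrix(-1), matrix(1)), "positive definite")
})

test_that("Frechet mean reproduces the geodesic midpoint and geometric means", {
  set.seed(42)
  P <- random_spd(4); Q <- random_spd(4)
  Ps <- erdica:::.spd_sqrt(P); Pi <- erdica:::.spd_isqrt(P)
  midpoint <- Ps %*% erdica:::.spd_sqrt(Pi %*% Q %*% Pi) %*% Ps
  expect_equal(unclass(riemannian_mean(list(P, Q))), midpoint,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unclass(riemannian_mean(list(P))), P, ignore_attr = TRUE)
  D <- list(diag(c(1, 4)), diag(c(9, 16)), diag(c(25, 1)))
  gm <- riemannian_mean(D)
  expect_equal(diag(gm), c((1 * 9 * 25)^(1 / 3), (4 * 16 * 1)^(1 / 3)),
               tolerance = 1e-8)
})

test_that("trial covariances are SPD, respect shrinkage limits, and converge to truth", {
  set.seed(43)
  arr <- array(rnorm(5 * 3 * 800), c(5, 3, 800))
  es <- epoch_set(arr, c(-1, 4), 160, "left", c("a", "b", "c"))
  cs <- trial_covariances(es)
  for (C in cs$mats)
    expect_true(all(eigen(C, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  # identical trials give identical matrices
  arr2 <- array(rep(arr[1, , ], each = 5), c(5, 3, 800))
  cs2 <- trial_covariances(es2 <- epoch_set(arr2, c(-1, 4), 160, "left",
                                            c("a", "b", "c")))
  expect_equal(cs2$mats[[1]], cs2$mats[[5]])
  # shrinkage = 1 gives exactly the scaled identity
  cs3 <- trial_covariances(es, shrinkage = 1)
  C3 <- cs3$mats[[1]]
  expect_equal(C3, diag(rep(C3[1, 1], 3)))
  # white noise at large n: close to identity (law of large numbers)
  arrN <- array(rnorm(2 * 3 * 10000), c(2, 3, 10000))
  esN <- epoch_set(arrN, c(0, 10000 / 160), 160, "left", c("a", "b", "c"))
  csN <- trial_covariances(esN, task_window = c(0, 10000 / 160),
                           shrinkage = 0)
  expect_lt(norm(csN$mats[[1]] - diag(3), "F"), 0.1)
})

test_that("ClassDis is symmetric, near zero under the null, and matches the scalar oracle", {
  set.seed(44)
  mk <- function(mu, n) lapply(seq_len(n), function(i)
    matrix(exp(rnorm(1, mu, 0.5))))
  a <- mk(0, 100); b <- mk(0, 100)
  expect_lte(class_distinctiveness(a, b)$classdis, 0.2)
  b2 <- mk(2, 100)
  r1 <- class_distinctiveness(a, b2)
  r2 <- class_distinctiveness(b2, a)
  expect_equal(r1$classdis, r2$classdis)
  la <- vapply(a, function(m) log(m[1]), numeric(1))
  lb <- vapply(b2, function(m) log(m[1]), numeric(1))
  oracle <- abs(mean(la) - mean(lb)) /
    (0.5 * (mean(abs(la - mean(la))) + mean(abs(lb - mean(lb)))))
  expect_equal(r1$classdis, oracle, tolerance = 1e-10)
})

test_that("ClassDis handles degenerate dispersion and is affine invariant", {
  expect_warning(
    r <- class_distinctiveness(list(matrix(1)), list(matrix(exp(2)))),
    "dispersion")
  expect_identical(r$classdis, Inf)
  expect_equal(class_distinctiveness(list(matrix(1), matrix(1)),
                                     list(matrix(1)))$classdis, 0)
  set.seed(45)
  A <- lapply(1:8, function(i) random_spd(3))
  B <- lapply(1:8, function(i) random_spd(3) * 2)
  T <- matrix(rnorm(9), 3)
  tr <- function(set) lapply(set, function(P) t(T) %*% P %*% T)
  expect_equal(class_distinctiveness(A, B)$classdis,
               class_distinctiveness(tr(A), tr(B))$classdis,
               tolerance = 1e-6)
})

test_that("ClassDis grows monotonically with planted mean separation", {
  set.seed(46)
  vals <- vapply(c(0, 0.5, 1, 2), function(shift) {
    A <- lapply(1:40, function(i) matrix(exp(rnorm(1, 0, 0.4))))
    B <- lapply(1:40, function(i) matrix(exp(rnorm(1, shift, 0.4))))
    class_distinctiveness(A, B)$classdis
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
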