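# Covariance templates and their analytic/numerical spectra.

test_that("circulant covariance has the alpha^(cyclic distance) pattern", {
  expect_equal(unclass(circulant_covariance(4, 0)), diag(4),
               ignore_attr = TRUE)
  expect_equal(circulant_covariance(5, 0.5)[1, ],
               c(1, 0.5, 0.25, 0.25, 0.5), ignore_attr = TRUE)
  C <- circulant_covariance(6, 0.8)
  expect_equal(unclass(C), t(unclass(C)))
  expect_gte(min(eigen(unclass(C), symmetric = TRUE)$values), -1e-12)
  expect_error(circulant_covariance(6, 1), "alpha")
  expect_error(circulant_covariance(1, 0.5), "n")
})

test_that("analytic cyclic eigenpairs diagonalize the circulant matrix", {
  for (n in c(4, 8, 64, 256)) {
    C <- unclass(circulant_covariance(n, 0.5))
    lam <- cyclic_eigenvalues(n, 0.5)
    v <- cyclic_eigenvectors(n)
    expect_lt(max(abs(C %*% v - v %*% diag(lam))), 1e-8)
  }
  for (a in seq(0.1, 0.9, by = 0.2)) {
    C <- unclass(circulant_covariance(8, a))
    lam <- cyclic_eigenvalues(8, a)
    v <- cyclic_eigenvectors(8)
    expect_lt(max(abs(C %*% v - v %*% diag(lam))), 1e-8)
  }
})

test_that("cyclic eigenvalues are the DCT of the first row and sum to n", {
  expect_equal(cyclic_eigenvalues(7, 0), rep(1, 7))
  expect_equal(sort(cyclic_eigenvalues(8, 0.6)),
               sort(eigen(unclass(circulant_covariance(8, 0.6)),
                          symmetric = TRUE, only.values = TRUE)$values),
               tolerance = 1e-8)
  for (n in c(5, 8, 13)) # odd n supported by the c_j formulation
    expect_equal(sum(cyclic_eigenvalues(n, 0.4)), n)
})

test_that("cyclic eigenvectors are the fixed-phase real Fourier basis", {
  v <- cyclic_eigenvectors(4)
  expect_equal(v[, 1], rep(1 / 2, 4))                 # constant mode
  expect_equal(v[2, 2], 0.5)                          # sqrt(2/4)*cos(pi/4)
  g <- crossprod(cyclic_eigenvectors(16))
  expect_lt(max(abs(g - diag(16))), 1e-10)
  # deterministic phase convention: repeated calls identical
  expect_identical(cyclic_eigenvectors(9), cyclic_eigenvectors(9))
})

test_that("KMS covariance is alpha^|i-j| and positive definite", {
  expect_equal(unclass(kms_covariance(3, 0.5)),
               matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3),
               ignore_attr = TRUE)
  expect_equal(unclass(kms_covariance(4, 0)), diag(4), ignore_attr = TRUE)
  ev <- eigen(unclass(kms_covariance(50, 0.9)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("KMS eigenvalue approximation is accurate and improves with n", {
  expect_equal(linear_eigenvalues(6, 0), rep(1, 6))
  expect_true(all(linear_eigenvalues(10, 0.5) > 0))
  relerr <- function(n, a) {
    num <- sort(eigen(unclass(kms_covariance(n, a)), symmetric = TRUE,
                      only.values = TRUE)$values)
    max(abs(sort(linear_eigenvalues(n, a)) - num) / num)
  }
  errs <- vapply(c(10, 50, 200), relerr, numeric(1), a = 0.7)
  expect_lt(relerr(100, 0.7), 0.05)
  expect_true(all(diff(errs) < 0))     # error decreases with n
})

test_that("numerical_template sorts, validates, and reconstructs", {
  spec <- numerical_template(diag(5))
  expect_equal(spec$eigenvalues, rep(1, 5))
  expect_equal(spectrum_covariance(spec), diag(5), tolerance = 1e-10)
  spec2 <- numerical_template(unclass(circulant_covariance(8, 0.6)))
  expect_equal(sort(spec2$eigenvalues), sort(cyclic_eigenvalues(8, 0.6)),
               tolerance = 1e-8)
  expect_false(is.unsorted(rev(spec2$eigenvalues)))
  expect_error(numerical_template(matrix(1:4, 2)), "symmetric")
  indef <- diag(c(1, -1))
  expect_error(numerical_template(indef), "indefinite")
  expect_equal(numerical_template(indef, clip_negative = TRUE)$eigenvalues,
               c(1, 0))
})

test_that("dropping the top cyclic component removes the constant direction", {
  spec <- cyclic_template(12, 0.7, drop_top = TRUE)
  expect_true(spec$dropped_top)
  expect_length(spec$eigenvalues, 11)
  proj <- crossprod(spec$eigenvectors, rep(1, 12))
  expect_lt(max(abs(proj)), 1e-8)
  expect_warning(drop_top_component(spec), "already dropped")
})

test_that("template spectra reproduce their covariance matrices", {
  for (make in list(function() circulant_covariance(9, 0.6),
                    function() kms_covariance(9, 0.6))) {
    C <- make()
    spec <- numerical_template(unclass(C))
    expect_lt(max(abs(spectrum_covariance(spec) - unclass(C))), 1e-6)
    expect_equal(sum(spec$eigenvalues), 9, tolerance = 1e-10)  # trace
  }
})

test_that("cluster covariance is the expected PSD block matrix", {
  expect_equal(unclass(cluster_covariance(c("a", "a"), 1)),
               matrix(1, 2, 2), ignore_attr = TRUE)
  expect_equal(unclass(cluster_covariance(c("a", "a", "b"), 0.5)),
               matrix(c(1, .5, 0, .5, 1, 0, 0, 0, 1), 3),
               ignore_attr = TRUE)
  set.seed(1)
  labs <- sample(letters[1:4], 30, replace = TRUE)
  ev <- eigen(unclass(cluster_covariance(labs, 0.8)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(sum(ev), 30, tolerance = 1e-10)
  expect_error(cluster_covariance(character(0)), "nonempty")
})

test_that("block-circulant covariance stacks circulant blocks", {
  one <- block_circulant_covariance(5, 0.5)
  expect_equal(unclass(one), unclass(circulant_covariance(5, 0.5)),
               ignore_attr = TRUE)
  two <- block_circulant_covariance(c(4, 4), c(0.5, 0.5), cross_corr = 0)
  expect_equal(unclass(two)[1:4, 1:4],
               unclass(circulant_covariance(4, 0.5)), ignore_attr = TRUE)
  expect_equal(unclass(two)[1:4, 5:8], matrix(0, 4, 4))
  mixed <- block_circulant_covariance(c(8, 8), c(0.6, 0.3), cross_corr = 0.1)
  ev <- eigen(unclass(mixed), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_error(block_circulant_covariance(c(4, 4), c(0.9, 0.9),
                                          cross_corr = 0.95),
               "cross_corr")
})

test_that("spatial affinity template uses shortest-path heat kernels", {
  # 3 collinear points, k=1: symmetrized chain, d(1,3) = 2
  coords <- cbind(c(0, 1, 2), 0)
  spec <- spatial_affinity_template(coords, k_neighbors = 1, bandwidth = 1)
  aff <- attr(spec, "affinity")
  expect_equal(diag(aff), rep(1, 3))
  expect_equal(aff[1, 3], exp(-4 / 2))           # d = 2
  expect_equal(aff, t(aff), tolerance = 1e-12)
  expect_gte(min(spec$eigenvalues), 0)
  # two far-apart pairs with k=1 stay disconnected
  far <- cbind(c(0, 0.1, 50, 50.1), 0)
  expect_error(spatial_affinity_template(far, k_neighbors = 1),
               "disconnected")
})
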