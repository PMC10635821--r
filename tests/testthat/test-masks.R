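# Gene-mask inference, enhancement, and filtering.

test_that("gene mask solves the separable box problem exactly", {
  A <- scale_unit(random_matrix(10, 6, seed = 1), "genes")
  spec <- cyclic_template(10, 0.6, drop_top = TRUE)
  # gamma = 0: nonnegative quadratic minimized at the zero mask, exactly
  gm0 <- infer_gene_mask(A, spec, optimizer_config(gamma = 0))
  expect_identical(unname(gm0$d), rep(0, 6))
  # closed form d_j = clip(gamma/(2 g_j)) against the independent energy
  C <- spectrum_covariance(spec)
  g <- diag(t(A) %*% C %*% A)
  gm <- infer_gene_mask(A, spec, optimizer_config(gamma = 0.3))
  expect_equal(unname(gm$d), unname(pmin(1, 0.3 / (2 * g))),
               tolerance = 1e-10)
  expect_equal(gm$scores + gm$d, rep(1, 6), ignore_attr = TRUE)
  expect_true(all(gm$d >= 0 & gm$d <= 1))
  # the masked solution beats box-edge alternatives on the objective
  objective <- function(d) sum(d^2 * g) - 0.3 * sum(d)
  expect_lte(objective(gm$d), objective(rep(0, 6)) + 1e-12)
  expect_lte(objective(gm$d), objective(rep(1, 6)) + 1e-12)
})

test_that("an all-zero gene gets d = 1 under positive regularization", {
  A <- random_matrix(8, 4, seed = 2)
  A[, 2] <- 0
  spec <- cyclic_template(8, 0.5, drop_top = TRUE)
  gm <- suppressWarnings(
    infer_gene_mask(scale_unit(A, "genes"), spec,
                    optimizer_config(gamma = 0.1)))
  expect_equal(unname(gm$d[2]), 1)
  gm0 <- suppressWarnings(
    infer_gene_mask(scale_unit(A, "genes"), spec,
                    optimizer_config(gamma = 0)))
  expect_equal(unname(gm0$d[2]), 0)
})

test_that("cyclic-informative genes outrank noise genes (AUC >= 0.9)", {
  # 100 genes that vary along a planted cycle vs 100 unstructured binary
  # genes; informativeness scores must rank them apart
  aucs <- sapply(1:5, function(seed) {
    mix <- gene_mixture_fixture(seed)
    spec <- cyclic_template(
      nrow(mix$A),
      as.numeric(estimate_alpha(scale_unit(mix$A, "cells"), "cyclic")),
      drop_top = TRUE)
    gm <- infer_gene_mask(suppressWarnings(scale_unit(mix$A, "genes")),
                          spec, optimizer_config(gamma = "auto"))
    auc_score(gm$scores, mix$truth)
  })
  expect_gte(mean(aucs >= 0.9), 0.8)
})

test_that("enhancement keeps an aligned rank-1 matrix intact", {
  spec <- cyclic_template(8, 0.6, drop_top = TRUE)
  g <- seq(0.5, 1.5, length.out = 5)
  A <- spec$eigenvectors[, 1, drop = FALSE] %*% t(g)   # rank-1, aligned
  mk <- enhance_signal(A, spec,
                       optimizer_config(gamma = 0, iterations = 100,
                                        noise_sd = 0.05, seed = 1))
  expect_equal(mk$objective, spec$eigenvalues[1] * sum(g^2),
               tolerance = 1e-8)
  expect_equal(mk$F, matrix(1, 8, 5), tolerance = 1e-8)
})

test_that("enhanced entries never exceed the input for nonnegative data", {
  sim <- simulate_cyclic(p = 60, k = 2, q = 8, seed = 3)
  A <- sim$matrix
  spec <- cyclic_template(nrow(A), 0.8, drop_top = TRUE)
  mk <- enhance_signal(A, spec,
                       optimizer_config(gamma = 0.05, iterations = 60,
                                        noise_sd = 0.05, seed = 2))
  expect_true(all(mk$F >= 0 & mk$F <= 1))
  expect_true(all(mk$enhanced <= A + 1e-12))
})

test_that("filtering is convex: chords dominate the objective", {
  A <- random_matrix(7, 5, seed = 4)
  spec <- cyclic_template(7, 0.5, drop_top = TRUE)
  set.seed(5)
  for (case in 1:5) {
    F1 <- matrix(runif(35), 7, 5)
    F2 <- matrix(runif(35), 7, 5)
    for (tt in c(0.25, 0.5, 0.75)) {
      mid <- topospect:::mask_objective(A, tt * F1 + (1 - tt) * F2, spec, gamma = 0.1)
      chord <- tt * topospect:::mask_objective(A, F1, spec, 0.1) +
        (1 - tt) * topospect:::mask_objective(A, F2, spec, 0.1)
      expect_lte(mid, chord + 1e-9)
    }
  }
})

test_that("filtering descends monotonically and hits the box edges", {
  A <- scale_unit(random_matrix(12, 8, seed = 6), "cells")
  spec <- cyclic_template(12, 0.6, drop_top = TRUE)
  mk <- filter_signal(A, spec, optimizer_config(gamma = 0.05,
                                                iterations = 200))
  expect_true(all(diff(mk$objective_trace) <= 1e-10))
  expect_true(all(mk$F >= 0 & mk$F <= 1))
  # gamma = 0: the nonnegative quadratic is minimized at the zero signal;
  # descent drives the mask to ~0 wherever the data entry is nonnegligible
  # (entries with |a| ~ 0 contribute nothing and converge slowest)
  mk0 <- filter_signal(A, spec, optimizer_config(gamma = 0,
                                                 iterations = 5000, tol = 0))
  expect_lt(tail(mk0$objective_trace, 1), 1e-4 * mk0$objective_trace[1])
  expect_lt(max(mk0$F[abs(A) >= median(abs(A))]), 0.05)
  expect_lt(max(abs(mk0$filtered)), 0.05)
  # huge gamma: the linear reward dominates, nothing is filtered
  big <- max(spec$eigenvalues) * max(rowSums(A^2)) * 10
  mkb <- filter_signal(A, spec, optimizer_config(gamma = big,
                                                 iterations = 50))
  expect_equal(dim(mkb$F), c(12L, 8L))
  expect_equal(max(abs(mkb$F - 1)), 0)
})

test_that("refiltering changes the matrix less than the first filtering", {
  sim <- simulate_cyclic(p = 80, k = 2, q = 10, seed = 7, shuffle = FALSE)
  A <- scale_unit(sim$matrix, "cells")
  spec <- cyclic_template(nrow(A), 0.9, drop_top = TRUE)
  cfg <- optimizer_config(gamma = "auto", iterations = 200)
  mk1 <- filter_signal(A, spec, cfg)
  d1 <- norm(A - mk1$filtered, "F")
  mk2 <- filter_signal(mk1$filtered, spec, cfg)
  d2 <- norm(mk1$filtered - mk2$filtered, "F")
  expect_lt(d2, d1)
})

test_that("enhancement and filtering disentangle composite signals", {
  # each direction is tested away from its ceiling: enhancement on
  # composites whose cluster signal pollutes phase clustering, filtering on
  # composites whose cyclic signal drowns the (weak) cluster signal
  nseeds <- 5
  enh_wins <- 0
  for (seed in 1:nseeds) {
    sim <- simulate_composite(p = 300, k = 3, q = 20, n_clusters = 2,
                              cluster_strength = 0.35, seed = seed,
                              noise_sd = 0.1, shuffle = FALSE)
    A <- sim$matrix
    bins <- phase_bins(sim$true_order, 4)
    spec <- cyclic_template(nrow(A), 0.95, drop_top = TRUE)
    set.seed(seed)
    ari_raw <- adjusted_rand_index(kmeans(A, 4, nstart = 5)$cluster, bins)
    gm <- infer_gene_mask(suppressWarnings(scale_unit(A, "genes")), spec,
                          optimizer_config(gamma = "auto"))
    mk <- enhance_signal(gm$reduced, spec,
                         optimizer_config(gamma = 0, iterations = 80,
                                          noise_sd = 0.05, seed = seed))
    ari_enh <- adjusted_rand_index(
      kmeans(mk$enhanced, 4, nstart = 5)$cluster, bins)
    enh_wins <- enh_wins + (ari_enh > ari_raw)
  }
  expect_gte(enh_wins, nseeds - 1)

  fil_wins <- 0
  for (seed in 1:nseeds) {
    sim <- simulate_composite(p = 300, k = 3, q = 20, n_clusters = 2,
                              cluster_strength = 0.2, seed = seed,
                              noise_sd = 0.1, shuffle = FALSE)
    A <- sim$matrix
    spec <- cyclic_template(nrow(A), 0.95, drop_top = TRUE)
    set.seed(seed)
    ari_raw <- adjusted_rand_index(kmeans(A, 2, nstart = 5)$cluster,
                                   sim$cluster_labels)
    fl <- filter_signal(A, spec,
                        optimizer_config(gamma = "auto", iterations = 150))
    ari_fil <- adjusted_rand_index(
      kmeans(fl$filtered, 2, nstart = 5)$cluster, sim$cluster_labels)
    fil_wins <- fil_wins + (ari_fil > ari_raw)
  }
  expect_gte(fil_wins, nseeds - 1)
})

test_that("projection proportion orders enhanced > raw > filtered", {
  sim <- simulate_composite(p = 200, k = 3, q = 15, n_clusters = 2,
                            cluster_strength = 1, seed = 9, shuffle = FALSE)
  A <- sim$matrix
  spec <- cyclic_template(nrow(A), 0.95, drop_top = TRUE)
  gm <- infer_gene_mask(suppressWarnings(scale_unit(A, "genes")), spec,
                        optimizer_config(gamma = "auto"))
  enh <- enhance_signal(gm$reduced, spec,
                        optimizer_config(gamma = 0, iterations = 60,
                                         noise_sd = 0.05, seed = 1))$enhanced
  fil <- filter_signal(A, spec,
                       optimizer_config(gamma = "auto",
                                        iterations = 150))$filtered
  p_raw <- projection_proportion(A, spec)
  expect_gt(projection_proportion(enh, spec), p_raw)
  expect_gt(p_raw, projection_proportion(fil, spec))
})
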