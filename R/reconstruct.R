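# Cell-ordering reconstruction: maximize the projection of the reordered
# expression matrix onto the template spectrum over the Birkhoff polytope
# (the convex hull of permutation matrices), then round greedily to a
# permutation. The objective
#   f(E) = sum_i lambda_i ||(E A)' v_i||^2 = tr(C E K E'),
# with C = V diag(lambda) V' the retained template covariance and K = A A'
# the data Gram matrix, is convex in E, so its maximum over the polytope is
# attained at a vertex (a permutation); projected stochastic gradient ascent
# with decaying noise walks toward that vertex.

#' Optimizer configuration
#'
#' @param iterations maximum gradient iterations.
#' @param step_size positive step size, or \code{"auto"} for \code{1/L} with
#'   \code{L} the gradient's Lipschitz constant estimated by power iteration.
#' @param noise_sd scale of the Gaussian exploration noise added to each
#'   ascent step (decays as \code{noise_sd/sqrt(t)}); 0 disables it.
#' @param gamma L1 regularization weight for the mask problems (>= 0).
#' @param seed integer seed for stochastic components.
#' @param tol relative objective-change convergence tolerance.
#' @return a list of class \code{optimizer_config}.
#' @export
optimizer_config <- function(iterations = 400, step_size = "auto",
                             noise_sd = 0, gamma = 0, seed = 1L,
                             tol = 1e-6) {
  stopifnot(iterations >= 1, gamma >= 0, noise_sd >= 0)
  if (!identical(step_size, "auto"))
    stopifnot(is.numeric(step_size), step_size > 0)
  structure(list(iterations = as.integer(iterations), step_size = step_size,
                 noise_sd = noise_sd, gamma = gamma, seed = as.integer(seed),
                 tol = tol),
            class = "optimizer_config")
}

#' Spectral projection objective of an ordering
#'
#' Evaluates \code{sum_i lambda_i ||(E A)' v_i||^2} for a doubly stochastic
#' matrix, a permutation, or no reordering (\code{E = NULL}, identity). With
#' the full (undropped) spectrum this equals
#' \code{tr(C (EA)(EA)')} where \code{C} is the template covariance.
#'
#' @param A numeric cells x genes matrix.
#' @param spectrum a \code{template_spectrum}.
#' @param E an \code{n x n} matrix, an integer permutation vector
#'   (\code{E[i]} = original row placed at ordered position \code{i}), or
#'   \code{NULL} for identity.
#' @return the scalar objective value.
#' @export
projection_objective <- function(A, spectrum, E = NULL) {
  A <- as_expression_matrix(A)
  if (nrow(A) != spectrum$n)
    stop("matrix has ", nrow(A), " cells but spectrum expects ", spectrum$n,
         call. = FALSE)
  B <- apply_ordering(A, E)
  pr <- crossprod(spectrum$eigenvectors, B)
  sum(spectrum$eigenvalues * rowSums(pr^2))
}

apply_ordering <- function(A, E) {
  if (is.null(E)) return(A)
  if (is.matrix(E)) {
    if (any(dim(E) != nrow(A)))
      stop("ordering matrix must be n x n", call. = FALSE)
    return(E %*% A)
  }
  perm <- as.integer(unclass(E))
  if (length(perm) != nrow(A) || anyDuplicated(perm))
    stop("permutation must be a bijection on the rows", call. = FALSE)
  A[perm, , drop = FALSE]
}

#' Project a matrix onto the Birkhoff polytope
#'
#' Bregmanian bi-stochastication: alternate the closed-form Euclidean
#' projection onto the affine set of matrices with unit row and column sums
#' with clipping of negative entries, until the maximum constraint violation
#' falls below \code{tol}. Exact (one affine step) whenever the affine
#' projection is already nonnegative.
#'
#' @param M square numeric matrix with finite entries.
#' @param tol maximum allowed deviation of row/column sums from 1.
#' @param max_iter alternation cap; exceeded means non-convergence (error).
#' @return a doubly stochastic matrix of the same dimension.
#' @export
bbs_project <- function(M, tol = 1e-9, max_iter = 10000L) {
  if (!is.matrix(M) || nrow(M) != ncol(M) || any(!is.finite(M)))
    stop("'M' must be a square matrix with finite entries", call. = FALSE)
  n <- nrow(M)
  for (it in seq_len(max_iter)) {
    r <- rowSums(M) - 1
    cl <- colSums(M) - 1
    s <- sum(r)
    M <- M - outer(r, rep(1 / n, n)) - outer(rep(1 / n, n), cl) + s / n^2
    M[M < 0] <- 0
    viol <- max(abs(rowSums(M) - 1), abs(colSums(M) - 1))
    if (viol < tol) return(M)
  }
  stop("bi-stochastication did not converge in ", max_iter, " alternations",
       call. = FALSE)
}

#' Greedily round a doubly stochastic matrix to a permutation
#'
#' Iterates over rows in ascending index order; each row is assigned to its
#' maximum-value column among those not yet taken, ties broken by lowest
#' column index.
#'
#' @param E a doubly stochastic (or any nonnegative square) matrix.
#' @return an integer vector of class \code{permutation}: position \code{i}
#'   of the ordering holds original row \code{perm[i]}. (As a matrix,
#'   \code{P[i, perm[i]] = 1}; the reordered data are \code{A[perm, ]}.)
#' @export
greedy_round <- function(E) {
  stopifnot(is.matrix(E), nrow(E) == ncol(E))
  n <- nrow(E)
  taken <- rep(FALSE, n)
  perm <- integer(n)
  for (i in seq_len(n)) {
    row <- E[i, ]
    row[taken] <- -Inf
    j <- which.max(row)          # which.max takes the first (lowest) index
    perm[i] <- j
    taken[j] <- TRUE
  }
  structure(perm, class = "permutation")
}

#' Relaxed ordering optimization over the Birkhoff polytope
#'
#' Projected stochastic gradient ascent on the spectral projection objective:
#' from the uniform matrix (the polytope barycenter) plus a small seeded
#' perturbation, repeat gradient step (+ Gaussian noise with standard
#' deviation \code{noise_sd/sqrt(t)}) and \code{\link{bbs_project}}. The best
#' iterate by objective is returned, so the result is never worse than the
#' initialization.
#'
#' @param A numeric cells x genes matrix, cells L2-scaled.
#' @param spectrum a \code{template_spectrum}; for cyclic templates drop the
#'   constant top component first.
#' @param cfg an \code{\link{optimizer_config}}.
#' @return the optimized doubly stochastic matrix, with attributes
#'   \code{objective_trace} (per accepted iterate) and \code{step_size}.
#' @export
optimize_doubly_stochastic <- function(A, spectrum,
                                       cfg = optimizer_config()) {
  A <- as_expression_matrix(A)
  n <- nrow(A)
  if (n != spectrum$n)
    stop("matrix/spectrum size mismatch", call. = FALSE)
  K <- tcrossprod(A)
  C <- spectrum_covariance(spectrum)
  base_step <- resolve_step(cfg$step_size, C, K)
  auto <- identical(cfg$step_size, "auto")
  set.seed(cfg$seed)
  E <- matrix(1 / n, n, n) + matrix(stats::rnorm(n * n, sd = 0.01 / n), n, n)
  E <- bbs_project(E)
  obj <- function(M) sum(C * (M %*% K %*% t(M)))   # tr(C E K E')
  f <- obj(E)
  best <- E; fbest <- f
  trace <- numeric(cfg$iterations + 1L); trace[1L] <- f
  kept <- 1L
  stalled <- 0L
  for (t in seq_len(cfg$iterations)) {
    G <- 2 * (C %*% E %*% K)
    if (cfg$noise_sd > 0)
      G <- G + matrix(stats::rnorm(n * n, sd = cfg$noise_sd / sqrt(t)), n, n)
    # the objective is convex, so its maximum sits at a polytope vertex and
    # long moves toward the boundary are principled; near the barycenter the
    # gradient is tiny, so a Lipschitz step alone barely moves. Scale the
    # step so the move spans ~ the polytope diameter, floored at 1/L.
    step <- if (auto)
      max(base_step, 0.5 * sqrt(n) / max(norm(G, "F"), 1e-12))
    else base_step
    E <- bbs_project(E + step * G)
    fnew <- obj(E)
    if (!is.finite(fnew))
      stop("objective became non-finite; reduce the step size", call. = FALSE)
    kept <- kept + 1L
    trace[kept] <- fnew
    if (fnew > fbest) { best <- E; fbest <- fnew }
    # stop only after the objective has been flat for several iterations
    stalled <- if (abs(fnew - f) < cfg$tol * max(1, abs(f)))
      stalled + 1L else 0L
    f <- fnew
    if (stalled >= 10L) break
  }
  structure(best, objective_trace = trace[seq_len(kept)],
            step_size = base_step)
}

# 1/L with L = 2 * ||C||_2 * ||K||_2, the Lipschitz constant of E -> 2 C E K;
# spectral norms by power iteration.
resolve_step <- function(step_size, C, K) {
  if (!identical(step_size, "auto")) return(step_size)
  L <- 2 * power_norm(C) * power_norm(K)
  if (L <= 0) return(1)
  1 / L
}

power_norm <- function(S, iters = 50L, tol = 1e-10) {
  # generic deterministic start: the constant vector can be exactly
  # orthogonal to the top eigenspace (e.g. dropped-top cyclic templates)
  v <- sin(seq_len(nrow(S)))
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in seq_len(iters)) {
    w <- S %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- as.numeric(w / nw)
    if (abs(nw - lam) < tol * max(1, nw)) return(nw)
    lam <- nw
  }
  lam
}

#' Reconstruct the cell ordering along a template topology
#'
#' Runs \code{\link{optimize_doubly_stochastic}}, rounds the result with
#' \code{\link{greedy_round}}, and then polishes the permutation by
#' deterministic pairwise-swap (2-opt) hill climbing on the objective, which
#' repairs vertex-level local optima the relaxed ascent can settle in;
#' returns the permutation, the reordered matrix and diagnostics. When
#' \code{prior_labels} are supplied (e.g. sampling times), optimization is
#' skipped: cells are ordered by label with a seeded random order within
#' ties.
#'
#' For cyclic templates every circular shift or reflection of a solution
#' attains the same objective, so the returned ordering is one arbitrary
#' representative of that equivalence class; compare orderings with
#' \code{\link{circular_rank_correlation}}.
#'
#' @inheritParams optimize_doubly_stochastic
#' @param prior_labels optional sortable vector, one label per cell.
#' @param polish logical; apply the 2-opt swap polish after rounding.
#' @return a list of class \code{reconstruction}: \code{permutation},
#'   \code{ordered} (the permuted matrix), \code{objective} (of the rounded
#'   permutation), \code{objective_trace}, \code{relaxed_objective}.
#' @export
reconstruct_order <- function(A, spectrum, cfg = optimizer_config(),
                              prior_labels = NULL, polish = TRUE) {
  A <- as_expression_matrix(A)
  if (!is.null(prior_labels)) {
    if (length(prior_labels) != nrow(A))
      stop("need one prior label per cell", call. = FALSE)
    set.seed(cfg$seed)
    perm <- structure(order(prior_labels, stats::runif(length(prior_labels))),
                      class = "permutation")
    return(structure(list(permutation = perm,
                          ordered = A[perm, , drop = FALSE],
                          objective = projection_objective(A, spectrum, perm),
                          objective_trace = numeric(0),
                          relaxed_objective = NA_real_),
                     class = "reconstruction"))
  }
  E <- optimize_doubly_stochastic(A, spectrum, cfg)
  perm <- greedy_round(E)
  if (polish)
    perm <- structure(polish_swaps(unclass(perm),
                                   spectrum_covariance(spectrum),
                                   tcrossprod(A)),
                      class = "permutation")
  structure(list(permutation = perm,
                 ordered = A[perm, , drop = FALSE],
                 objective = projection_objective(A, spectrum, perm),
                 objective_trace = attr(E, "objective_trace"),
                 relaxed_objective = projection_objective(A, spectrum, E)),
            class = "reconstruction")
}

# Deterministic 2-opt hill climbing on obj(perm) = sum(C * K[perm, perm]).
# Each candidate swap of positions (a, b) is scored by an O(n) delta on the
# maintained reordered Gram matrix; first-improvement passes repeat until no
# swap helps or the pass cap is hit.
polish_swaps <- function(perm, C, K, max_pass = 50L) {
  n <- length(perm)
  if (n < 3L) return(perm)
  Kp <- K[perm, perm]
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        keep <- -c(a, b)
        delta <- 2 * sum((C[a, keep] - C[b, keep]) *
                           (Kp[b, keep] - Kp[a, keep])) +
          (C[a, a] - C[b, b]) * (Kp[b, b] - Kp[a, a])
        if (delta > 1e-10) {
          perm[c(a, b)] <- perm[c(b, a)]
          Kp[c(a, b), ] <- Kp[c(b, a), ]
          Kp[, c(a, b)] <- Kp[, c(b, a)]
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  perm
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("<reconstruction> n=%d objective=%.6g (relaxed %.6g)\n",
              length(x$permutation), x$objective, x$relaxed_objective))
  invisible(x)
}
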