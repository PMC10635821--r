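# ---- parameter checks -------------------------------------------------------

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha >= 1)
    stop("'alpha' must be a single number in [0, 1)", call. = FALSE)
  alpha
}

check_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2 || n != round(n))
    stop("'n' must be a single integer >= 2", call. = FALSE)
  as.integer(n)
}

# ---- covariance constructors ------------------------------------------------

#' Circulant covariance template for a cyclic topology
#'
#' Theoretical cell-cell covariance of a cyclic process: entry (k, j) equals
#' \code{alpha^m} where \code{m} is the cyclic distance
#' \code{min((j-k) mod n, (k-j) mod n)}. Neighboring cells on the cycle
#' correlate at \code{alpha}, second neighbors at \code{alpha^2}, and so on
#' around the circle in both directions.
#'
#' @param n number of cells (integer >= 2).
#' @param alpha neighbor correlation, in \code{[0, 1)}.
#' @return an \code{n x n} symmetric circulant matrix with unit diagonal,
#'   of class \code{covariance_template}.
#' @examples
#' circulant_covariance(5, 0.5)[1, ]   # 1 0.5 0.25 0.25 0.5
#' @export
circulant_covariance <- function(n, alpha) {
  n <- check_n(n); alpha <- check_alpha(alpha)
  idx <- 0:(n - 1L)
  m <- outer(idx, idx, function(k, j) pmin((j - k) %% n, (k - j) %% n))
  cov <- alpha^m
  new_covariance_template(cov, kind = "cyclic", alpha = alpha)
}

#' Kac-Murdock-Szego covariance template for a linear topology
#'
#' Theoretical cell-cell covariance of a linear chain: entry (i, j) equals
#' \code{alpha^|i-j|}, the stationary AR(1) correlation structure. Positive
#' definite for \code{alpha} in \code{[0, 1)}.
#'
#' @inheritParams circulant_covariance
#' @return an \code{n x n} symmetric Toeplitz matrix with unit diagonal,
#'   of class \code{covariance_template}.
#' @export
kms_covariance <- function(n, alpha) {
  n <- check_n(n); alpha <- check_alpha(alpha)
  idx <- 0:(n - 1L)
  cov <- alpha^abs(outer(idx, idx, "-"))
  new_covariance_template(cov, kind = "linear", alpha = alpha)
}

new_covariance_template <- function(values, kind, alpha = NA_real_) {
  structure(values, kind = kind, alpha = alpha,
            class = c("covariance_template", "matrix", "array"))
}

#' @export
print.covariance_template <- function(x, ...) {
  cat(sprintf("<covariance_template> kind=%s n=%d alpha=%s\n",
              attr(x, "kind"), nrow(x),
              format(attr(x, "alpha"), digits = 3)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE], ...)
  invisible(x)
}

# ---- analytic spectra -------------------------------------------------------

#' Analytic eigenvalues of the circulant cyclic template
#'
#' The eigenvalues of a symmetric circulant matrix are the discrete cosine
#' transform of its first row: \code{lambda_i = sum_j c_j cos(2*pi*j*i/n)}
#' with \code{c_j = alpha^min(j, n-j)}. All are real and nonnegative and sum
#' to \code{n} (the trace of a unit-diagonal matrix).
#'
#' @inheritParams circulant_covariance
#' @return numeric vector of \code{n} eigenvalues, indexed by Fourier
#'   frequency \code{i = 0..n-1} (not sorted).
#' @export
cyclic_eigenvalues <- function(n, alpha) {
  n <- check_n(n); alpha <- check_alpha(alpha)
  j <- 0:(n - 1L)
  cj <- alpha^pmin(j, n - j)
  vapply(j, function(i) sum(cj * cos(2 * pi * j * i / n)), numeric(1))
}

#' Analytic eigenvectors of circulant matrices (real Fourier modes)
#'
#' Entry (s, i) is \code{sqrt(2/n) * cos(2*pi*i*s/n - pi/4)}, for
#' \code{s, i = 0..n-1}. The phase shift of \code{-pi/4} mixes the cosine and
#' sine modes of each conjugate frequency pair into a real orthonormal basis
#' that is fixed (no arbitrary rotation within degenerate eigenspaces), so
#' outputs are deterministic. Column \code{i} is an eigenvector of every
#' symmetric circulant matrix of size \code{n}, with eigenvalue
#' \code{cyclic_eigenvalues(n, alpha)[i + 1]} for the cyclic template.
#'
#' @param n number of cells (integer >= 2).
#' @return an \code{n x n} orthonormal matrix, columns indexed by frequency.
#' @export
cyclic_eigenvectors <- function(n) {
  n <- check_n(n)
  s <- 0:(n - 1L)
  sqrt(2 / n) * cos(outer(s, s, function(s, i) 2 * pi * i * s / n) - pi / 4)
}

#' Approximate eigenvalues of the Kac-Murdock-Szego matrix
#'
#' Closed-form approximation
#' \code{lambda_i = (1 - alpha^2) / (1 + alpha^2 - 2*alpha*cos((i+1)*pi/(n+1)))},
#' accurate for large \code{n}; all values are positive for \code{alpha} in
#' \code{[0, 1)}. Exact eigenpairs are available from
#' \code{numerical_template(kms_covariance(n, alpha))}.
#'
#' @inheritParams circulant_covariance
#' @return numeric vector of \code{n} approximate eigenvalues (descending in
#'   \code{i} for \code{alpha > 0}).
#' @export
linear_eigenvalues <- function(n, alpha) {
  n <- check_n(n); alpha <- check_alpha(alpha)
  i <- 0:(n - 1L)
  (1 - alpha^2) / (1 + alpha^2 - 2 * cos((i + 1) * pi / (n + 1)) * alpha)
}

# ---- template spectrum ------------------------------------------------------

new_template_spectrum <- function(kind, n, alpha, eigenvalues, eigenvectors,
                                  dropped_top = FALSE) {
  structure(list(kind = kind, n = as.integer(n), alpha = alpha,
                 eigenvalues = eigenvalues, eigenvectors = eigenvectors,
                 dropped_top = dropped_top),
            class = "template_spectrum")
}

#' @export
print.template_spectrum <- function(x, ...) {
  cat(sprintf(
    "<template_spectrum> kind=%s n=%d alpha=%s components=%d dropped_top=%s\n",
    x$kind, x$n, format(x$alpha, digits = 3), length(x$eigenvalues),
    x$dropped_top))
  cat("leading eigenvalues:",
      paste(format(utils::head(x$eigenvalues, 5), digits = 4),
            collapse = ", "), "\n")
  invisible(x)
}

#' Spectrum of a covariance template by numerical eigendecomposition
#'
#' Eigendecomposes a symmetric covariance (or affinity) matrix and returns its
#' spectrum sorted by descending eigenvalue, optionally with the top component
#' removed. Removing the top component discards the near-constant direction
#' that dominates unit-diagonal templates and carries no ordering information;
#' for the cyclic template the dropped eigenvector is exactly constant.
#'
#' Tiny negative eigenvalues (above \code{-1e-8}) from floating-point error
#' are clipped to zero. Larger negative eigenvalues are rejected unless
#' \code{clip_negative = TRUE}, in which case they are zeroed - the declared
#' repair for affinity matrices (e.g. heat kernels of graph distances) that
#' need not be positive semidefinite.
#'
#' @param cov symmetric numeric matrix (a \code{covariance_template} or plain
#'   matrix).
#' @param drop_top logical; remove the largest-eigenvalue component.
#' @param kind template kind recorded in the result; defaults to the input's
#'   kind attribute or \code{"custom"}.
#' @param clip_negative logical; zero out genuinely negative eigenvalues
#'   instead of erroring (used for affinity inputs).
#' @return a \code{template_spectrum} with fields \code{kind}, \code{n},
#'   \code{alpha}, \code{eigenvalues} (descending), \code{eigenvectors}
#'   (orthonormal columns), \code{dropped_top}.
#' @export
numerical_template <- function(cov, drop_top = FALSE, kind = NULL,
                               clip_negative = FALSE) {
  if (!is.matrix(cov) || nrow(cov) != ncol(cov))
    stop("'cov' must be a square matrix", call. = FALSE)
  if (max(abs(cov - t(cov))) > 1e-8)
    stop("'cov' must be symmetric", call. = FALSE)
  if (is.null(kind))
    kind <- attr(cov, "kind") %||% "custom"
  alpha <- attr(cov, "alpha") %||% NA_real_
  eig <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  lam <- eig$values
  if (any(lam < -1e-8)) {
    if (clip_negative) lam[lam < 0] <- 0
    else stop(sprintf(
      "matrix is indefinite (min eigenvalue %.3g); not a covariance",
      min(lam)), call. = FALSE)
  }
  lam[lam < 0 & lam > -1e-8] <- 0
  spec <- new_template_spectrum(kind, nrow(cov), alpha, lam, eig$vectors)
  if (drop_top) drop_top_component(spec) else spec
}

#' Analytic spectrum of the cyclic template
#'
#' Convenience constructor combining \code{\link{cyclic_eigenvalues}} and
#' \code{\link{cyclic_eigenvectors}}, sorted by descending eigenvalue.
#'
#' @inheritParams circulant_covariance
#' @param drop_top logical; remove the constant top eigenvector (recommended
#'   before reconstruction and masking).
#' @return a \code{template_spectrum}.
#' @export
cyclic_template <- function(n, alpha, drop_top = FALSE) {
  n <- check_n(n); alpha <- check_alpha(alpha)
  lam <- cyclic_eigenvalues(n, alpha)
  v <- cyclic_eigenvectors(n)
  ord <- order(lam, decreasing = TRUE)
  spec <- new_template_spectrum("cyclic", n, alpha, lam[ord],
                                v[, ord, drop = FALSE])
  if (drop_top) drop_top_component(spec) else spec
}

#' Spectrum of the linear (chain) template
#'
#' Numerically decomposes the Kac-Murdock-Szego covariance. The closed-form
#' eigenvalue approximation is available separately as
#' \code{\link{linear_eigenvalues}}; eigenvectors are always numerical.
#'
#' @inheritParams cyclic_template
#' @return a \code{template_spectrum} of kind \code{"linear"}.
#' @export
linear_template <- function(n, alpha, drop_top = FALSE) {
  numerical_template(kms_covariance(n, alpha), drop_top = drop_top)
}

# ---- generalized templates --------------------------------------------------

#' Cluster-structured covariance template
#'
#' Block covariance encoding membership in discrete groups: 1 on the diagonal,
#' \code{within_corr} between cells sharing a label, 0 across labels. Positive
#' semidefinite for \code{within_corr} in \code{(0, 1]} (each block is a
#' convex combination of the identity and the all-ones matrix).
#'
#' @param labels vector of cluster identifiers, one per cell.
#' @param within_corr correlation between same-cluster cells, in \code{(0, 1]}.
#' @return a \code{covariance_template} of kind \code{"cluster"}.
#' @export
cluster_covariance <- function(labels, within_corr = 1) {
  if (length(labels) == 0L) stop("'labels' must be nonempty", call. = FALSE)
  if (!is.numeric(within_corr) || within_corr <= 0 || within_corr > 1)
    stop("'within_corr' must be in (0, 1]", call. = FALSE)
  same <- outer(labels, labels, "==")
  cov <- ifelse(same, within_corr, 0)
  diag(cov) <- 1
  new_covariance_template(cov, kind = "cluster", alpha = within_corr)
}

#' Block-circulant covariance template for multiple cyclic processes
#'
#' Block-diagonal arrangement of circulant templates (one cycle per block,
#' each with its own neighbor correlation) with a constant \code{cross_corr}
#' between cells of different blocks. Models several simultaneously cycling
#' populations. The result must be positive semidefinite; too large a
#' \code{cross_corr} is rejected with instructions to reduce it.
#'
#' @param block_sizes integer vector of cells per block (each >= 2).
#' @param alphas neighbor correlation per block, same length as
#'   \code{block_sizes}.
#' @param cross_corr correlation between cells of different blocks, in
#'   \code{[0, 1)}.
#' @return a \code{covariance_template} of kind \code{"block_circulant"}.
#' @export
block_circulant_covariance <- function(block_sizes, alphas, cross_corr = 0) {
  if (length(block_sizes) != length(alphas))
    stop("'block_sizes' and 'alphas' must have equal length", call. = FALSE)
  if (cross_corr < 0 || cross_corr >= 1)
    stop("'cross_corr' must be in [0, 1)", call. = FALSE)
  n <- sum(block_sizes)
  cov <- matrix(cross_corr, n, n)
  at <- 0L
  for (b in seq_along(block_sizes)) {
    idx <- at + seq_len(block_sizes[b]); at <- at + block_sizes[b]
    cov[idx, idx] <- unclass(circulant_covariance(block_sizes[b], alphas[b]))
  }
  if (cross_corr > 0) {
    ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop(sprintf(
        "block-circulant template is indefinite (min eigenvalue %.3g); use a smaller cross_corr",
        min(ev)), call. = FALSE)
  }
  new_covariance_template(cov, kind = "block_circulant", alpha = NA_real_)
}

#' Spatial affinity template from 2D coordinates
#'
#' Builds the symmetrized k-nearest-neighbor graph over per-cell coordinates,
#' computes all-pairs shortest-path distances along it, and converts distance
#' to affinity with a Gaussian heat kernel
#' \code{exp(-d^2 / (2 * bandwidth^2))}. The affinity matrix serves as the
#' covariance template of the spatial signal; since a heat kernel of graph
#' distances need not be positive semidefinite, negative eigenvalues are
#' clipped to zero.
#'
#' @param coords numeric \code{n x 2} matrix of spatial positions.
#' @param k_neighbors number of nearest neighbors for the graph.
#' @param bandwidth kernel bandwidth; default is the median nonzero
#'   shortest-path distance.
#' @param drop_top logical; remove the top spectral component.
#' @return a \code{template_spectrum} of kind \code{"spatial"}, with the
#'   affinity matrix attached as attribute \code{"affinity"}.
#' @export
spatial_affinity_template <- function(coords, k_neighbors = 5,
                                      bandwidth = NULL, drop_top = FALSE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (ncol(coords) != 2L) stop("'coords' must be n x 2", call. = FALSE)
  if (n < k_neighbors + 1L)
    stop("need at least k_neighbors + 1 points", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  # mutual-union kNN adjacency: edge if either endpoint lists the other
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k_neighbors + 1L)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  w <- ifelse(adj, d, Inf)
  diag(w) <- 0
  sp <- shortest_paths_dense(w)
  if (any(!is.finite(sp))) {
    comp <- graph_components(adj)
    stop(sprintf("kNN graph is disconnected (%d components); increase k_neighbors",
                 max(comp)), call. = FALSE)
  }
  if (is.null(bandwidth)) bandwidth <- stats::median(sp[sp > 0])
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("'bandwidth' must be positive", call. = FALSE)
  aff <- exp(-sp^2 / (2 * bandwidth^2))
  aff <- (aff + t(aff)) / 2
  diag(aff) <- 1
  spec <- numerical_template(aff, drop_top = drop_top, kind = "spatial",
                             clip_negative = TRUE)
  attr(spec, "affinity") <- aff
  attr(spec, "bandwidth") <- bandwidth
  spec
}

# Floyd-Warshall on a dense weight matrix (Inf = no edge). n is small for
# template construction, so the O(n^3) vectorized sweep is adequate.
shortest_paths_dense <- function(w) {
  n <- nrow(w)
  for (k in seq_len(n)) {
    via <- outer(w[, k], w[k, ], "+")
    w <- pmin(w, via)
  }
  w
}

graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Reconstruct the covariance matrix implied by a spectrum
#'
#' Returns \code{V diag(lambda) V'} over the retained components. With all
#' components retained this reproduces the template covariance; after
#' \code{\link{drop_top_component}} it gives the covariance of the
#' orientation-informative part only.
#'
#' @param spectrum a \code{template_spectrum}.
#' @return a symmetric numeric matrix.
#' @export
spectrum_covariance <- function(spectrum) {
  stopifnot(inherits(spectrum, "template_spectrum"))
  v <- spectrum$eigenvectors
  v %*% (spectrum$eigenvalues * t(v))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
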