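# Hadamard-mask problems on an ordered expression matrix. All three share
# the quadratic form q(B) = sum_i lambda_i ||B' v_i||^2 = tr(C B B') with
# C = V diag(lambda) V' PSD, evaluated at B = A D (diagonal gene mask),
# or B = A (.) F (elementwise mask). q is convex in the mask, so
# minimization (gene inference, filtering) is convex optimization, while
# enhancement (maximization) is solved by projected stochastic gradient
# ascent with box clipping.

#' Infer topology-informative genes via a diagonal mask
#'
#' Solves \code{min_d sum_j d_j^2 g_j - gamma * sum_j d_j} over the box
#' \code{[0,1]^p}, where \code{g_j = sum_i lambda_i (v_i' a_j)^2} is gene
#' \code{j}'s energy in the template spectrum. The objective is separable
#' and convex per gene, so the projected (per-coordinate Newton) step lands
#' exactly on the minimizer \code{d_j = clip(gamma / (2 g_j), 0, 1)}
#' (\code{d_j = 1} for an all-zero gene under \code{gamma > 0}, since only
#' the linear term acts). Genes with LOW \code{d} (high complement
#' \code{1 - d}) are the informative ones; the gene-reduced matrix is
#' \code{A \%*\% diag(1 - d)}.
#'
#' Genes should be L2-scaled to 1 beforehand so scores are comparable
#' across genes.
#'
#' @param A_ordered numeric cells x genes matrix in reconstructed order,
#'   genes L2-scaled.
#' @param spectrum a \code{template_spectrum} (top component dropped).
#' @param cfg an \code{\link{optimizer_config}}; \code{cfg$gamma} is the L1
#'   weight. \code{gamma = "auto"} via \code{\link{auto_gamma_genes}} is
#'   accepted.
#' @return a list of class \code{gene_mask}: \code{d} (the mask diagonal),
#'   \code{scores} (informativeness \code{= 1 - d}), \code{gene_energy}
#'   (\code{g_j}), \code{gamma}, and \code{reduced}
#'   (\code{A_ordered \%*\% diag(1 - d)}).
#' @export
infer_gene_mask <- function(A_ordered, spectrum, cfg = optimizer_config()) {
  A <- as_expression_matrix(A_ordered)
  gamma <- cfg$gamma
  if (identical(gamma, "auto")) gamma <- auto_gamma_genes(A, spectrum)
  if (!is.numeric(gamma) || gamma < 0)
    stop("'gamma' must be >= 0", call. = FALSE)
  g <- gene_energy(A, spectrum)
  d <- ifelse(g > 0, pmin(1, pmax(0, gamma / (2 * g))),
              as.numeric(gamma > 0))
  scores <- 1 - d
  reduced <- sweep(A, 2, scores, "*")
  structure(list(d = stats::setNames(d, colnames(A)),
                 scores = stats::setNames(scores, colnames(A)),
                 gene_energy = g, gamma = gamma, reduced = reduced),
            class = "gene_mask")
}

# g_j = sum_i lambda_i (v_i' a_j)^2, the diagonal of A' C A
gene_energy <- function(A, spectrum) {
  pr <- crossprod(spectrum$eigenvectors, A)         # m x p
  stats::setNames(colSums(spectrum$eigenvalues * pr^2), colnames(A))
}

#' Heuristic L1 weight for gene inference
#'
#' Scans a 5-point gamma grid spanning the gene-energy range and returns the
#' value maximizing the bimodality (variance of the mask values \code{d}),
#' i.e. the sharpest split into retained and discarded genes.
#'
#' @inheritParams infer_gene_mask
#' @return a scalar gamma.
#' @export
auto_gamma_genes <- function(A_ordered, spectrum) {
  A <- as_expression_matrix(A_ordered)
  g <- gene_energy(A, spectrum)
  gpos <- g[g > 0]
  if (length(gpos) == 0L) return(0)
  grid <- 2 * stats::quantile(gpos, c(0.1, 0.3, 0.5, 0.7, 0.9), names = FALSE)
  spread <- vapply(grid, function(gam) {
    d <- pmin(1, pmax(0, gam / (2 * pmax(g, .Machine$double.eps))))
    stats::var(d)
  }, numeric(1))
  grid[which.max(spread)]
}

#' @export
print.gene_mask <- function(x, ...) {
  cat(sprintf("<gene_mask> genes=%d gamma=%.4g retained (score >= 0.5): %d\n",
              length(x$d), x$gamma, sum(x$scores >= 0.5)))
  invisible(x)
}

# shared machinery for the elementwise-mask problems -------------------------

mask_objective <- function(A, F, spectrum, gamma) {
  pr <- crossprod(spectrum$eigenvectors, A * F)
  sum(spectrum$eigenvalues * rowSums(pr^2)) - gamma * sum(F)
}

mask_gradient_quad <- function(A, F, C) 2 * (C %*% (A * F)) * A

# The objective decomposes over gene columns (column j only interacts with
# itself through diag(a_j) C diag(a_j)), so each column can take its own
# Lipschitz step 1/L_j with L_j = 2 ||C||_2 max_s a_{sj}^2; a single global
# step would crawl on weak columns. Returns an n x p step matrix.
mask_steps <- function(A, C) {
  colL <- 2 * power_norm(C) * apply(A^2, 2, max)
  step <- ifelse(colL > 0, 1 / pmax(colL, .Machine$double.eps), 1)
  matrix(step, nrow(A), ncol(A), byrow = TRUE)
}

#' Enhance the template-matching signal with an elementwise mask
#'
#' Maximizes \code{sum_i lambda_i ||(A (.) F)' v_i||^2 - gamma ||F||_1} over
#' masks \code{F} with entries in \code{[0,1]} by projected stochastic
#' gradient ascent (Gaussian noise decaying as \code{noise_sd/sqrt(t)}, box
#' clipping each step) from the all-ones mask. The best iterate by objective
#' is returned. Entries of the data that do not contribute to the template
#' spectrum are driven toward 0, leaving \code{A (.) F} dominated by the
#' matching signal.
#'
#' @param A_genes_inferred ordered, gene-reduced matrix (the \code{reduced}
#'   field of \code{\link{infer_gene_mask}}).
#' @param spectrum a \code{template_spectrum}.
#' @param cfg an \code{\link{optimizer_config}}; \code{gamma} the L1 weight,
#'   \code{noise_sd} the ascent noise scale.
#' @return a list of class \code{mask_result}: \code{F} (mask in
#'   \code{[0,1]}), \code{enhanced} (\code{A (.) F}), \code{objective},
#'   \code{objective_trace}.
#' @export
enhance_signal <- function(A_genes_inferred, spectrum,
                           cfg = optimizer_config(noise_sd = 0.05)) {
  A <- as_expression_matrix(A_genes_inferred)
  check_mask_compat(A, spectrum)
  if (!is.numeric(cfg$gamma) || cfg$gamma < 0)
    stop("'gamma' must be >= 0", call. = FALSE)
  C <- spectrum_covariance(spectrum)
  step <- if (identical(cfg$step_size, "auto")) mask_steps(A, C)
          else cfg$step_size
  set.seed(cfg$seed)
  F <- matrix(1, nrow(A), ncol(A))
  f <- mask_objective(A, F, spectrum, cfg$gamma)
  best <- F; fbest <- f
  trace <- f
  for (t in seq_len(cfg$iterations)) {
    G <- mask_gradient_quad(A, F, C) - cfg$gamma
    if (cfg$noise_sd > 0)
      G <- G + matrix(stats::rnorm(length(F), sd = cfg$noise_sd / sqrt(t)),
                      nrow(F), ncol(F))
    F <- pmin(pmax(F + step * G, 0), 1)
    fnew <- mask_objective(A, F, spectrum, cfg$gamma)
    trace <- c(trace, fnew)
    if (fnew > fbest) { best <- F; fbest <- fnew }
    if (abs(fnew - f) < cfg$tol * max(1, abs(f))) { f <- fnew; break }
    f <- fnew
  }
  structure(list(F = best, enhanced = A * best, objective = fbest,
                 objective_trace = trace),
            class = "mask_result")
}

#' Filter the template-matching signal out with an elementwise mask
#'
#' Minimizes \code{sum_i lambda_i ||(A (.) F)' v_i||^2 - gamma ||F||_1} over
#' \code{F} in \code{[0,1]^(n x p)} by deterministic projected gradient
#' descent at step \code{1/L} (the problem is convex; the objective is
#' non-increasing across iterations). Entries carrying template signal are
#' suppressed while \code{gamma} holds unrelated entries at 1, so
#' \code{A (.) F} retains everything except the matching signal.
#' \code{gamma = "auto"} sets \code{0.1 * lambda_max * mean squared cell
#' norm} (see \code{\link{auto_gamma_filter}}).
#'
#' @param A_ordered ordered numeric cells x genes matrix.
#' @inheritParams enhance_signal
#' @return a \code{mask_result} with field \code{filtered}
#'   (\code{A (.) F}) instead of \code{enhanced}.
#' @export
filter_signal <- function(A_ordered, spectrum, cfg = optimizer_config()) {
  A <- as_expression_matrix(A_ordered)
  check_mask_compat(A, spectrum)
  gamma <- cfg$gamma
  if (identical(gamma, "auto")) gamma <- auto_gamma_filter(A, spectrum)
  if (!is.numeric(gamma) || gamma < 0)
    stop("'gamma' must be >= 0", call. = FALSE)
  C <- spectrum_covariance(spectrum)
  step <- if (identical(cfg$step_size, "auto")) mask_steps(A, C)
          else cfg$step_size
  F <- matrix(1, nrow(A), ncol(A))
  f <- mask_objective(A, F, spectrum, gamma)
  trace <- f
  for (t in seq_len(cfg$iterations)) {
    G <- mask_gradient_quad(A, F, C) - gamma
    F <- pmin(pmax(F - step * G, 0), 1)
    fnew <- mask_objective(A, F, spectrum, gamma)
    trace <- c(trace, fnew)
    if (abs(fnew - f) < cfg$tol * max(1, abs(f))) { f <- fnew; break }
    f <- fnew
  }
  structure(list(F = F, filtered = A * F, objective = f,
                 objective_trace = trace, gamma = gamma),
            class = "mask_result")
}

#' Default L1 weight for filtering
#'
#' \code{0.1 * lambda_max(spectrum) * mean(A^2)}: a tenth of the largest
#' template eigenvalue times the mean squared entry. The quadratic
#' objective's per-entry gradient scales like \code{2 lambda_max a^2}, so
#' this puts the linear reward for keeping an entry at roughly a twentieth
#' of the quadratic cost of the template signal an average entry carries -
#' strong signal entries are suppressed, weak ones stay.
#'
#' @inheritParams filter_signal
#' @return a scalar gamma.
#' @export
auto_gamma_filter <- function(A_ordered, spectrum) {
  A <- as_expression_matrix(A_ordered)
  0.1 * max(spectrum$eigenvalues) * mean(A^2)
}

check_mask_compat <- function(A, spectrum) {
  if (nrow(A) != spectrum$n)
    stop("matrix has ", nrow(A), " cells but spectrum expects ", spectrum$n,
         call. = FALSE)
}

#' @export
print.mask_result <- function(x, ...) {
  cat(sprintf("<mask_result> %d x %d, objective=%.6g, mean mask=%.3f\n",
              nrow(x$F), ncol(x$F), x$objective, mean(x$F)))
  invisible(x)
}
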