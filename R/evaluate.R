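# Evaluation of reconstructed orderings and manipulated matrices: circular
# statistics of gene activity along an inferred cycle, the projection
# proportion of a matrix onto a template spectrum, and circular rank
# correlation between orderings (which is invariant to the circular
# shift/reflection ambiguity of cyclic reconstruction).

#' Circular mean, resultant length and variance of weights on a cycle
#'
#' Cells at ordered positions \code{j = 0..n-1} sit at angles
#' \code{2*pi*j/n} on the unit circle. The weighted resultant is
#' \code{R = |sum_j w_j exp(i theta_j)| / sum_j w_j}; the circular mean is
#' its argument and the circular variance is \code{1 - R}. Concentrated
#' weight gives variance near 0; uniform (or antipodally balanced) weight
#' gives variance 1. For randomly ordered data the variance is expected to
#' be close to 1.
#'
#' @param weights nonnegative weights, one per ordered cell, summing > 0.
#' @return a list of class \code{circular_summary}: \code{mean_angle} (in
#'   \code{[0, 2*pi)}), \code{resultant_length}, \code{variance}
#'   (\code{= 1 - resultant_length}).
#' @export
circular_summary <- function(weights) {
  if (any(weights < 0) || any(!is.finite(weights)))
    stop("weights must be finite and nonnegative", call. = FALSE)
  tot <- sum(weights)
  if (tot <= 0) stop("weights must not all be zero", call. = FALSE)
  n <- length(weights)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  zr <- sum(weights * cos(theta)) / tot
  zi <- sum(weights * sin(theta)) / tot
  r <- sqrt(zr^2 + zi^2)
  mean_angle <- atan2(zi, zr) %% (2 * pi)
  structure(list(mean_angle = mean_angle, resultant_length = r,
                 variance = 1 - r),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("<circular_summary> mean=%.3f rad  R=%.3f  variance=%.3f\n",
              x$mean_angle, x$resultant_length, x$variance))
  invisible(x)
}

#' Circular statistics of gene-set activity along an ordering
#'
#' For each named gene set, sums the member genes' expression per cell (in
#' the given order), min-max normalizes the profile to \code{[0,1]}, and
#' computes its \code{\link{circular_summary}}. A sharply phase-locked set
#' yields low circular variance with the mean angle at its activity peak.
#' Gene ids absent from the matrix are skipped with a message; a set with no
#' matching genes is dropped, and an error is raised if no set matches.
#'
#' @param A_ordered cells x genes matrix in reconstructed cyclic order, with
#'   gene ids as column names.
#' @param gene_sets named list of character vectors of gene ids.
#' @return a list of class \code{phase_summary}: \code{sets} (per-set
#'   \code{circular_summary}), \code{mean_variance}.
#' @export
phase_gene_summary <- function(A_ordered, gene_sets) {
  A <- as_expression_matrix(A_ordered)
  if (is.null(colnames(A))) stop("matrix needs gene ids", call. = FALSE)
  if (length(gene_sets) == 0L || is.null(names(gene_sets)))
    stop("'gene_sets' must be a named list", call. = FALSE)
  sets <- list()
  for (nm in names(gene_sets)) {
    ids <- intersect(gene_sets[[nm]], colnames(A))
    missing <- setdiff(gene_sets[[nm]], colnames(A))
    if (length(missing))
      message("set '", nm, "': skipping ", length(missing),
              " gene id(s) not in the matrix")
    if (length(ids) == 0L) next
    prof <- rowSums(A[, ids, drop = FALSE])
    rng <- range(prof)
    prof <- if (diff(rng) > 0) (prof - rng[1]) / diff(rng)
            else rep(1, length(prof))
    sets[[nm]] <- circular_summary(prof)
  }
  if (length(sets) == 0L)
    stop("no gene set intersects the matrix's genes", call. = FALSE)
  structure(list(sets = sets,
                 mean_variance = mean(vapply(sets, `[[`, numeric(1),
                                             "variance"))),
            class = "phase_summary")
}

#' Fraction of variance captured by the template spectrum
#'
#' \code{sum_i ||A' v_i||^2 / ||A||_F^2} over the retained eigenvectors: the
#' proportion of the matrix's total variance lying in the span of the
#' template components. 1 when every column lies in that span, 0 when
#' orthogonal to it; a convergence-quality diagnostic with no universal
#' threshold.
#'
#' @param A cells x genes matrix.
#' @param spectrum a \code{template_spectrum}, top component dropped
#'   consistently with how it is used elsewhere.
#' @return a scalar in \code{[0, 1]}.
#' @export
projection_proportion <- function(A, spectrum) {
  A <- as_expression_matrix(A)
  total <- sum(A^2)
  if (total == 0) stop("matrix is identically zero", call. = FALSE)
  pr <- crossprod(spectrum$eigenvectors, A)
  min(1, sum(pr^2) / total)
}

#' Circular rank correlation between two cyclic orderings
#'
#' Maximum Spearman correlation between the estimated positions and all
#' \code{2n} circular shifts and reflections of the true positions - the
#' natural score for cyclic reconstruction, where any shift or reflection of
#' a solution is equally valid.
#'
#' @param estimate,truth integer positions \code{0..n-1} per cell (same
#'   cells, same order of entries).
#' @return the best correlation, with the aligning \code{shift} and
#'   \code{reflected} flag as attributes.
#' @export
circular_rank_correlation <- function(estimate, truth) {
  n <- length(truth)
  stopifnot(length(estimate) == n, n >= 3)
  est <- as.numeric(estimate)
  best <- -Inf; bshift <- 0L; brefl <- FALSE
  for (refl in c(FALSE, TRUE)) {
    tr <- if (refl) (n - as.numeric(truth)) %% n else as.numeric(truth)
    for (s in 0:(n - 1L)) {
      r <- stats::cor(est, (tr + s) %% n, method = "spearman")
      if (r > best) { best <- r; bshift <- s; brefl <- refl }
    }
  }
  structure(best, shift = bshift, reflected = brefl)
}

#' Adjusted Rand index between two labelings
#'
#' Standard chance-corrected agreement between partitions, used to score how
#' well k-means clusters recover planted cluster labels or cyclic phase
#' bins.
#'
#' @param a,b label vectors of equal length.
#' @return the ARI (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  nc2 <- comb2(length(a))
  expected <- sum_a * sum_b / nc2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

#' Bin cyclic positions into phase classes
#'
#' Splits positions \code{0..n-1} into \code{bins} contiguous arcs of the
#' cycle, for clustering-based evaluation against phase.
#'
#' @param positions integer positions \code{0..n-1}.
#' @param bins number of arcs.
#' @return integer bin labels \code{1..bins}.
#' @export
phase_bins <- function(positions, bins = 4L) {
  n <- max(positions) + 1L
  pmin(as.integer(floor(as.numeric(positions) * bins / n)) + 1L, bins)
}
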