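# Standard scRNA-seq preprocessing ahead of spectral template matching, plus
# estimation of the template's neighbor-correlation parameter alpha from the
# empirical cell-cell covariance spectrum.

#' Standard preprocessing of a raw counts matrix
#'
#' Drops genes expressed in no cell, normalizes each cell to the same total
#' (the median of per-cell totals), applies \code{log1p}, and keeps the top
#' \code{n_hvg} highly variable genes ranked by dispersion
#' (variance / mean of the normalized counts). Deterministic given its
#' inputs.
#'
#' @param raw numeric cells x genes counts matrix with row (cell) and column
#'   (gene) names; entries must be nonnegative and finite.
#' @param n_hvg number of highly variable genes to retain (default 2000);
#'   values >= the number of nonzero genes keep all of them.
#' @return the preprocessed matrix with attribute \code{layer} set to
#'   \code{"log"}.
#' @export
standard_preprocess <- function(raw, n_hvg = 2000) {
  raw <- as_expression_matrix(raw)
  if (any(raw < 0)) stop("counts must be nonnegative", call. = FALSE)
  keep <- colSums(raw) > 0
  if (!any(keep)) stop("matrix has no expressed gene", call. = FALSE)
  x <- raw[, keep, drop = FALSE]
  totals <- rowSums(x)
  if (any(totals == 0)) stop("matrix contains all-zero cells", call. = FALSE)
  target <- stats::median(totals)
  norm <- x * (target / totals)
  disp <- apply(norm, 2, function(g) {
    m <- mean(g)
    if (m == 0) 0 else stats::var(g) / m
  })
  n_keep <- min(n_hvg, ncol(norm))
  hvg <- order(disp, decreasing = TRUE)[seq_len(n_keep)]
  out <- log1p(norm[, sort(hvg), drop = FALSE])
  attr(out, "layer") <- "log"
  out
}

#' Scale cells or genes to unit L2 norm
#'
#' Cell scaling makes the diagonal of the empirical cell-cell covariance
#' constant, matching the unit diagonal of the theoretical templates; gene
#' scaling puts genes on a common footing before informativeness scoring.
#' All-zero vectors are left at zero with a warning.
#'
#' @param x numeric matrix (cells x genes).
#' @param axis \code{"cells"} (rows) or \code{"genes"} (columns).
#' @return the rescaled matrix, attribute \code{layer = "scaled"}.
#' @export
scale_unit <- function(x, axis = c("cells", "genes")) {
  axis <- match.arg(axis)
  x <- as_expression_matrix(x)
  if (axis == "cells") {
    nrm <- sqrt(rowSums(x^2))
    zero <- nrm == 0
    if (any(zero)) {
      warning(sum(zero), " all-zero cell(s) left unscaled")
      nrm[zero] <- 1
    }
    out <- x / nrm
  } else {
    nrm <- sqrt(colSums(x^2))
    zero <- nrm == 0
    if (any(zero)) {
      warning(sum(zero), " all-zero gene(s) left unscaled")
      nrm[zero] <- 1
    }
    out <- sweep(x, 2, nrm, "/")
  }
  attr(out, "layer") <- "scaled"
  out
}

#' Estimate the neighbor correlation alpha from data
#'
#' Grid search for the template parameter alpha whose eigenvalue profile
#' best matches the spectrum of the empirical cell-cell covariance. Both
#' spectra are sorted descending, truncated to \code{min(n, p)} components,
#' normalized to sum 1, and compared in L2; the returned alpha is the grid
#' argmin. Cells should be L2-scaled first so the empirical covariance has a
#' constant diagonal like the template.
#'
#' With a finite gene count the sample eigenvalues of even a perfectly
#' template-distributed matrix are spread around the population values
#' (Marchenko-Pastur-type distortion), which biases a match against the
#' population spectrum upward. The default \code{reference =
#' "sample-matched"} therefore compares the data against the spectrum of a
#' sample covariance drawn from the candidate template at the same \code{n}
#' and \code{p} (one fixed internal draw shared across the grid, so the
#' estimate is deterministic and the global RNG state is untouched);
#' \code{reference = "population"} compares against the noiseless template
#' spectrum.
#'
#' @param x numeric cells x genes matrix (cell-scaled).
#' @param kind \code{"cyclic"} (circulant template) or \code{"linear"}
#'   (Kac-Murdock-Szego template).
#' @param grid candidate alpha values; default \code{seq(0.05, 0.95, 0.01)}.
#' @param reference \code{"sample-matched"} (default) or \code{"population"}.
#' @return the best-matching alpha (an element of \code{grid}), with the full
#'   profile of distances attached as attribute \code{"profile"}.
#' @export
estimate_alpha <- function(x, kind = c("cyclic", "linear"),
                           grid = seq(0.05, 0.95, by = 0.01),
                           reference = c("sample-matched", "population")) {
  kind <- match.arg(kind)
  reference <- match.arg(reference)
  x <- as_expression_matrix(x)
  n <- nrow(x); p <- ncol(x)
  m <- min(n, p)
  emp <- eigen(tcrossprod(x) / p, symmetric = TRUE, only.values = TRUE)$values
  emp <- sort(emp, decreasing = TRUE)[seq_len(m)]
  if (sum(abs(emp)) < .Machine$double.eps)
    stop("empirical spectrum is degenerate (rank 0)", call. = FALSE)
  emp <- emp / sum(emp)
  ref_spectra <- reference_spectra(kind, reference, n, p, grid)
  dist2 <- vapply(ref_spectra, function(th) {
    th <- sort(th, decreasing = TRUE)[seq_len(m)]
    th <- th / sum(th)
    sum((th - emp)^2)
  }, numeric(1))
  best <- grid[which.min(dist2)]
  attr(best, "profile") <- stats::setNames(dist2, grid)
  best
}

# Eigenvalue reference profiles per candidate alpha. For "sample-matched"
# the reference is eig( diag(sqrt(lam)) V' S V diag(sqrt(lam)) ) with
# S = Z Z'/p a fixed white-noise Gram matrix: the sample covariance a
# template-distributed matrix of the same shape would produce, sharing one
# draw across the grid (common random numbers).
reference_spectra <- function(kind, reference, n, p, grid) {
  if (reference == "population") {
    return(lapply(grid, function(a)
      switch(kind,
             cyclic = cyclic_eigenvalues(n, a),
             linear = linear_eigenvalues(n, a))))
  }
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(727L)
  z <- matrix(stats::rnorm(n * p), n, p)
  s <- tcrossprod(z) / p
  if (kind == "cyclic") {
    v <- cyclic_eigenvectors(n)
    tmat <- crossprod(v, s %*% v)
    lapply(grid, function(a) {
      sq <- sqrt(pmax(cyclic_eigenvalues(n, a), 0))
      eigen(sq * t(sq * tmat), symmetric = TRUE, only.values = TRUE)$values
    })
  } else {
    lapply(grid, function(a) {
      ed <- eigen(unclass(kms_covariance(n, a)), symmetric = TRUE)
      v <- ed$vectors
      tmat <- crossprod(v, s %*% v)
      sq <- sqrt(pmax(ed$values, 0))
      eigen(sq * t(sq * tmat), symmetric = TRUE, only.values = TRUE)$values
    })
  }
}

#' Remove the top component of a template spectrum
#'
#' Drops the largest-eigenvalue eigenpair. For unit-diagonal templates this
#' component is (near-)constant across cells, carries no ordering
#' information, and dominates the projection objective; removing it improves
#' reconstruction and masking. A no-op with a warning if already dropped.
#'
#' @param spectrum a \code{template_spectrum} with >= 2 components.
#' @return the reduced \code{template_spectrum} with \code{dropped_top = TRUE}.
#' @export
drop_top_component <- function(spectrum) {
  stopifnot(inherits(spectrum, "template_spectrum"))
  if (isTRUE(spectrum$dropped_top)) {
    warning("top component already dropped; returning spectrum unchanged")
    return(spectrum)
  }
  if (length(spectrum$eigenvalues) < 2L)
    stop("spectrum needs at least 2 components", call. = FALSE)
  top <- which.max(spectrum$eigenvalues)
  spectrum$eigenvalues <- spectrum$eigenvalues[-top]
  spectrum$eigenvectors <- spectrum$eigenvectors[, -top, drop = FALSE]
  spectrum$dropped_top <- TRUE
  spectrum
}

# coerce to a plain numeric matrix with unique ids; reject NaN/Inf
as_expression_matrix <- function(x) {
  if (inherits(x, "simulated_dataset")) x <- x$matrix
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x)))
    stop("expression matrix contains NA/NaN/Inf", call. = FALSE)
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x)))
    stop("duplicate cell ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x)))
    stop("duplicate gene ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  x
}
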