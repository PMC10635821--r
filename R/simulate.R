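# Binary flip-process simulators with planted topologies. Cells are rows,
# genes are columns; each gene is ON (1) or OFF (0). Along the planted
# topology, neighboring cells differ by exactly k gene flips, which induces
# the exponential covariance decay exp(-2*m*k/p) at topological distance m
# that the analytic templates assume.

#' Simulate a cyclic binary expression process
#'
#' Starts from a random root cell of \code{p} ON/OFF genes. The forward phase
#' generates \code{q} cells, each duplicating the previous and flipping
#' \code{k} uniformly chosen genes. The return phase then flips, per step,
#' \code{k} genes that still differ from the root (chosen without
#' replacement), until the profile equals the root again, closing the cycle;
#' the final cell identical to the root is not emitted a second time. If
#' fewer than \code{k} discordant genes remain, the last step flips all of
#' them. The cycle length is therefore \code{q + ceiling(h/k)} where \code{h}
#' is the root-to-cell-q Hamming distance, and is not fixed in advance.
#'
#' Rows are generated in true cyclic order, then shuffled with a recorded
#' permutation so reconstruction can be scored against ground truth.
#'
#' @param p number of genes.
#' @param k gene flips per step (\code{k >= 0}, \code{k*q <= p}).
#' @param q forward steps along the cycle.
#' @param seed integer seed; all randomness flows from it.
#' @param noise_sd standard deviation of optional additive Gaussian noise
#'   (default 0, pure binary output).
#' @param shuffle logical; emit rows in randomized order (default) with the
#'   true positions recorded, or in true cyclic order.
#' @return a list of class \code{simulated_dataset}: \code{matrix} (cells x
#'   genes, with cell/gene ids), \code{true_order} (0-based position of each
#'   emitted row along the cycle), \code{params}.
#' @export
simulate_cyclic <- function(p, k, q, seed = 1L, noise_sd = 0,
                            shuffle = TRUE) {
  stopifnot(p >= 1, k >= 0, q >= 1)
  if (k * q > p)
    stop("infeasible parameters: need k*q <= p so the return path can use distinct flips",
         call. = FALSE)
  set.seed(as.integer(seed))
  root <- sample(c(0L, 1L), p, replace = TRUE)
  cells <- list(root)
  cur <- root
  for (step in seq_len(q)) {
    flip <- sample.int(p, k)
    cur[flip] <- 1L - cur[flip]
    cells[[length(cells) + 1L]] <- cur
  }
  # return phase: move back toward the root k flips at a time
  repeat {
    diffg <- which(cur != root)
    if (length(diffg) == 0L) break
    flip <- if (length(diffg) <= k) diffg
            else sample(diffg, k)
    cur[flip] <- 1L - cur[flip]
    if (all(cur == root)) break          # root reached: do not emit twice
    cells[[length(cells) + 1L]] <- cur
  }
  x <- do.call(rbind, cells)
  finish_simulation(x, seed = seed, noise_sd = noise_sd, shuffle = shuffle,
                    topology = "cyclic",
                    params = list(p = p, k = k, q = q, seed = seed,
                                  noise_sd = noise_sd))
}

#' Simulate a linear-chain binary expression process
#'
#' A root cell of \code{p} ON/OFF genes is extended over \code{n - 1}
#' iterations; each new cell flips \code{k} uniformly chosen genes relative
#' to its predecessor, producing a chain of \code{n} cells. Rows are shuffled
#' with a recorded permutation.
#'
#' @param p number of genes.
#' @param k gene flips per step.
#' @param n chain length (number of cells).
#' @inheritParams simulate_cyclic
#' @return a \code{simulated_dataset}; \code{true_order} gives each row's
#'   0-based chain position.
#' @export
simulate_linear <- function(p, k, n, seed = 1L, noise_sd = 0,
                            shuffle = TRUE) {
  stopifnot(p >= 1, k >= 0, k <= p, n >= 1)
  set.seed(as.integer(seed))
  cur <- sample(c(0L, 1L), p, replace = TRUE)
  x <- matrix(0L, n, p)
  x[1L, ] <- cur
  for (i in seq_len(n - 1L)) {
    flip <- sample.int(p, k)
    cur[flip] <- 1L - cur[flip]
    x[i + 1L, ] <- cur
  }
  finish_simulation(x, seed = seed, noise_sd = noise_sd, shuffle = shuffle,
                    topology = "linear",
                    params = list(p = p, k = k, n = n, seed = seed,
                                  noise_sd = noise_sd))
}

#' Simulate overlaid cyclic and cluster signals
#'
#' Emulates tissue data carrying two independent structures at once (e.g. a
#' circadian oscillation across spatially zonated cell populations): a cyclic
#' flip process over the first half of the genes, plus cluster-specific ON
#' blocks of amplitude \code{cluster_strength} over the second half. Cells
#' are assigned to \code{n_clusters} groups round-robin along the cycle so
#' cluster identity and cyclic phase are unconfounded.
#'
#' @inheritParams simulate_cyclic
#' @param n_clusters number of discrete clusters (>= 2).
#' @param cluster_strength amplitude of the cluster-specific ON blocks.
#' @return a \code{simulated_dataset} with additional fields
#'   \code{informative_genes} (TRUE for the cyclic half) and
#'   \code{cluster_labels} (per emitted row).
#' @export
simulate_composite <- function(p, k, q, n_clusters = 2,
                               cluster_strength = 1, seed = 1L,
                               noise_sd = 0, shuffle = TRUE) {
  stopifnot(n_clusters >= 2, p >= 2)
  p_cyc <- p %/% 2L
  p_clu <- p - p_cyc
  base <- simulate_cyclic(p_cyc, k, q, seed = seed, noise_sd = 0,
                          shuffle = FALSE)
  n <- nrow(base$matrix)
  set.seed(as.integer(seed) + 1L)
  clusters <- ((seq_len(n) - 1L) %% n_clusters) + 1L   # round-robin on phase
  genes_per <- p_clu %/% n_clusters
  blk <- matrix(0, n, p_clu)
  for (cl in seq_len(n_clusters)) {
    gidx <- if (cl < n_clusters) (cl - 1L) * genes_per + seq_len(genes_per)
            else ((cl - 1L) * genes_per + 1L):p_clu
    blk[clusters == cl, gidx] <- cluster_strength
  }
  x <- cbind(base$matrix, blk)
  out <- finish_simulation(x, seed = seed + 2L, noise_sd = noise_sd,
                           shuffle = shuffle, topology = "composite",
                           params = list(p = p, k = k, q = q,
                                         n_clusters = n_clusters,
                                         cluster_strength = cluster_strength,
                                         seed = seed, noise_sd = noise_sd))
  out$informative_genes <- c(rep(TRUE, p_cyc), rep(FALSE, p_clu))
  out$cluster_labels <- clusters[out$emit_index]
  out
}

# common tail: ids, optional noise, recorded shuffle
finish_simulation <- function(x, seed, noise_sd, shuffle, topology, params) {
  n <- nrow(x)
  storage.mode(x) <- "double"
  # offset so the shuffle stream differs from the generation stream
  set.seed((as.integer(seed) + 10007L) %% .Machine$integer.max)
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), sd = noise_sd)
  emit <- if (shuffle) sample.int(n) else seq_len(n)
  x <- x[emit, , drop = FALSE]
  rownames(x) <- sprintf("cell_%03d", seq_len(n))
  colnames(x) <- sprintf("gene_%04d", seq_len(ncol(x)))
  structure(list(matrix = x,
                 true_order = emit - 1L,     # position along topology per row
                 emit_index = emit,
                 topology = topology,
                 params = params),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> topology=%s cells=%d genes=%d\n",
              x$topology, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}
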