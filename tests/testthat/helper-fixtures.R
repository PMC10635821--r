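# shared fixtures: small seeded matrices and a brute-force ordering oracle

random_matrix <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(sprintf("c%d", seq_len(n)),
                         sprintf("g%d", seq_len(p))))
}

# exhaustive maximum of the projection objective over all n! row orderings
brute_force_best_order <- function(A, spectrum) {
  n <- nrow(A)
  perms <- all_permutations(n)
  vals <- vapply(perms, function(p)
    projection_objective(A, spectrum, structure(p, class = "permutation")),
    numeric(1))
  list(objective = max(vals), permutation = perms[[which.max(vals)]])
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    sub <- all_permutations(n - 1L)
    rest <- setdiff(seq_len(n), i)
    out <- c(out, lapply(sub, function(s) c(i, rest[s])))
  }
  out
}

# ordered position of each original row implied by a permutation
positions_from_perm <- function(perm) {
  pos <- integer(length(perm))
  pos[perm] <- seq_along(perm) - 1L
  pos
}

# draw p genes from a multivariate normal with the given cell covariance
mvn_from_covariance <- function(cov, p, seed = 1) {
  set.seed(seed)
  ev <- eigen(cov, symmetric = TRUE)
  root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  root %*% matrix(rnorm(nrow(cov) * p), nrow(cov), p)
}

# 100 varying cyclic genes + 100 unstructured binary noise genes; genes the
# flip process never touches are constant, hence not cyclic-informative, so
# the positive class is drawn from the varying columns only
gene_mixture_fixture <- function(seed) {
  sim <- simulate_cyclic(p = 300, k = 6, q = 50, seed = seed,
                         shuffle = FALSE)
  n <- nrow(sim$matrix)
  varying <- which(apply(sim$matrix, 2, sd) > 0)[1:100]
  set.seed(seed + 500)
  noise <- matrix(rbinom(n * 100, 1, 0.5), n, 100)
  A <- cbind(sim$matrix[, varying], noise)
  colnames(A) <- sprintf("g%03d", seq_len(200))
  list(A = A, truth = c(rep(TRUE, 100), rep(FALSE, 100)))
}

# area under the ROC curve of score for a binary truth
auc_score <- function(scores, truth) {
  r <- rank(scores)
  pos <- sum(truth); neg <- sum(!truth)
  (sum(r[truth]) - pos * (pos + 1) / 2) / (pos * neg)
}
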