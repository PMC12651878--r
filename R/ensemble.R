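#' Initial dissimilarity matrix between combinations
#'
#' Pairwise Gehan-Wilcoxon effect-size dissimilarities between the survival
#' samples of every pair of combinations: entry (i, j) is
#' \code{effect_size_dissimilarity} of combination i versus j. Symmetric
#' with a zero diagonal; degenerate pairs receive the sentinel value with a
#' warning.
#'
#' @param cohort A \code{combination_cohort} with at least two nonempty
#'   combinations.
#' @param degenerate_value Sentinel for degenerate pairs.
#' @return Labeled symmetric matrix of dissimilarities.
#' @export
initial_dissimilarity_matrix <- function(cohort, degenerate_value = 1) {
  stopifnot(inherits(cohort, "combination_cohort"))
  labs <- names(cohort$groups)
  n <- length(labs)
  if (n < 2L) stop("need at least two combinations")
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- effect_size_dissimilarity(
        cohort$groups[[i]], cohort$groups[[j]],
        degenerate_value = degenerate_value)
    }
  }
  d
}

#' Ensemble (learned) dissimilarity from PAM partitions at every k
#'
#' For each k in 1..n, PAM partitions the combinations using the initial
#' dissimilarities; the learned dissimilarity of a pair is the weighted
#' fraction of those partitions that separate it:
#' \deqn{dis(C_i, C_j) = \sum_{k=1}^{n} w_k \, \delta_k(i, j)}
#' with \eqn{\delta_k = 1} when i and j land in different clusters. With the
#' default equal weights \eqn{w_k = 1/n}, every off-diagonal entry lies in
#' \eqn{[1/n, (n-1)/n]}: k = 1 always co-clusters, k = n always separates.
#'
#' @param d0 Initial dissimilarity matrix (labeled, symmetric).
#' @param weights Nonnegative weights of length n summing to 1; default
#'   equal weights.
#' @return Labeled symmetric consensus dissimilarity matrix with entries in
#'   [0, 1].
#' @export
ensemble_dissimilarity <- function(d0, weights = NULL) {
  d0 <- check_dissim(d0)
  n <- nrow(d0)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n)
    stop("weights must have length ", n, " (one per k)")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  acc <- matrix(0, n, n, dimnames = dimnames(d0))
  for (k in seq_len(n)) {
    if (weights[k] == 0) next
    a <- pam_partition(d0, k)$assignment
    acc <- acc + weights[k] * outer(a, a, "!=")
  }
  dimnames(acc) <- dimnames(d0)
  acc
}
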