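#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster labelings of the same
#' objects; 1 means identical partitions, 0 is the expected agreement of
#' random labelings.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (abs(maxi - expected) < 1e-300) return(1)
  (sij - expected) / (maxi - expected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
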