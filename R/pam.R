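#' Partitioning Around Medoids (two-phase BUILD + SWAP, multi-start)
#'
#' Deterministic Kaufman-Rousseeuw PAM on a precomputed dissimilarity
#' matrix. Each run is the classical two-phase algorithm: BUILD greedily
#' seeds the k medoids, then SWAP repeatedly applies the best strictly
#' improving (medoid, non-medoid) exchange until none remains. Because a
#' single BUILD seed can strand SWAP in a local optimum, the search is
#' restarted once per object with that object pinned as the first medoid
#' (the remaining seeds chosen greedily), and the best final configuration
#' is kept — still fully deterministic, with no random restarts. On small
#' instances this reliably attains the exhaustive-search optimum. All ties
#' break toward the lowest label index or the lexicographically smallest
#' medoid set.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal; row/column
#'   names are the object labels.
#' @param k Number of clusters, \code{1 <= k <= nrow(d)}.
#' @return A \code{pam_partition}: \code{k}, named integer \code{assignment}
#'   (label -> cluster id in 1..k, clusters numbered by medoid label index),
#'   \code{medoids} (one label per cluster), and the total \code{cost}
#'   (sum of dissimilarities to assigned medoids).
#' @export
pam_partition <- function(d, k) {
  d <- check_dissim(d)
  n <- nrow(d)
  if (k < 1 || k > n) stop("k must be in 1..", n)
  cost_of <- function(meds) sum(apply(d[, meds, drop = FALSE], 1L, min))

  build_from <- function(first) {
    med <- first
    dmin <- d[, first]
    while (length(med) < k) {
      cand <- setdiff(seq_len(n), med)
      gain <- vapply(cand, function(h) sum(pmax(dmin - d[, h], 0)), numeric(1))
      h <- cand[which.max(gain)]         # which.max -> lowest index on ties
      med <- c(med, h)
      dmin <- pmin(dmin, d[, h])
    }
    med
  }

  # SWAP with O(n) exchange deltas from nearest/second-nearest medoid
  # distances; best strictly improving exchange, scanned in index order.
  swap_descent <- function(med) {
    repeat {
      dm <- d[, med, drop = FALSE]
      nearest <- apply(dm, 1L, which.min)
      d1 <- dm[cbind(seq_len(n), nearest)]
      d2 <- if (k > 1) apply(dm, 1L, function(r) sort(r, partial = 2)[2])
            else rep(Inf, n)
      cur <- sum(d1)
      best_delta <- -1e-12
      best <- NULL
      for (mi in order(med)) {
        is_m <- nearest == mi
        for (h in setdiff(seq_len(n), med)) {
          newd <- ifelse(is_m, pmin(d2, d[, h]), pmin(d1, d[, h]))
          delta <- sum(newd) - cur
          if (delta < best_delta) {
            best_delta <- delta
            best <- c(mi, h)
          }
        }
      }
      if (is.null(best)) return(sort(med))
      med[best[1]] <- best[2]
    }
  }

  best_med <- NULL
  best_cost <- Inf
  for (s in seq_len(n)) {
    med <- swap_descent(build_from(s))
    cst <- cost_of(med)
    better <- cst < best_cost - 1e-12 ||
      (abs(cst - best_cost) <= 1e-12 && !is.null(best_med) &&
       lex_smaller(med, best_med))
    if (is.null(best_med) || better) {
      best_med <- med
      best_cost <- cst
    }
  }

  dm <- d[, best_med, drop = FALSE]
  nearest <- apply(dm, 1L, which.min)    # ties -> lowest medoid index
  nearest[best_med] <- seq_len(k)        # a medoid anchors its own cluster
  assignment <- stats::setNames(as.integer(nearest), rownames(d))
  structure(list(k = k, assignment = assignment,
                 medoids = rownames(d)[best_med], cost = best_cost),
            class = "pam_partition")
}

# TRUE if integer vector a precedes b lexicographically.
lex_smaller <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' @export
print.pam_partition <- function(x, ...) {
  cat("PAM partition: k =", x$k, ", cost =", format(x$cost, digits = 5), "\n")
  cat("Medoids:", paste(x$medoids, collapse = ", "), "\n")
  invisible(x)
}

# Validate a labeled dissimilarity matrix: square, symmetric, finite,
# nonnegative, zero diagonal; invents labels if absent.
check_dissim <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("dissimilarity matrix must be square")
  if (any(!is.finite(d))) stop("dissimilarity matrix has non-finite entries")
  if (any(d < 0)) stop("dissimilarities must be nonnegative")
  if (any(abs(d - t(d)) > 1e-8)) stop("dissimilarity matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  if (is.null(rownames(d))) {
    lab <- paste0("C", seq_len(nrow(d)))
    dimnames(d) <- list(lab, lab)
  }
  if (is.null(colnames(d))) colnames(d) <- rownames(d)
  d
}
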