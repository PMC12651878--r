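#' Minimax-linkage agglomerative clustering
#'
#' Hierarchical clustering in which the cost of merging clusters G and H is
#' the minimax radius of their union: the smallest value r such that some
#' member p (the prototype) is within dissimilarity r of every member of
#' G and H. At each of the n-1 steps the cheapest merge is performed; ties
#' break toward the pair with the lexicographically smallest leaf indices,
#' and prototype ties toward the smallest leaf index. Every cluster is thus
#' summarized by an actual member, which keeps dendrogram nodes
#' interpretable as representative combinations.
#'
#' @param d Symmetric dissimilarity matrix with labels.
#' @return An \code{eaccd_dendrogram}: \code{merge} (hclust convention),
#'   \code{height}, \code{prototypes} (label per merge), \code{labels},
#'   \code{order}. Height inversions, if any, are kept as computed and
#'   signalled with a warning (cutting is by merge count, so results stay
#'   well defined).
#' @export
minimax_linkage <- function(d) {
  d <- check_dissim(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two objects")
  labels <- rownames(d)

  members <- lapply(seq_len(n), identity)   # leaf indices per active cluster
  code <- -seq_len(n)                       # hclust merge codes
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  prototypes <- character(n - 1L)

  radius <- function(ix) {
    sub <- d[ix, ix, drop = FALSE]
    r <- apply(sub, 1L, max)
    list(h = min(r), proto = ix[which.min(r)])
  }

  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (i in seq_along(members)[-length(members)]) {
      for (j in seq.int(i + 1L, length(members))) {
        cand <- radius(sort(c(members[[i]], members[[j]])))
        key <- c(min(members[[i]][1], members[[j]][1]),
                 max(members[[i]][1], members[[j]][1]))
        if (is.null(best) || cand$h < best$h - 1e-12 ||
            (abs(cand$h - best$h) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, h = cand$h, proto = cand$proto, key = key)
        }
      }
    }
    merge[step, ] <- sort(c(code[best$i], code[best$j]))
    height[step] <- best$h
    prototypes[step] <- labels[best$proto]
    members[[best$i]] <- sort(c(members[[best$i]], members[[best$j]]))
    code[best$i] <- step
    members[[best$j]] <- NULL
    code <- code[-best$j]
  }
  if (any(diff(height) < -1e-10))
    warning("minimax heights are not monotone (inversion); reported as computed")

  structure(list(merge = merge, height = height, prototypes = prototypes,
                 labels = labels, order = merge_order(merge)),
            class = "eaccd_dendrogram")
}

# Leaf ordering consistent with the merge matrix (for plotting/as.hclust).
merge_order <- function(merge) {
  res <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    l <- if (merge[i, 1] < 0) -merge[i, 1] else res[[merge[i, 1]]]
    r <- if (merge[i, 2] < 0) -merge[i, 2] else res[[merge[i, 2]]]
    res[[i]] <- c(l, r)
  }
  res[[nrow(merge)]]
}

#' @export
print.eaccd_dendrogram <- function(x, ...) {
  cat("Minimax-linkage dendrogram:", length(x$labels), "leaves\n")
  cat("Merge heights:", paste(format(x$height, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method stats::as.hclust
as.hclust.eaccd_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "minimax",
                 call = match.call(), dist.method = "ensemble"),
            class = "hclust")
}

#' Cut a dendrogram into k groups
#'
#' Undoes the last k-1 merges, leaving exactly k clusters. Each cluster's
#' medoid is the prototype of the merge that formed it (the leaf itself for
#' singletons); clusters are numbered 1..k by their smallest leaf index.
#'
#' @param tree An \code{eaccd_dendrogram}.
#' @param k Number of groups, \code{1 <= k <=} number of leaves.
#' @return A \code{pam_partition}-style labeling: \code{k}, named
#'   \code{assignment}, \code{medoids}.
#' @export
cut_dendrogram <- function(tree, k) {
  stopifnot(inherits(tree, "eaccd_dendrogram"))
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be in 1..", n)
  # replay the first n-k merges
  node_members <- vector("list", n - 1L)
  node_proto <- integer(n - 1L)
  get_members <- function(codeval)
    if (codeval < 0) -codeval else node_members[[codeval]]
  steps <- seq_len(n - k)
  for (s in steps) {
    node_members[[s]] <- sort(c(get_members(tree$merge[s, 1]),
                                get_members(tree$merge[s, 2])))
    node_proto[s] <- match(tree$prototypes[s], tree$labels)
  }
  # roots after undoing the last k-1 merges: merge codes never referenced by
  # later replayed merges, plus never-merged leaves
  referenced <- c(tree$merge[steps, ])
  root_codes <- setdiff(c(-seq_len(n), seq_len(n - k)), referenced)
  clusters <- lapply(root_codes, function(cd) {
    if (cd < 0) list(members = -cd, proto = -cd)
    else list(members = node_members[[cd]], proto = node_proto[cd])
  })
  ord <- order(vapply(clusters, function(cl) cl$members[1], numeric(1)))
  clusters <- clusters[ord]
  assignment <- integer(n)
  for (i in seq_along(clusters)) assignment[clusters[[i]]$members] <- i
  structure(list(k = k,
                 assignment = stats::setNames(assignment, tree$labels),
                 medoids = tree$labels[vapply(clusters, function(cl) cl$proto,
                                              integer(1))],
                 cost = NA_real_),
            class = "pam_partition")
}
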