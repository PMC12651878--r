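# Independent reference implementations used as oracles. These deliberately
# take the slow, direct route (full enumeration, O(n^2) pair loops) and share
# no code with the package internals they check.

# Harrell C by explicit enumeration of all ordered pairs.
brute_cindex <- function(risk, time, event) {
  n <- length(time)
  conc <- disc <- tied <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      i_shorter <- (time[i] < time[j] && event[i] == 1) ||
        (time[i] == time[j] && event[i] == 1 && event[j] == 0)
      if (!i_shorter) next
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] < risk[j]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  comparable <- conc + disc + tied
  list(cindex = if (comparable > 0) (conc + 0.5 * tied) / comparable else NA,
       comparable = comparable)
}

# Globally optimal k-medoid clustering by trying every medoid subset.
exhaustive_pam <- function(d, k) {
  n <- nrow(d)
  sets <- utils::combn(n, k)
  costs <- apply(sets, 2, function(m)
    sum(apply(d[, m, drop = FALSE], 1, min)))
  best <- which(costs == min(costs))
  list(cost = min(costs),
       medoid_sets = lapply(best, function(b) sets[, b]))
}

# Minimax linkage by direct recomputation: at each step scan every cluster
# pair and every candidate prototype in the union.
brute_minimax <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  protos <- integer(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        u <- sort(c(clusters[[i]], clusters[[j]]))
        rad <- sapply(u, function(p) max(d[p, u]))
        h <- min(rad)
        p <- u[which.min(rad)]      # lowest leaf index on ties
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        better <- is.null(best) || h < best$h - 1e-12 ||
          (abs(h - best$h) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))
        if (better) best <- list(i = i, j = j, h = h, p = p, key = key)
      }
    }
    heights <- c(heights, best$h)
    protos <- c(protos, best$p)
    merges <- c(merges, list(sort(c(min(clusters[[best$i]]),
                                    min(clusters[[best$j]])))))
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, prototypes = protos)
}

# Exact permutation variance of Gehan's U by enumerating group assignments.
perm_var_gehan <- function(ta, da, tb, db) {
  tt <- c(ta, tb); dd <- c(da, db)
  N <- length(tt); m <- length(ta)
  h <- function(i, j) {
    if ((tt[i] > tt[j] && dd[j] == 1) ||
        (tt[i] == tt[j] && dd[j] == 1 && dd[i] == 0)) return(1)
    if ((tt[j] > tt[i] && dd[i] == 1) ||
        (tt[j] == tt[i] && dd[i] == 1 && dd[j] == 0)) return(-1)
    0
  }
  sets <- utils::combn(N, m)
  us <- apply(sets, 2, function(ix) {
    out <- 0
    for (i in ix) for (j in setdiff(seq_len(N), ix)) out <- out + h(i, j)
    out
  })
  stats::var(us) * (length(us) - 1) / length(us)   # population variance
}

# Random symmetric dissimilarity matrix with zero diagonal.
random_dissim <- function(n, labels = sprintf("L%02d", seq_len(n))) {
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  m
}

# Right-censored exponential sample as an observations data.frame.
rexp_obs <- function(n, rate, cens_rate = NULL) {
  te <- stats::rexp(n, rate)
  if (is.null(cens_rate)) return(data.frame(time = te, event = 1L))
  ct <- stats::rexp(n, cens_rate)
  data.frame(time = pmin(te, ct), event = as.integer(te <= ct))
}
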