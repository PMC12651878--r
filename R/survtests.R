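#' Gehan-Wilcoxon generalized rank test for right-censored samples
#'
#' Computes Gehan's U over all cross-pairs: a pair scores +1 when the first
#' observation definitely outlives the second given censoring, -1 in the
#' opposite case, and 0 when censoring leaves the order indeterminate.
#' The variance is the exact permutation variance
#' \deqn{Var(U) = \frac{mn}{(m+n)(m+n-1)} \sum_k s_k^2}
#' with \eqn{s_k} the pooled Gehan scores, and the two-sided p-value comes
#' from the normal approximation (or exact permutation enumeration for tiny
#' samples).
#'
#' @param a,b Data.frames of observations (\code{time}, \code{event}).
#' @param exact Compute the p-value by full enumeration of group-label
#'   permutations (only for pooled size <= 12); the statistic and variance
#'   are unchanged.
#' @return A \code{survtest_result}: \code{statistic} (U of a versus b),
#'   \code{variance}, \code{z}, two-sided \code{p}, and \code{degenerate}
#'   flag (all pairs indeterminate).
#' @export
gehan_wilcoxon <- function(a, b, exact = FALSE) {
  a <- as_observations(a); b <- as_observations(b)
  if (nrow(a) < 1L || nrow(b) < 1L) stop("both samples need >= 1 observation")
  m <- nrow(a); n <- nrow(b); N <- m + n
  tt <- c(a$time, b$time); dd <- c(a$event, b$event)
  H <- gehan_score_matrix(tt, dd)
  U <- sum(H[seq_len(m), m + seq_len(n)])
  s <- rowSums(H)
  v <- m * n / (N * (N - 1)) * sum(s^2)
  if (v <= 0) {
    return(structure(list(statistic = U, variance = 0, z = NA_real_,
                          p = NA_real_, degenerate = TRUE,
                          method = "Gehan-Wilcoxon"),
                     class = "survtest_result"))
  }
  z <- U / sqrt(v)
  if (exact) {
    if (N > 12L) stop("exact enumeration limited to pooled size <= 12")
    sets <- utils::combn(N, m)
    perm <- apply(sets, 2L, function(ix) sum(H[ix, -ix, drop = FALSE]))
    p <- mean(abs(perm) >= abs(U) - 1e-12)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = U, variance = v, z = z, p = p,
                 degenerate = FALSE, method = "Gehan-Wilcoxon"),
            class = "survtest_result")
}

# Pairwise Gehan scores over a pooled sample: H[i, j] = +1 if i definitely
# survives longer than j, -1 if definitely shorter, 0 otherwise. Ties where
# one observation is censored at the other's event time treat the censored
# one as surviving longer (censoring after events).
gehan_score_matrix <- function(tt, dd) {
  ev <- dd == 1
  gt <- outer(tt, tt, ">")
  eq <- outer(tt, tt, "==")
  evi <- matrix(ev, length(tt), length(tt))
  evj <- matrix(ev, length(tt), length(tt), byrow = TRUE)
  plus <- (gt & evj) | (eq & evj & !evi)
  minus <- (t(gt) & evi) | (eq & evi & !evj)
  plus - minus
}

#' Effect-size dissimilarity between two censored samples
#'
#' The sample-size-stabilized magnitude of the standardized Gehan-Wilcoxon
#' statistic, \eqn{|z| / \sqrt{m+n}} — an r-type effect size. It is zero for
#' identical samples, symmetric in its arguments, and serves as the initial
#' dissimilarity between factor-level combinations.
#'
#' When the permutation variance is degenerate (for instance, everything
#' censored so no pair is ordered), a configurable sentinel dissimilarity is
#' returned with a warning so that clustering can proceed.
#'
#' @param a,b Data.frames of observations.
#' @param degenerate_value Sentinel returned when the Gehan variance is zero.
#' @return Nonnegative scalar dissimilarity.
#' @export
effect_size_dissimilarity <- function(a, b, degenerate_value = 1) {
  res <- gehan_wilcoxon(a, b)
  if (res$degenerate) {
    warning("degenerate Gehan variance; returning sentinel dissimilarity ",
            degenerate_value)
    return(degenerate_value)
  }
  abs(res$z) / sqrt(nrow(a) + nrow(b))
}

#' Two-sample log-rank test
#'
#' Standard log-rank score with hypergeometric variance, computed through
#' \code{survival::survdiff}. The statistic is reported as observed minus
#' expected events in the first sample, so a positive value indicates worse
#' survival in \code{a}.
#'
#' @param a,b Data.frames of observations.
#' @return A \code{survtest_result} with \code{statistic} (O - E for
#'   \code{a}), \code{variance}, \code{z}, and chi-square (1 df) two-sided
#'   \code{p}; degenerate (no events) results are flagged.
#' @export
logrank <- function(a, b) {
  a <- as_observations(a); b <- as_observations(b)
  if (nrow(a) < 1L || nrow(b) < 1L) stop("both samples need >= 1 observation")
  df <- data.frame(time = c(a$time, b$time), event = c(a$event, b$event),
                   grp = rep(1:2, c(nrow(a), nrow(b))))
  if (sum(df$event) == 0)
    return(structure(list(statistic = 0, variance = 0, z = NA_real_,
                          p = NA_real_, degenerate = TRUE, method = "log-rank"),
                     class = "survtest_result"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  stat <- unname(sd$obs[1] - sd$exp[1])
  v <- sd$var[1, 1]
  z <- if (v > 0) stat / sqrt(v) else NA_real_
  structure(list(statistic = stat, variance = v, z = z,
                 p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 degenerate = v <= 0, method = "log-rank"),
            class = "survtest_result")
}

#' @export
print.survtest_result <- function(x, ...) {
  cat(x$method, "test: statistic =", format(x$statistic, digits = 4),
      ", z =", format(x$z, digits = 4), ", p =", format(x$p, digits = 4), "\n")
  if (x$degenerate) cat("  (degenerate: no ordered pairs/events)\n")
  invisible(x)
}
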