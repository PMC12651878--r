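#' C-index curve over dendrogram cuts
#'
#' For each candidate group count k, cuts the dendrogram into k groups,
#' orders the groups by decreasing 5-year survival, assigns every patient
#' the ordinal rank of their group as a risk score (1 = least severe), and
#' computes Harrell's C-index over all patients. A single group carries no
#' ordering information, so C(1) = 0.5 by construction (all risks tied).
#'
#' @param tree An \code{eaccd_dendrogram} over the cohort's combinations.
#' @param cohort The \code{combination_cohort} the tree was built from.
#' @param K Largest group count to evaluate (default: number of leaves).
#' @param risk_type \code{"rank"} (ordinal group rank; default) or
#'   \code{"mortality"} (1 - group 5-year survival) as the per-group risk.
#' @return Data.frame with \code{k}, \code{cindex}, \code{n_comparable}.
#' @export
cindex_curve <- function(tree, cohort, K = NULL, risk_type = c("rank", "mortality")) {
  stopifnot(inherits(tree, "eaccd_dendrogram"),
            inherits(cohort, "combination_cohort"))
  risk_type <- match.arg(risk_type)
  n <- length(tree$labels)
  if (is.null(K)) K <- n
  if (K > n) stop("K cannot exceed the number of combinations")
  pooled <- pool_observations(cohort)
  out <- data.frame(k = seq_len(K), cindex = NA_real_, n_comparable = NA_real_)
  for (k in seq_len(K)) {
    groups <- order_groups(cut_dendrogram(tree, k), cohort)
    risk <- patient_risk(groups, pooled$combination, risk_type)
    cc <- harrell_cindex(risk, pooled, B = 0)
    out$cindex[k] <- cc$cindex
    out$n_comparable[k] <- cc$n_comparable
  }
  out
}

# Per-patient risk from ordered prognostic groups.
patient_risk <- function(groups, combination, risk_type = "rank") {
  map <- group_assignment(groups)
  gid <- map[combination]
  if (any(is.na(gid))) stop("patient combination not covered by the grouping")
  if (risk_type == "rank") as.numeric(gid)
  else 1 - vapply(groups, function(g) g$surv5_key, numeric(1))[gid]
}

# combination -> group id lookup from a list of prognostic groups
group_assignment <- function(groups) {
  ids <- rep(vapply(groups, `[[`, integer(1), "id"),
             vapply(groups, function(g) length(g$members), integer(1)))
  stats::setNames(ids, unlist(lapply(groups, `[[`, "members")))
}

#' Select the group count at the knee of the C-index curve
#'
#' Formal knee rule: the smallest k such that every later marginal gain
#' C(j+1) - C(j), j >= k, stays below \code{tol}. If even the final gain
#' exceeds \code{tol} (no plateau), the largest evaluated k is returned with
#' a warning.
#'
#' @param cindex Numeric vector C(1..K) (or the data.frame from
#'   \code{cindex_curve}).
#' @param tol Absolute plateau tolerance for marginal C gains (default
#'   0.005).
#' @return Integer n*, the selected number of prognostic groups.
#' @export
select_knee <- function(cindex, tol = 0.005) {
  if (is.data.frame(cindex)) cindex <- cindex$cindex
  K <- length(cindex)
  if (K < 2L) stop("curve must have length >= 2")
  stopifnot(tol > 0)
  gains <- diff(cindex)
  for (k in seq_len(K - 1L)) {
    if (all(gains[k:(K - 1L)] < tol)) return(k)
  }
  warning("no C-index plateau below tol = ", tol, "; returning K = ", K)
  K
}

#' Order cut groups by disease severity
#'
#' Pools the observations of each cluster, estimates its KM curve, and
#' relabels clusters 1..k by decreasing 5-year overall survival (group 1 =
#' least severe). When some group's follow-up does not reach 60 months, the
#' ordering falls back to survival at the largest follow-up time common to
#' all groups, with a warning. Ties break by larger restricted mean
#' survival, then by first member label.
#'
#' @param partition A cluster labeling (from \code{cut_dendrogram} or
#'   \code{pam_partition}).
#' @param cohort The \code{combination_cohort}.
#' @return List of \code{prognostic_group}s, each with \code{id},
#'   \code{members}, \code{km}, \code{surv5}, \code{n}, \code{deaths},
#'   \code{medoid}.
#' @export
order_groups <- function(partition, cohort) {
  stopifnot(inherits(cohort, "combination_cohort"))
  assignment <- partition$assignment
  missing <- setdiff(names(assignment), names(cohort$groups))
  if (length(missing))
    stop("partition labels absent from cohort: ", paste(missing, collapse = ", "))
  k <- partition$k
  raw <- lapply(seq_len(k), function(cid) {
    members <- names(assignment)[assignment == cid]
    obs <- do.call(rbind, cohort$groups[members])
    km <- km_estimate(obs)
    list(members = members, km = km, obs_n = nrow(obs),
         deaths = sum(obs$event), surv5 = survival_at(km, 60),
         medoid = if (length(partition$medoids) >= cid) partition$medoids[cid] else members[1])
  })
  key <- vapply(raw, `[[`, numeric(1), "surv5")
  if (any(is.na(key))) {
    tcommon <- min(vapply(raw, function(g) g$km$max_time, numeric(1)))
    warning("5-year survival undefined for some group(s); ordering by ",
            "survival at the common follow-up limit (", round(tcommon, 1),
            " months)")
    key <- vapply(raw, function(g) survival_at(g$km, tcommon), numeric(1))
  }
  tmax <- min(60, min(vapply(raw, function(g) g$km$max_time, numeric(1))))
  rmst <- vapply(raw, function(g) km_rmst(g$km, tmax), numeric(1))
  first_member <- vapply(raw, function(g) min(g$members), character(1))
  ord <- order(-key, -rmst, first_member)
  groups <- lapply(seq_len(k), function(i) {
    g <- raw[[ord[i]]]
    structure(list(id = i, members = sort(g$members), km = g$km,
                   surv5 = g$surv5, surv5_key = key[ord[i]], n = g$obs_n,
                   deaths = g$deaths, medoid = g$medoid),
              class = "prognostic_group")
  })
  groups
}

#' Build the full EACCD prognostic system
#'
#' Runs the whole pipeline on a filtered combination cohort: initial
#' effect-size dissimilarities, ensemble PAM consensus, minimax-linkage
#' dendrogram, C-index curve over cuts, knee selection of the group count
#' n*, severity-ordered groups with KM curves, Harrell C-index (with
#' bootstrap CI) of the final grouping, and adjacent-group log-rank tests.
#'
#' @param cohort A filtered \code{combination_cohort} (>= 2 combinations).
#' @param weights Ensemble weights (default equal).
#' @param knee_tol Plateau tolerance for knee selection.
#' @param n_groups Optional forced group count, overriding the knee rule.
#' @param B Bootstrap replicates for the C-index CI.
#' @param seed Optional RNG seed (bootstrap only; the pipeline itself is
#'   deterministic).
#' @param risk_type Risk score construction, see \code{\link{cindex_curve}}.
#' @return A \code{prognostic_system}: \code{dendrogram}, \code{assignments}
#'   (combination -> group id), \code{groups}, \code{cindex}
#'   (\code{concordance_result}), \code{curve}, \code{n_star},
#'   \code{adjacent} (log-rank p-values between adjacent groups), plus the
#'   initial and learned dissimilarity matrices.
#' @export
build_prognostic_system <- function(cohort, weights = NULL, knee_tol = 0.005,
                                    n_groups = NULL, B = 1000, seed = NULL,
                                    risk_type = "rank") {
  stopifnot(inherits(cohort, "combination_cohort"))
  d0 <- initial_dissimilarity_matrix(cohort)
  dl <- ensemble_dissimilarity(d0, weights)
  tree <- minimax_linkage(dl)
  curve <- cindex_curve(tree, cohort, risk_type = risk_type)
  n_star <- if (!is.null(n_groups)) {
    if (n_groups < 1 || n_groups > nrow(d0)) stop("n_groups out of range")
    as.integer(n_groups)
  } else select_knee(curve, knee_tol)
  groups <- order_groups(cut_dendrogram(tree, n_star), cohort)
  pooled <- pool_observations(cohort)
  risk <- patient_risk(groups, pooled$combination, risk_type)
  cind <- harrell_cindex(risk, pooled, B = B, seed = seed)
  adjacent <- if (n_star > 1) {
    data.frame(
      group_a = seq_len(n_star - 1L), group_b = seq.int(2L, n_star),
      p = vapply(seq_len(n_star - 1L), function(g) {
        oa <- do.call(rbind, cohort$groups[groups[[g]]$members])
        ob <- do.call(rbind, cohort$groups[groups[[g + 1]]$members])
        logrank(oa, ob)$p
      }, numeric(1)))
  } else data.frame(group_a = integer(0), group_b = integer(0), p = numeric(0))
  sys <- structure(list(dendrogram = tree,
                        assignments = group_assignment(groups),
                        groups = groups, cindex = cind, curve = curve,
                        n_star = n_star, adjacent = adjacent,
                        dis0 = d0, dis = dl, scheme = cohort$scheme,
                        cohort_n = cohort$n, knee_tol = knee_tol,
                        risk_type = risk_type),
                   class = "prognostic_system")
  stopifnot(sum(vapply(sys$groups, `[[`, integer(1), "n")) == cohort$n)
  sys
}

#' @export
print.prognostic_system <- function(x, ...) {
  cat("EACCD prognostic system: ", x$n_star, " groups over ",
      length(x$assignments), " combinations (", x$cohort_n, " patients)\n",
      sep = "")
  for (g in x$groups)
    cat(sprintf("  Group %d: n=%d, deaths=%d, 5-yr survival=%s | %s\n",
                g$id, g$n, g$deaths,
                ifelse(is.na(g$surv5), "NA", sprintf("%.1f%%", 100 * g$surv5)),
                paste(g$members, collapse = ", ")))
  print(x$cindex)
  invisible(x)
}

#' Assign a patient to a prognostic group
#'
#' Looks up the group of the patient's factor-level combination. A
#' combination valid under the scheme but absent from the system (for
#' instance excluded by the minimum-size filter) yields an explicit
#' unassignable result (\code{NA} with a warning), never a guess; levels
#' outside the scheme are an error.
#'
#' @param system A \code{prognostic_system}.
#' @param levels Named character vector/list of factor levels, e.g.
#'   \code{c(T = "T2", N = "N0", M = "M0")}.
#' @return Integer group id, or \code{NA} if unassignable.
#' @export
assign_patient <- function(system, levels) {
  stopifnot(inherits(system, "prognostic_system"))
  sch <- system$scheme
  for (f in names(sch$factors)) {
    if (is.null(levels[[f]])) stop("missing level for factor '", f, "'")
    if (!levels[[f]] %in% sch$factors[[f]])
      stop("level '", levels[[f]], "' invalid for factor '", f, "'")
  }
  lab <- combination_label(as.list(levels), sch)
  gid <- system$assignments[lab]
  if (is.na(gid)) {
    warning("combination ", lab, " is not part of the system (unassignable)")
    return(NA_integer_)
  }
  unname(gid)
}

#' Export the group-assignment table of a system
#'
#' @param system A \code{prognostic_system}.
#' @return Data.frame with one row per combination: group id, group size,
#'   deaths, and group 5-year survival.
#' @export
group_table <- function(system) {
  stopifnot(inherits(system, "prognostic_system"))
  do.call(rbind, lapply(system$groups, function(g)
    data.frame(combination = g$members, group = g$id, group_n = g$n,
               group_deaths = g$deaths, group_surv5 = g$surv5,
               stringsAsFactors = FALSE)))
}
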