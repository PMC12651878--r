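#' Run the full staging pipeline and write its artifacts
#'
#' End-to-end orchestration: obtain patient records (from a delimited file
#' or a simulation config), group them into combinations, apply the
#' minimum-size filter, build the EACCD prognostic system, and write every
#' export artifact — exclusion report, group-assignment table, C-index
#' curve, per-group KM curves, dendrogram (Newick + JSON sidecar), both
#' dissimilarity matrices, adjacent-group log-rank table, and a JSON run
#' manifest (config, seed, versions) sufficient to reproduce the run.
#'
#' @param out_dir Output directory (created if absent).
#' @param input Path to a delimited cohort file (with \code{column_map}), or
#'   \code{NULL} when simulating.
#' @param column_map Column mapping for \code{\link{read_cohort}}.
#' @param simulate A \code{simulation_config} used when \code{input} is
#'   \code{NULL}.
#' @param scheme Factor scheme (default TNM).
#' @param min_n Minimum patients per combination (default 15).
#' @param weights,knee_tol,n_groups,B,risk_type Passed to
#'   \code{\link{build_prognostic_system}}.
#' @param seed Seed recorded in the manifest and used for the bootstrap.
#' @return Invisibly, a list with the \code{system}, the filtered
#'   \code{cohort}, the \code{audit}/\code{exclusions}, and \code{paths} of
#'   all written artifacts.
#' @export
run_pipeline <- function(out_dir, input = NULL, column_map = NULL,
                         simulate = NULL, scheme = tnm_scheme(), min_n = 15,
                         weights = NULL, knee_tol = 0.005, n_groups = NULL,
                         B = 1000, seed = 1, risk_type = "rank") {
  if (is.null(input) && is.null(simulate))
    stop("provide either an input file or a simulation config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  audit <- NULL
  if (!is.null(input)) {
    rd <- read_cohort(input, column_map)
    records <- rd$records
    audit <- rd$audit
  } else {
    stopifnot(inherits(simulate, "simulation_config"))
    records <- simulate_cohort(simulate)$records
    scheme <- simulate$scheme
  }
  for (f in names(scheme$factors))
    if (is.null(records[[f]]))
      stop("factor '", f, "' not present in the cohort records")
  cohort <- build_combinations(records, scheme)
  flt <- filter_small_combinations(cohort, min_n)
  if (length(flt$cohort$groups) < 2L)
    stop("fewer than two combinations remain after filtering")
  system <- build_prognostic_system(flt$cohort, weights = weights,
                                    knee_tol = knee_tol, n_groups = n_groups,
                                    B = B, seed = seed, risk_type = risk_type)

  p <- function(f) file.path(out_dir, f)
  wtsv <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", row.names = FALSE, quote = FALSE)
    p(f)
  }
  paths <- list(
    exclusions = wtsv(flt$exclusions, "cohort_exclusions.tsv"),
    groups = wtsv(group_table(system), "group_assignments.tsv"),
    curve = wtsv(system$curve, "cindex_curve.tsv"),
    km = wtsv(do.call(rbind, lapply(system$groups, function(g)
      cbind(group = g$id, km_table(g$km)))), "km_groups.tsv"),
    adjacent = wtsv(system$adjacent, "adjacent_logrank.tsv"),
    dis0 = write_dissimilarity(system$dis0, p("dissimilarity_initial.tsv")),
    dis = write_dissimilarity(system$dis, p("dissimilarity_learned.tsv")),
    newick = write_dendrogram_newick(system$dendrogram, p("dendrogram.nwk")),
    dendro_json = write_dendrogram_json(system$dendrogram, p("dendrogram.json")),
    manifest = p("manifest.json"))
  manifest <- list(
    package = "eaccd",
    version = as.character(utils::packageVersion("eaccd")),
    r_version = as.character(getRversion()),
    seed = seed, min_n = min_n, knee_tol = knee_tol,
    n_groups_forced = n_groups, risk_type = risk_type,
    n_star = system$n_star,
    factors = names(scheme$factors),
    input = if (!is.null(input)) normalizePath(input) else "simulated",
    simulation = if (!is.null(simulate))
      list(seed = simulate$seed, horizon = simulate$horizon,
           censor_fraction = simulate$censor_fraction,
           combinations = simulate$combinations) else NULL,
    audit = audit,
    cindex = list(value = system$cindex$cindex,
                  ci = c(system$cindex$ci_low, system$cindex$ci_high)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(list(system = system, cohort = flt$cohort, audit = audit,
                 exclusions = flt$exclusions, paths = paths))
}

#' Compare the EACCD system with rule-based AJCC staging on one cohort
#'
#' Stages every patient with the AJCC TNM rule, builds the EACCD system on
#' the same (filtered) cohort, and contrasts the two: both C-indices, a
#' paired-bootstrap CI and p-value for their difference, and adjacent-group
#' log-rank tables for each system.
#'
#' @param records Patient records with \code{time}, \code{event}, and
#'   \code{T}/\code{N}/\code{M} columns (an age factor may additionally be
#'   present in the scheme).
#' @param scheme Factor scheme for the EACCD side (default TNM).
#' @param min_n Minimum combination size.
#' @param B Bootstrap replicates.
#' @param seed Seed for the bootstraps.
#' @param ... Further arguments to \code{\link{build_prognostic_system}}.
#' @return List with \code{cindex_ajcc}, \code{cindex_eaccd},
#'   \code{difference} (from \code{\link{compare_cindex}}, EACCD minus
#'   AJCC), \code{adjacent_ajcc}, \code{adjacent_eaccd}, and the
#'   \code{system}.
#' @export
compare_systems <- function(records, scheme = tnm_scheme(), min_n = 15,
                            B = 1000, seed = 1, ...) {
  for (f in c("T", "N", "M"))
    if (is.null(records[[f]])) stop("records lack required column '", f, "'")
  cohort <- build_combinations(records, scheme)
  flt <- filter_small_combinations(cohort, min_n)
  system <- build_prognostic_system(flt$cohort, B = B, seed = seed, ...)
  pooled <- pool_observations(flt$cohort)
  # recover the per-patient TNM levels from kept records
  kept_labels <- names(flt$cohort$groups)
  keep <- combination_label(records, scheme) %in% kept_labels
  kept <- records[keep, , drop = FALSE]
  kept <- kept[order(match(combination_label(kept, scheme), kept_labels),
                     method = "radix"), , drop = FALSE]
  stopifnot(identical(kept$time, pooled$time),
            identical(as.integer(kept$event), as.integer(pooled$event)))
  stage <- assign_ajcc_stage(kept$T, kept$N, kept$M)
  risk_ajcc <- as.integer(stage)
  risk_eaccd <- patient_risk(system$groups, pooled$combination,
                             system$risk_type)
  obs <- data.frame(time = kept$time, event = kept$event)
  diffres <- compare_cindex(risk_eaccd, risk_ajcc, obs, B = B, seed = seed)
  adjacent_ajcc <- local({
    lv <- levels(stage)[levels(stage) %in% unique(as.character(stage))]
    if (length(lv) < 2) return(data.frame(stage_a = character(0),
                                          stage_b = character(0),
                                          p = numeric(0)))
    data.frame(stage_a = lv[-length(lv)], stage_b = lv[-1],
               p = vapply(seq_len(length(lv) - 1), function(i) {
                 oa <- obs[stage == lv[i], ]
                 ob <- obs[stage == lv[i + 1], ]
                 logrank(oa, ob)$p
               }, numeric(1)))
  })
  list(cindex_ajcc = diffres$cindex_b, cindex_eaccd = diffres$cindex_a,
       difference = diffres, adjacent_ajcc = adjacent_ajcc,
       adjacent_eaccd = system$adjacent, system = system,
       exclusions = flt$exclusions)
}

#' Write a dissimilarity matrix as delimited text
#'
#' @param d Labeled symmetric matrix.
#' @param path Output path.
#' @export
write_dissimilarity <- function(d, path) {
  d <- check_dissim(d)
  utils::write.table(data.frame(combination = rownames(d), d,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths derive from the merge heights via the standard
#' hclust-to-phylo conversion.
#'
#' @param tree An \code{eaccd_dendrogram}.
#' @param path Output path.
#' @export
write_dendrogram_newick <- function(tree, path) {
  stopifnot(inherits(tree, "eaccd_dendrogram"))
  phy <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Export a dendrogram's merge structure as JSON
#'
#' Structured sidecar: labels, merge list (hclust codes), heights and the
#' prototype label of every merge.
#'
#' @param tree An \code{eaccd_dendrogram}.
#' @param path Output path.
#' @export
write_dendrogram_json <- function(tree, path) {
  stopifnot(inherits(tree, "eaccd_dendrogram"))
  jsonlite::write_json(
    list(labels = tree$labels,
         merges = lapply(seq_along(tree$height), function(i)
           list(children = tree$merge[i, ], height = tree$height[i],
                prototype = tree$prototypes[i]))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
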