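#' Define an ordered factor scheme
#'
#' A factor scheme is the ordered list of categorical staging factors and
#' their ordered level labels. Combination labels are formed by concatenating
#' one level per factor in scheme order (e.g. \code{"T2N0M0"}), and that label
#' is the stable identity of a combination throughout the package.
#'
#' @param ... Named character vectors, one per factor, in the order the
#'   factors should appear in combination labels, e.g.
#'   \code{factor_scheme(T = c("T1","T2"), N = c("N0","N1"))}.
#' @return An object of class \code{"factor_scheme"}.
#' @examples
#' sch <- factor_scheme(T = paste0("T", 1:4), N = c("N0", "N1"), M = c("M0", "M1"))
#' enumerate_combinations(sch)
#' @export
factor_scheme <- function(...) {
  factors <- list(...)
  if (length(factors) == 1L && is.list(factors[[1]]) && is.null(names(factors)))
    factors <- factors[[1]]
  if (length(factors) < 1L) stop("a factor scheme needs at least one factor")
  nm <- names(factors)
  if (is.null(nm) || any(nm == "")) stop("every factor must be named")
  if (anyDuplicated(nm)) stop("duplicate factor names: ", paste(nm[duplicated(nm)], collapse = ", "))
  for (f in nm) {
    lev <- factors[[f]]
    if (!is.character(lev) || length(lev) < 1L)
      stop("levels of factor '", f, "' must be a nonempty character vector")
    if (anyDuplicated(lev))
      stop("duplicate levels in factor '", f, "'")
  }
  structure(list(factors = factors), class = "factor_scheme")
}

#' @export
print.factor_scheme <- function(x, ...) {
  cat("Factor scheme (", length(x$factors), " factors, ",
      prod(lengths(x$factors)), " combinations):\n", sep = "")
  for (f in names(x$factors))
    cat("  ", f, ": ", paste(x$factors[[f]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Standard TNM (and TNMA) staging scheme
#'
#' The AJCC-style scheme for pancreatic neuroendocrine tumors: tumor extent
#' T1-T4, nodal involvement N0/N1, distant metastasis M0/M1, and optionally
#' age dichotomized at 50 years (A1: under 50, A2: 50 and over).
#'
#' @param include_age Include the dichotomized age factor \code{A}.
#' @return A \code{factor_scheme}.
#' @export
tnm_scheme <- function(include_age = FALSE) {
  f <- list(T = paste0("T", 1:4), N = c("N0", "N1"), M = c("M0", "M1"))
  if (include_age) f$A <- c("A1", "A2")
  factor_scheme(f)
}

#' Enumerate all factor-level combinations
#'
#' Cartesian product of the scheme's level lists, ordered lexicographically by
#' scheme order (the first factor varies slowest).
#'
#' @param scheme A \code{factor_scheme}.
#' @return Character vector of combination labels; length is the product of
#'   the level counts.
#' @export
enumerate_combinations <- function(scheme) {
  stopifnot(inherits(scheme, "factor_scheme"))
  g <- expand.grid(rev(scheme$factors), stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_along(g)), drop = FALSE]
  apply(g, 1L, paste0, collapse = "")
}

#' Build combination labels from per-record factor levels
#'
#' @param levels A data.frame (or named list) holding one column per scheme
#'   factor.
#' @param scheme A \code{factor_scheme}.
#' @return Character vector of labels, concatenated in scheme order.
#' @export
combination_label <- function(levels, scheme) {
  stopifnot(inherits(scheme, "factor_scheme"))
  nm <- names(scheme$factors)
  missing <- setdiff(nm, names(levels))
  if (length(missing))
    stop("missing factor columns: ", paste(missing, collapse = ", "))
  do.call(paste0, lapply(nm, function(f) as.character(levels[[f]])))
}
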