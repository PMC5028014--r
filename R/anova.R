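#' One-way analysis of variance across treatment groups
#'
#' Classical fixed-effects one-way ANOVA: \code{F} is the between-group mean
#' square over the within-group mean square on \code{(k - 1, N - k)} degrees
#' of freedom, with the p value from the F distribution. Used to test
#' whether a per-video feature separates the treatment classes.
#'
#' @param groups named list of numeric vectors, one per group (at least two
#'   groups of at least two values each).
#' @param feature optional feature name recorded in the result.
#' @return list of class \code{"anovaResult"}: \code{feature},
#'   \code{groups}, \code{F}, \code{p}, \code{df}, \code{means},
#'   \code{sizes}.
#' @examples
#' oneWayAnova(list(control = c(3.52, 3.75, 3.45, 3.56),
#'                  atp10 = c(3.04, 3.09, 3.08, 3.01),
#'                  atp50 = c(2.00, 2.22, 2.06, 1.83)))
#' @export
oneWayAnova <- function(groups, feature = NA_character_) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop("every group needs at least two values", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(vals))) stop("values must be finite", call. = FALSE)
  withinSS <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                         numeric(1)))
  if (withinSS == 0)
    stop("zero within-group variance: F statistic is undefined",
         call. = FALSE)
  fac <- factor(rep(names(groups), sizes), levels = names(groups))
  ow <- oneway.test(vals ~ fac, var.equal = TRUE)
  structure(list(feature = feature, groups = names(groups),
                 F = unname(ow$statistic), p = unname(ow$p.value),
                 df = unname(ow$parameter),
                 means = vapply(groups, mean, numeric(1)),
                 sizes = sizes),
            class = "anovaResult")
}

#' @export
print.anovaResult <- function(x, ...) {
  cat(sprintf("One-way ANOVA%s: F(%g, %g) = %.4g, p = %.3g\n",
              if (is.na(x$feature)) "" else paste0(" [", x$feature, "]"),
              x$df[1], x$df[2], x$F, x$p))
  print(data.frame(group = x$groups, n = as.integer(x$sizes),
                   mean = x$means, row.names = NULL))
  invisible(x)
}

#' Per-feature ANOVA over a labeled feature table
#'
#' @param features a feature \code{data.frame} (e.g. from [featureTable()])
#'   with a label column.
#' @param labelColumn name of the label column.
#' @param columns feature columns to test; defaults to the standard ten.
#' @return \code{data.frame} with one row per testable feature:
#'   \code{feature, F, p} (features with missing values in some videos are
#'   tested on the videos where they are defined; untestable features are
#'   skipped).
#' @export
anovaTable <- function(features, labelColumn = "label",
                       columns = intersect(featureNames(), names(features))) {
  rows <- list()
  for (col in columns) {
    ok <- !is.na(features[[col]])
    if (sum(ok) < 4L) next
    grp <- split(features[[col]][ok], features[[labelColumn]][ok])
    grp <- grp[lengths(grp) >= 2L]
    if (length(grp) < 2L) next
    res <- tryCatch(oneWayAnova(grp, feature = col), error = function(e) NULL)
    if (!is.null(res))
      rows[[length(rows) + 1L]] <- data.frame(feature = col, F = res$F,
                                              p = res$p)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), F = numeric(), p = numeric())
  rownames(out) <- NULL
  out
}
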