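#' @include AllClasses.R
NULL

#' Mean and standard error of the mean
#'
#' @param values numeric vector, `n >= 1`.
#' @return A list with `mean`, `sem` (`sd/sqrt(n)`, sample sd), `n` and
#'   `flag` (`"single_value"` when `n = 1`, in which case `sem` is 0).
#' @examples
#' meanSem(c(1, 2, 3))
#' @export
meanSem <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) .stopf("meanSem requires at least one value")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else 0,
       n = n, flag = if (n == 1) "single_value" else "")
}

#' Compare group means: t-test or one-way ANOVA with Tukey HSD
#'
#' Two groups are compared with Student's t-test (equal variances by
#' default; set `welch = TRUE` for the Welch correction); three or more
#' with one-way ANOVA followed by Tukey's multiple-comparison post hoc
#' test, reporting every pairwise comparison.
#'
#' @param groups named list of numeric vectors, each with `n >= 2`.
#' @param paired paired t-test (two groups only).
#' @param welch use the Welch (unequal-variance) t-test.
#' @return A list of class `StatResult` with `test`, `groups` (data.frame
#'   of label, n, mean, sem), `statistic`, `p_value` and `pairwise` (Tukey
#'   HSD table for ANOVA, `NULL` for the t-test).
#' @examples
#' compareGroups(list(a = rnorm(5), b = rnorm(5, 1)))
#' @export
compareGroups <- function(groups, paired = FALSE, welch = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns < 2))
    .stopf("every group needs at least 2 values (group '%s' has %d)",
           names(groups)[which.min(ns)], min(ns))
  gtab <- data.frame(
    label = names(groups), n = as.integer(ns),
    mean = vapply(groups, mean, numeric(1)),
    sem = vapply(groups, function(g) stats::sd(g) / sqrt(length(g)),
                 numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (length(groups) == 2) {
    tt <- stats::t.test(groups[[1]], groups[[2]], paired = paired,
                        var.equal = !welch)
    return(structure(list(
      test = if (welch) "Welch t-test" else "Student t-test",
      groups = gtab, statistic = unname(tt$statistic),
      p_value = tt$p.value, pairwise = NULL), class = "StatResult"))
  }
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), ns), levels = names(groups))
  fit <- stats::aov(values ~ fac)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$fac
  pairwise <- data.frame(comparison = rownames(tk),
                         diff = tk[, "diff"], p_adj = tk[, "p adj"],
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(test = "one-way ANOVA + Tukey HSD", groups = gtab,
                 statistic = an[["F value"]][1],
                 p_value = an[["Pr(>F)"]][1], pairwise = pairwise),
            class = "StatResult")
}

# Convert any result object to plain lists for JSON serialization.
.toPlain <- function(x) {
  if (isVirtualClass(class(x)) || !isS4(x)) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, .toPlain))
    return(x)
  }
  out <- lapply(slotNames(x), function(s) .toPlain(slot(x, s)))
  names(out) <- slotNames(x)
  out
}

#' Write an analysis report
#'
#' Serializes a named list of results — fiber summaries, hue profiles,
#' marker scores, morphometry, statistics — into one JSON file per section
#' plus a CSV for each tabular section and an `index.json` listing the
#' sections. Regenerating the report from the same inputs yields
#' byte-identical files. With `plots = TRUE`, box-whisker plots are written
#' for numeric-vector sections and bar plots for named scalar sections.
#'
#' @param results named list; elements may be plain lists, data.frames or
#'   package S4 results (which are flattened to lists).
#' @param outDir output directory, created if needed.
#' @param plots also write PNG figures.
#' @return The output directory, invisibly.
#' @export
buildReport <- function(results, outDir, plots = FALSE) {
  stopifnot(is.list(results))
  if (length(results) > 0 && is.null(names(results)))
    .stopf("results must be a named list")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(results)) {
    plain <- .toPlain(results[[nm]])
    jsonlite::write_json(plain, file.path(outDir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    if (is.data.frame(plain))
      writeResultsCsv(plain, file.path(outDir, paste0(nm, ".csv")))
    if (plots) .reportPlot(plain, nm, outDir)
  }
  jsonlite::write_json(list(sections = as.list(names(results))),
                       file.path(outDir, "index.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

.reportPlot <- function(x, nm, outDir) {
  if (is.numeric(x) && length(x) > 4) {
    grDevices::png(file.path(outDir, paste0(nm, "_box.png")), 480, 480)
    graphics::boxplot(x, main = nm, range = 1.5)
    grDevices::dev.off()
  } else if (is.numeric(x) && !is.null(names(x))) {
    grDevices::png(file.path(outDir, paste0(nm, "_bar.png")), 480, 480)
    graphics::barplot(x, main = nm)
    grDevices::dev.off()
  }
  invisible(NULL)
}
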