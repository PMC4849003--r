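# evaluation: confusion counts under the five threshold scenarios,
# the nine classification statistics, cut-off scans, and regression
# summaries of calculated vs experimental binding free energy changes.

#' Threshold scenario definition
#'
#' The five scenarios compare the magnitude of the calculated change
#' (a = |calc|) and of the experimental change (b = |exp|) against cut-offs
#' x, y, z. A true positive additionally requires sign agreement between the
#' calculated and experimental values. The scenario predicates are:
#' \tabular{lllll}{
#'   \tab tp \tab tn \tab fp \tab fn \cr
#'   1 (x) \tab a>=x, b>=x \tab a<x, b<x \tab a>=x, b<x \tab a<x, b>=x \cr
#'   2 (x,y) \tab a>=y, b>=y \tab a<x, b<x \tab a>=y, b<x \tab a<x, b>=y \cr
#'   3 (x,y) \tab a>=x, b>=y \tab a<y, b<x \tab a>=y, b<x \tab a<x, b>=y \cr
#'   4 (x,y,z) \tab a>=x, b>=y \tab a<z, b<y \tab a>=x, b<y \tab a<z, b>=y \cr
#'   5 (x,y,z) \tab a>=y, b>=x \tab a<y, b<z \tab a>=y, b<z \tab a<y, b>=x
#' }
#' Scenario 1 has no gray zone (every pair is counted); scenarios 2-5 leave
#' intermediate pairs unclassified (counted only in the database size, which
#' lowers coverage).
#'
#' @param scenario_id integer 1-5.
#' @param x,y,z cut-offs in kcal/mol; y is required for scenarios 2-5, z for
#'   scenarios 4-5. Where present they must satisfy x <= y <= z.
#' @return object of class \code{scenario_definition}.
#' @examples
#' scenario_definition(1, x = 0.5)
#' scenario_definition(3, x = 1, y = 2)
#' @export
scenario_definition <- function(scenario_id, x, y = NULL, z = NULL) {
  scenario_id <- as.integer(scenario_id)
  if (!scenario_id %in% 1:5) stop("scenario_id must be 1..5")
  if (missing(x) || is.null(x)) stop("cut-off x is required")
  if (scenario_id >= 2 && is.null(y)) {
    stop(sprintf("scenario %d requires cut-off y", scenario_id))
  }
  if (scenario_id >= 4 && is.null(z)) {
    stop(sprintf("scenario %d requires cut-off z", scenario_id))
  }
  if (scenario_id < 4) z <- NULL
  if (scenario_id < 2) y <- NULL
  vals <- c(x = x, if (!is.null(y)) c(y = y), if (!is.null(z)) c(z = z))
  if (is.unsorted(vals)) stop("cut-offs must satisfy x <= y <= z")
  structure(list(scenario_id = scenario_id, x = x, y = y, z = z),
            class = "scenario_definition")
}

#' Confusion counts of calculated vs experimental energy changes
#'
#' Applies the scenario predicates (see
#' \code{\link{scenario_definition}}) to the magnitudes of each
#' (calculated, experimental) pair. Classification order is tp, fp, fn, tn
#' (first match wins); a pair whose magnitudes satisfy the tp conditions but
#' whose signs disagree is a false positive (a large predicted change of the
#' wrong direction is not a correct detection). Pairs matching no predicate
#' fall in the gray zone: excluded from the counts but retained in
#' \code{n_total}, which is the coverage denominator.
#'
#' @param pairs data frame with numeric columns \code{calc} and \code{exp}
#'   (kcal/mol); an optional \code{label} column is ignored here.
#' @param scenario a \code{\link{scenario_definition}}.
#' @return object of class \code{confusion_counts}: list with \code{tp},
#'   \code{tn}, \code{fp}, \code{fn}, \code{n_total}.
#' @examples
#' pairs <- data.frame(calc = c(1.2, 0.3, 1.2, 0.3),
#'                     exp  = c(1.5, 0.2, 0.3, 1.2))
#' confusion_counts(pairs, scenario_definition(1, x = 0.5))
#' @export
confusion_counts <- function(pairs, scenario) {
  stopifnot(inherits(scenario, "scenario_definition"))
  if (!all(c("calc", "exp") %in% names(pairs))) {
    stop("pairs must have columns 'calc' and 'exp'")
  }
  calc <- pairs$calc; expv <- pairs$exp
  if (!all(is.finite(calc)) || !all(is.finite(expv))) {
    stop("calc and exp must be finite")
  }
  cls <- vapply(seq_along(calc), function(i) {
    classify_pair(calc[i], expv[i], scenario)
  }, character(1))
  structure(list(tp = sum(cls == "tp"), tn = sum(cls == "tn"),
                 fp = sum(cls == "fp"), fn = sum(cls == "fn"),
                 n_total = length(cls)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("tp %d  tn %d  fp %d  fn %d  (of %d; %d in gray zone)\n",
              x$tp, x$tn, x$fp, x$fn, x$n_total,
              x$n_total - x$tp - x$tn - x$fp - x$fn))
  invisible(x)
}

#' @noRd
# sign with sign(0) treated as positive (an exact-zero value falls below
# every positive cut-off, so the choice only fixes determinism).
sign_pos <- function(v) ifelse(v < 0, -1, 1)

#' @noRd
# Classify one pair under a scenario: "tp", "tn", "fp", "fn" or "gray".
classify_pair <- function(calc, expv, sc) {
  a <- abs(calc); b <- abs(expv)
  same_sign <- sign_pos(calc) == sign_pos(expv)
  x <- sc$x; y <- sc$y; z <- sc$z
  th <- switch(sc$scenario_id,
    list(tp = c(x, x), tn = c(x, x), fp = c(x, x), fn = c(x, x)),
    list(tp = c(y, y), tn = c(x, x), fp = c(y, x), fn = c(x, y)),
    list(tp = c(x, y), tn = c(y, x), fp = c(y, x), fn = c(x, y)),
    list(tp = c(x, y), tn = c(z, y), fp = c(x, y), fn = c(z, y)),
    list(tp = c(y, x), tn = c(y, z), fp = c(y, z), fn = c(y, x)))
  if (a >= th$tp[1] && b >= th$tp[2]) {
    return(if (same_sign) "tp" else "fp")
  }
  if (a >= th$fp[1] && b < th$fp[2]) return("fp")
  if (a < th$fn[1] && b >= th$fn[2]) return("fn")
  if (a < th$tn[1] && b < th$tn[2]) return("tn")
  "gray"
}

#' Classification statistics from confusion counts
#'
#' The nine statistics: true positive rate (sensitivity), false negative
#' rate, true negative rate (specificity), positive and negative predictive
#' value, accuracy, F1 score, Matthews correlation coefficient, and coverage
#' (classified fraction of the database). A statistic whose denominator is
#' zero is reported as 0 and listed in the \code{flagged} attribute rather
#' than raising an error, so cut-off sweeps never abort.
#'
#' @param counts a \code{\link{confusion_counts}} object (or list with tp,
#'   tn, fp, fn, n_total).
#' @return named numeric with tpr, fnr, tnr, ppv, npv, acc, f1, mcc,
#'   coverage; attribute \code{flagged} names any zero-denominator entries.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n_total <- counts$n_total
  flagged <- character(0)
  safe <- function(num, den, nm) {
    if (den == 0) { flagged <<- c(flagged, nm); return(0) }
    num / den
  }
  tpr <- safe(tp, tp + fn, "tpr")
  fnr <- safe(fn, fn + tp, "fnr")
  tnr <- safe(tn, tn + fp, "tnr")
  ppv <- safe(tp, tp + fp, "ppv")
  npv <- safe(tn, tn + fn, "npv")
  acc <- safe(tp + tn, tp + tn + fp + fn, "acc")
  f1 <- safe(2 * tp, 2 * tp + fp + fn, "f1")
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) { flagged <- c(flagged, "mcc"); 0 }
  else (tp * tn - fp * fn) / mcc_den
  coverage <- safe(tp + tn + fp + fn, n_total, "coverage")
  structure(c(tpr = tpr, fnr = fnr, tnr = tnr, ppv = ppv, npv = npv,
              acc = acc, f1 = f1, mcc = mcc, coverage = coverage),
            flagged = unique(flagged))
}

#' Sweep scenario cut-offs over a grid
#'
#' Evaluates \code{\link{confusion_counts}} +
#' \code{\link{confusion_metrics}} at each point of a cut-off grid, e.g. the
#' canonical sweep of a single cut-off from 0.5 to 2 kcal/mol in steps of
#' 0.5 for scenario 1.
#'
#' @param pairs data frame with columns \code{calc}, \code{exp}.
#' @param scenario_id integer 1-5.
#' @param cutoff_grid for scenario 1 a numeric vector of x values; for
#'   scenarios 2-3 a data frame (or matrix) with columns x, y; for 4-5 with
#'   columns x, y, z.
#' @return data frame: one row per grid point with the cut-offs, the four
#'   counts and the nine statistics.
#' @examples
#' pairs <- make_prediction_pairs(200, correlation = 0.6, seed = 1)
#' scan_cutoffs(pairs, 1, c(0.5, 1, 1.5, 2))
#' @export
scan_cutoffs <- function(pairs, scenario_id, cutoff_grid) {
  scenario_id <- as.integer(scenario_id)
  need <- if (scenario_id == 1) 1 else if (scenario_id <= 3) 2 else 3
  if (is.numeric(cutoff_grid) && is.null(dim(cutoff_grid))) {
    if (need != 1) stop(sprintf(
      "scenario %d needs %d cut-offs per grid point; give a data frame",
      scenario_id, need))
    grid <- data.frame(x = cutoff_grid)
  } else {
    grid <- as.data.frame(cutoff_grid)
    if (ncol(grid) != need) {
      stop(sprintf("scenario %d needs %d cut-offs per grid point, got %d",
                   scenario_id, need, ncol(grid)))
    }
    names(grid) <- c("x", "y", "z")[seq_len(need)]
  }
  if (!nrow(grid)) stop("cut-off grid is empty")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- scenario_definition(scenario_id, x = grid$x[i],
                              y = if (need >= 2) grid$y[i],
                              z = if (need >= 3) grid$z[i])
    cc <- confusion_counts(pairs, sc)
    m <- confusion_metrics(cc)
    cbind(grid[i, , drop = FALSE],
          data.frame(tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn),
          as.data.frame(as.list(m)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$scenario <- scenario_id
  out
}

#' Linear regression summary of experimental vs calculated changes
#'
#' Ordinary least squares of the experimental on the calculated values, with
#' the Pearson correlation coefficient, intercept and slope. When
#' \code{trim_sd} is given, pairs whose fit residual exceeds that many
#' standard deviations of the residuals are removed and the correlation and
#' fit are recomputed on the remainder (the conventional "within k standard
#' deviations" variant).
#'
#' @param pairs data frame with columns \code{calc}, \code{exp}.
#' @param trim_sd optional residual-SD multiplier (e.g. 2).
#' @return object of class \code{regression_summary}: list with
#'   \code{pearson_r}, \code{intercept}, \code{slope}, \code{n}, and, when
#'   trimming, \code{trimmed_r}, \code{trimmed_intercept},
#'   \code{trimmed_slope}, \code{n_trimmed}.
#' @export
regression_summary <- function(pairs, trim_sd = NULL) {
  if (!all(c("calc", "exp") %in% names(pairs))) {
    stop("pairs must have columns 'calc' and 'exp'")
  }
  n <- nrow(pairs)
  if (n < 2) stop("need at least 2 pairs")
  if (stats::sd(pairs$calc) == 0) stop("zero variance in calculated values")
  fit <- stats::lm(exp ~ calc, data = pairs)
  out <- list(pearson_r = stats::cor(pairs$calc, pairs$exp),
              intercept = unname(stats::coef(fit)[1]),
              slope = unname(stats::coef(fit)[2]), n = n)
  if (!is.null(trim_sd)) {
    res <- stats::residuals(fit)
    keep <- abs(res) <= trim_sd * stats::sd(res)
    kept <- pairs[keep, , drop = FALSE]
    if (nrow(kept) >= 2 && stats::sd(kept$calc) > 0) {
      fit2 <- stats::lm(exp ~ calc, data = kept)
      out$trimmed_r <- stats::cor(kept$calc, kept$exp)
      out$trimmed_intercept <- unname(stats::coef(fit2)[1])
      out$trimmed_slope <- unname(stats::coef(fit2)[2])
      out$n_trimmed <- nrow(kept)
    }
  }
  structure(out, class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("n = %d: R = %.3f, intercept = %.3f, slope = %.3f\n",
              x$n, x$pearson_r, x$intercept, x$slope))
  if (!is.null(x$trimmed_r)) {
    cat(sprintf("trimmed (n = %d): R = %.3f, intercept = %.3f, slope = %.3f\n",
                x$n_trimmed, x$trimmed_r, x$trimmed_intercept,
                x$trimmed_slope))
  }
  invisible(x)
}

#' Read (calculated, experimental) pairs from a delimited file
#'
#' @param path CSV or TSV file with headers \code{calc}, \code{exp} and
#'   optionally \code{label}.
#' @return data frame with columns calc, exp (and label when present).
#' @export
read_pairs <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!all(c("calc", "exp") %in% names(d))) {
    stop("pairs file must have headers 'calc' and 'exp'; found: ",
         paste(names(d), collapse = ", "))
  }
  d
}
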