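# case_protocols: clinical case-study procedures — absolute-value cut-off
# discrimination of large-effect mutations, and the homodimer protocol that
# sums the effects of introducing the mutation separately on each chain.

#' Classify a mutation effect as large or small
#'
#' A mutation is a large-effect (candidate disease-causing) one when the
#' magnitude of its predicted binding free energy change reaches the cut-off:
#' \code{|ddg| >= cutoff}. The magnitude is used because destabilising and
#' (over-)stabilising interface changes are both disruptive.
#'
#' @param ddg predicted change(s), kcal/mol (vectorised).
#' @param cutoff positive cut-off, kcal/mol (1 by convention in the
#'   case studies).
#' @return character vector: "large" or "small".
#' @examples
#' classify_effect_size(c(-1.32, 0.81, 1.04), cutoff = 1)
#' @export
classify_effect_size <- function(ddg, cutoff = 1) {
  if (cutoff <= 0) stop("cutoff must be positive")
  ifelse(abs(ddg) >= cutoff, "large", "small")
}

#' Sum per-chain mutation effects of a homodimer
#'
#' For a homodimeric complex the substitution occurs on both chains; with a
#' single-mutation predictor the effect is estimated by introducing the
#' mutation separately on each chain and summing the two predicted changes.
#'
#' @param ddg_a,ddg_b per-chain predicted changes, kcal/mol (vectorised).
#' @return ddg_a + ddg_b.
#' @examples
#' sum_chain_effects(0.50, 0.29)
#' @export
sum_chain_effects <- function(ddg_a, ddg_b) {
  if (!all(is.finite(ddg_a)) || !all(is.finite(ddg_b))) {
    stop("per-chain ddG values must be finite")
  }
  ddg_a + ddg_b
}

#' Large/small counts per clinical effect class
#'
#' Applies the absolute-value cut-off to each record's predicted change (or,
#' for homodimer tables, to the sum of the per-chain changes) and tabulates
#' large/small counts within each annotation class (Disease, Polymorphism,
#' Unclassified).
#'
#' @param records data frame of case records: columns \code{wt},
#'   \code{position}, \code{mt}, \code{effect}, and either \code{ddg}
#'   (single-chain) or \code{ddg_a} + \code{ddg_b} (homodimer).
#' @param cutoff positive cut-off, kcal/mol.
#' @param use_sum if TRUE, classify \code{sum_chain_effects(ddg_a, ddg_b)};
#'   requires the per-chain columns. If FALSE, requires \code{ddg}.
#' @return object of class \code{case_summary}: data frame with one row per
#'   effect class and columns \code{effect}, \code{large}, \code{small},
#'   \code{total}.
#' @examples
#' case_summary(load_case_table("angiogenin"), cutoff = 1)
#' case_summary(load_case_table("aldolase"), cutoff = 1, use_sum = TRUE)
#' @export
case_summary <- function(records, cutoff = 1, use_sum = FALSE) {
  if (!nrow(records)) stop("records must be non-empty")
  has_single <- "ddg" %in% names(records)
  has_dual <- all(c("ddg_a", "ddg_b") %in% names(records))
  if (use_sum) {
    if (!has_dual) stop("use_sum = TRUE requires per-chain columns ddg_a and ddg_b")
    vals <- sum_chain_effects(records$ddg_a, records$ddg_b)
  } else {
    if (!has_single) stop("records lack a 'ddg' column (single-chain table expected; ",
                          "pass use_sum = TRUE for a homodimer table)")
    if (has_dual) stop("mixed single/dual-chain table: found both ddg and ddg_a/ddg_b")
    vals <- records$ddg
  }
  size <- classify_effect_size(vals, cutoff)
  classes <- unique(records$effect)
  out <- do.call(rbind, lapply(classes, function(cl) {
    sel <- records$effect == cl
    data.frame(effect = cl,
               large = sum(sel & size == "large"),
               small = sum(sel & size == "small"),
               total = sum(sel), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("case_summary", "data.frame"),
            cutoff = cutoff, use_sum = use_sum)
}

#' @export
print.case_summary <- function(x, ...) {
  cat(sprintf("effect-size classification at |ddG| >= %g kcal/mol%s\n",
              attr(x, "cutoff"),
              if (isTRUE(attr(x, "use_sum"))) " (per-chain sums)" else ""))
  print.data.frame(x)
  invisible(x)
}

#' Read a case table from CSV
#'
#' Expected headers: \code{wt}, \code{position}, \code{mt}, \code{effect},
#' and \code{ddg} (single-chain) or \code{ddg_a}, \code{ddg_b} (homodimer);
#' optional \code{location}, \code{ddg_sum}.
#'
#' @param path CSV file.
#' @return data frame of case records.
#' @export
read_case_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wt", "position", "mt", "effect")
  missing <- setdiff(need, names(d))
  if (!("ddg" %in% names(d)) && !all(c("ddg_a", "ddg_b") %in% names(d))) {
    missing <- c(missing, "ddg (or ddg_a + ddg_b)")
  }
  if (length(missing)) {
    stop("case table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  d
}

#' Write a case table as CSV
#' @param records data frame of case records.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_case_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
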