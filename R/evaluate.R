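# Evaluation of classification against gold-standard class assignments:
# exact / partial / mismatch tabulation with dual-classification tracking.

#' Compare a classification result with a gold assignment
#'
#' Categories: `exact` when any most-specific class maps to the gold LIPID
#' MAPS class; else `partial` when any most-specific class is an asserted
#' ancestor of the gold class (classification to a more general class);
#' else `mismatch` when any most-specific class is a different terminal
#' class; else `none`.  Orthogonally, `dual` flags results that contain
#' both a gold-consistent member (the gold class or an ancestor) and an
#' inconsistent terminal class at the same time.
#'
#' @param result A `classification_result`.
#' @param gold_lm The asserted LIPID MAPS class id (e.g. "FA0305").
#' @param ont A `lipid_ontology`.
#' @return A list with `category` (one of exact/partial/mismatch/none) and
#'   `dual` (logical).
#' @export
compare_classification <- function(result, gold_lm, ont) {
  stopifnot(inherits(result, "classification_result"),
            inherits(ont, "lipid_ontology"))
  lm_ids <- vapply(ont$classes, function(x) x$lm_id, character(1))
  gold_class <- names(ont$classes)[!is.na(lm_ids) & lm_ids == gold_lm]
  if (length(gold_class) == 0L) {
    stop(sprintf("gold class '%s' is not mapped in the ontology (known: %s)",
                 gold_lm, paste(sort(lm_ids[!is.na(lm_ids)]), collapse = ", ")))
  }
  gold_class <- gold_class[1]
  gold_anc <- lipid_ancestors(ont, gold_class, strict = TRUE)

  ms <- result$most_specific
  ms_lm <- vapply(ms, function(nm) lm_mapping(ont, nm), character(1))
  ms_terminal <- vapply(ms, function(nm) ont$classes[[nm]]$terminal, logical(1))

  is_exact <- length(ms) > 0L && any(!is.na(ms_lm) & ms_lm == gold_lm)
  is_partial <- any(ms %in% gold_anc)
  wrong_terminal <- ms_terminal & (is.na(ms_lm) | ms_lm != gold_lm)

  category <- if (is_exact) "exact"
              else if (is_partial) "partial"
              else if (any(wrong_terminal)) "mismatch"
              else "none"
  dual <- (is_exact || is_partial) && any(wrong_terminal)
  list(category = category, dual = dual)
}

#' Tabulate evaluation outcomes over a corpus
#'
#' @param results A list of `classification_result` objects.
#' @param gold A data frame with columns `uri` and `asserted_lm` (as read
#'   by [read_gold_tsv()] or produced by [generate_fixture_set()]).
#' @param ont A `lipid_ontology`.
#' @return An object of class `evaluation_tally`: per-molecule `report`
#'   data frame (`uri`, `predicted`, `asserted_lm`, `category`, `dual`),
#'   counts and percentages per category, the consistent percentage
#'   (exact + partial), and the dual percentage.  Both dual conventions
#'   are reported: `pct_consistent` counts dual-flagged molecules as
#'   consistent, `pct_consistent_strict` excludes them.
#' @export
tabulate_outcomes <- function(results, gold, ont) {
  stopifnot(length(results) > 0L)
  rows <- lapply(results, function(r) {
    g <- gold$asserted_lm[gold$uri == r$uri]
    if (length(g) == 0L) {
      stop(sprintf("no gold assignment for molecule %s", r$uri))
    }
    out <- tryCatch(compare_classification(r, g[1], ont), error = function(e)
      stop(sprintf("%s: %s", r$uri, conditionMessage(e)), call. = FALSE))
    data.frame(uri = r$uri,
               predicted = paste(r$most_specific, collapse = ";"),
               asserted_lm = g[1], category = out$category, dual = out$dual,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  n <- nrow(report)
  counts <- vapply(c(exact = "exact", partial = "partial",
                     mismatch = "mismatch", none = "none"),
                   function(cat) sum(report$category == cat), integer(1))
  n_dual <- sum(report$dual)
  pct <- function(x) 100 * x / n
  structure(list(
    report = report,
    n = n,
    counts = counts,
    n_dual = n_dual,
    pct_exact = pct(counts[["exact"]]),
    pct_partial = pct(counts[["partial"]]),
    pct_mismatch = pct(counts[["mismatch"]]),
    pct_none = pct(counts[["none"]]),
    pct_consistent = pct(counts[["exact"]] + counts[["partial"]]),
    pct_consistent_strict = pct(sum(report$category %in%
                                      c("exact", "partial") & !report$dual)),
    pct_dual = pct(n_dual)
  ), class = "evaluation_tally")
}

#' @export
print.evaluation_tally <- function(x, ...) {
  cat(sprintf("<evaluation_tally> n = %d molecules\n", x$n))
  cat(sprintf("  exact      %3d  (%5.1f%%)\n", x$counts[["exact"]], x$pct_exact))
  cat(sprintf("  partial    %3d  (%5.1f%%)\n", x$counts[["partial"]], x$pct_partial))
  cat(sprintf("  mismatch   %3d  (%5.1f%%)\n", x$counts[["mismatch"]], x$pct_mismatch))
  cat(sprintf("  none       %3d  (%5.1f%%)\n", x$counts[["none"]], x$pct_none))
  cat(sprintf("  consistent (exact+partial): %.1f%% (%.1f%% excluding dual)\n",
              x$pct_consistent, x$pct_consistent_strict))
  cat(sprintf("  dual-classified: %d (%.1f%%)\n", x$n_dual, x$pct_dual))
  invisible(x)
}

#' Read gold-standard class assignments from TSV
#'
#' Two tab-separated columns without header: molecule uri, LIPID MAPS class
#' id.
#'
#' @param path File path.
#' @return A data frame with columns `uri`, `asserted_lm`.
#' @export
read_gold_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          col.names = c("uri", "asserted_lm"))
  df
}

#' Write an evaluation report as TSV
#'
#' @param tally An `evaluation_tally`.
#' @param path Output file path.
#' @return Invisibly, the report data frame.
#' @export
write_report_tsv <- function(tally, path) {
  stopifnot(inherits(tally, "evaluation_tally"))
  utils::write.table(tally$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tally$report)
}
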