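#' One-to-one C-alpha matching
#'
#' Greedy trace-order pairing: each predicted atom, in order, claims
#' the nearest still-unclaimed native atom within `cutoff`; predictions
#' with no available native atom stay unmatched, which allows skips in
#' the native backbone. This mirrors the trace-walking evaluation used
#' by map-to-model assessment tools rather than a globally optimal
#' assignment.
#'
#' @param pred numeric matrix (n_pred x 3) of predicted CA positions.
#' @param native numeric matrix (n_native x 3) of ground-truth CA.
#' @param cutoff match distance cutoff, A (default 3.0).
#' @return Data frame with columns `pred`, `native`, `distance`, one
#'   row per matched pair.
#' @export
match_ca_one_to_one <- function(pred, native, cutoff = 3.0) {
  stopifnot(cutoff > 0)
  pred <- rbind(pred); native <- rbind(native)
  claimed <- logical(nrow(native))
  out <- list()
  for (i in seq_len(nrow(pred))) {
    open <- which(!claimed)
    if (length(open) == 0) break
    d <- sqrt(rowSums((native[open, , drop = FALSE] -
                         matrix(pred[i, ], length(open), 3, byrow = TRUE))^2))
    j <- which.min(d)
    if (d[j] <= cutoff) {
      claimed[open[j]] <- TRUE
      out[[length(out) + 1L]] <- data.frame(pred = i, native = open[j],
                                            distance = d[j])
    }
  }
  if (length(out) == 0) {
    return(data.frame(pred = integer(0), native = integer(0),
                      distance = numeric(0)))
  }
  do.call(rbind, out)
}

#' Score a predicted C-alpha set against ground truth
#'
#' Computes the one-to-one matching metrics: RMSD over matched pairs,
#' the percentage of native C-alpha atoms found within 3 A
#' (completeness), the false-positive count (predicted atoms farther
#' than 3 A from every native atom), and the error rate
#' `false positives / total predicted`. A predicted-denominator
#' variant of the percentage is reported alongside.
#'
#' @param pred numeric matrix (n_pred x 3); may have zero rows.
#' @param native numeric matrix (n_native x 3); must be non-empty.
#' @param cutoff match cutoff, A.
#' @return Object of class `metrics_report`.
#' @export
compute_metrics <- function(pred, native, cutoff = 3.0) {
  native <- rbind(native)
  if (nrow(native) == 0) stop("native C-alpha set is empty")
  pred <- rbind(pred)
  n_pred <- nrow(pred)
  n_native <- nrow(native)
  if (n_pred == 0) {
    warning("empty prediction: metrics degenerate")
    rep <- list(n_pred = 0L, n_native = n_native,
                matched = data.frame(pred = integer(0), native = integer(0),
                                     distance = numeric(0)),
                rmsd = NA_real_, pct3 = 0, pct3_pred = NA_real_,
                fp = 0L, error_rate = 0)
    return(structure(rep, class = "metrics_report"))
  }
  matched <- match_ca_one_to_one(pred, native, cutoff)
  # false positive: farther than cutoff from ANY native atom
  near_any <- vapply(seq_len(n_pred), function(i) {
    min(rowSums((native - matrix(pred[i, ], n_native, 3, byrow = TRUE))^2)) <=
      cutoff^2
  }, TRUE)
  fp <- sum(!near_any)
  rep <- list(
    n_pred = n_pred, n_native = n_native, matched = matched,
    rmsd = if (nrow(matched) > 0) sqrt(mean(matched$distance^2)) else NA_real_,
    pct3 = 100 * nrow(matched) / n_native,
    pct3_pred = 100 * nrow(matched) / n_pred,
    fp = as.integer(fp),
    error_rate = fp / n_pred)
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  predicted CA : %d\n", x$n_pred))
  cat(sprintf("  native CA    : %d\n", x$n_native))
  cat(sprintf("  matched      : %d\n", nrow(x$matched)))
  cat(sprintf("  RMSD (match) : %s A\n",
              if (is.na(x$rmsd)) "NA" else sprintf("%.3f", x$rmsd)))
  cat(sprintf("  %% CA in 3 A  : %.1f (of native), %s (of predicted)\n",
              x$pct3, if (is.na(x$pct3_pred)) "NA"
              else sprintf("%.1f", x$pct3_pred)))
  cat(sprintf("  false pos.   : %d (error rate %.4f)\n", x$fp, x$error_rate))
  invisible(x)
}

#' Serialize a metrics report
#'
#' Writes the report both as a one-row CSV (columns `n_pred`,
#' `n_native`, `n_matched`, `rmsd`, `pct3`, `pct3_pred`, `fp`,
#' `error_rate`) and as JSON.
#'
#' @param report a `metrics_report`.
#' @param csv,json output paths (either may be `NULL` to skip).
#' @return The report, invisibly.
#' @export
write_metrics <- function(report, csv = NULL, json = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  row <- data.frame(n_pred = report$n_pred, n_native = report$n_native,
                    n_matched = nrow(report$matched), rmsd = report$rmsd,
                    pct3 = report$pct3, pct3_pred = report$pct3_pred,
                    fp = report$fp, error_rate = report$error_rate)
  if (!is.null(csv)) utils::write.csv(row, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(as.list(row), json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
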