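# Off-target specificity: onC^h / offC^h (the highest C->T conversion
# frequency in a site's quantification window) and the score
# (onC^h - offC^h) / onC^h, with categorical labels for degenerate cases.

#' Highest C->T conversion frequency in a window
#'
#' The maximum C->T frequency over covered reference-C positions; ties are
#' broken toward the smallest position, which is reported alongside.
#'
#' @param table A `conversion_table`.
#' @param min_depth Minimum depth for a position to count (default 1).
#' @return List with `value` and `cp`; `value` is `NA` (undefined) when no
#'   reference C is covered, which propagates as "no-activity".
#' @export
highest_conversion <- function(table, min_depth = 1L) {
  f <- conversion_frequencies(table, min_depth = min_depth)
  ok <- !is.na(f)
  if (!any(ok)) return(list(value = NA_real_, cp = NA_integer_))
  f <- f[ok]
  i <- which.max(f)  # which.max returns the first (smallest-position) maximum
  list(value = unname(f[i]), cp = as.integer(names(f)[i]))
}

#' Specificity score for one on/off-target pair
#'
#' `(onCh - offCh) / onCh` when defined. An undefined or sub-threshold
#' on-target activity yields the label `"no-activity"` (operationalizing "no
#' obvious activity in on-target site"); off-target activity exceeding the
#' on-target yields `"N.Sp."` (the negative value is still recorded);
#' otherwise the label is `"numeric"` with a value in `[0, 1]`.
#'
#' @param onCh,offCh Highest on-/off-target C->T conversion frequencies
#'   (in `[0, 1]`, or `NA` when undefined).
#' @param min_activity Minimum on-target activity for a defined score
#'   (default 0.05).
#' @return List with `value` and `label` (one of `"numeric"`, `"N.Sp."`,
#'   `"no-activity"`).
#' @export
specificity_score <- function(onCh, offCh, min_activity = 0.05) {
  if (is.na(onCh) || onCh < min_activity) {
    return(list(value = NA_real_, label = "no-activity"))
  }
  if (is.na(offCh)) {
    # off-target window has no covered C: nothing to compare against
    return(list(value = NA_real_, label = "no-coverage"))
  }
  value <- (onCh - offCh) / onCh
  list(value = value, label = if (offCh > onCh) "N.Sp." else "numeric")
}

#' Specificity panel over on/off-target pairings
#'
#' Computes one specificity result per (on-target, off-target) pair and a
#' per-on-target summary. The per-pair scores are primary; the summary
#' reports both the worst (minimum) per-pair specificity and a pooled score
#' computed against the panel's maximum off-target activity.
#'
#' @param tables Named list of `conversion_table`s, one per site id.
#' @param pairs Data frame with columns `on_site_id`, `off_site_id`.
#' @param editor_id Editor identifier carried into the result.
#' @param min_activity Passed to [specificity_score()].
#' @param min_depth Passed to [highest_conversion()].
#' @return List with `pairs` (data frame `editor_id`, `on_site`, `off_site`,
#'   `onCh`, `offCh`, `specificity`, `label`) and `summary` (data frame per
#'   on-target: worst-case and pooled specificity).
#' @export
specificity_panel <- function(tables, pairs, editor_id = "editor",
                              min_activity = 0.05, min_depth = 1L) {
  stopifnot(all(c("on_site_id", "off_site_id") %in% names(pairs)))
  missing_sites <- setdiff(unique(c(pairs$on_site_id, pairs$off_site_id)),
                           names(tables))
  if (length(missing_sites)) {
    stop("pairing references site(s) with no conversion table: ",
         paste(missing_sites, collapse = ", "))
  }
  hc <- lapply(tables, highest_conversion, min_depth = min_depth)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    on <- pairs$on_site_id[i]; off <- pairs$off_site_id[i]
    sc <- specificity_score(hc[[on]]$value, hc[[off]]$value,
                            min_activity = min_activity)
    data.frame(editor_id = editor_id, on_site = on, off_site = off,
               onCh = hc[[on]]$value, offCh = hc[[off]]$value,
               specificity = sc$value, label = sc$label,
               stringsAsFactors = FALSE)
  })
  per_pair <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_pair, per_pair$on_site), function(d) {
    onCh <- d$onCh[1]
    worst <- if (all(is.na(d$specificity))) NA_real_ else min(d$specificity, na.rm = TRUE)
    worst_label <- if (all(d$label == "no-activity")) "no-activity"
                   else if (any(d$label == "N.Sp.")) "N.Sp." else "numeric"
    pooled <- specificity_score(onCh,
                                if (all(is.na(d$offCh))) NA_real_
                                else max(d$offCh, na.rm = TRUE),
                                min_activity = min_activity)
    data.frame(editor_id = editor_id, on_site = d$on_site[1],
               n_off = nrow(d), onCh = onCh,
               worst_specificity = worst, worst_label = worst_label,
               pooled_specificity = pooled$value, pooled_label = pooled$label,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(pairs = per_pair, summary = summary)
}
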