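# Editing-window statistics: per-sgRNA normalization, editing scope,
# comprehensive editing window (CEW), and window-location classification.

#' Normalize per-position frequencies within one sgRNA
#'
#' The cytosine with the highest C->T conversion frequency is normalized to 1
#' and every other position is divided by the same maximum. Missing values
#' stay missing. An sgRNA whose frequencies are all zero or missing is
#' flagged `no_editing` (attribute) with all values set to `NA`; such sgRNAs
#' are excluded from CEW averaging rather than raising an error.
#'
#' @param freqs Named numeric vector: raw C->T frequency by signed position.
#' @return Named numeric vector of normalized values (max exactly 1), with
#'   attribute `no_editing`.
#' @export
normalize_sgrna <- function(freqs) {
  if (length(freqs) == 0L || all(is.na(freqs))) {
    return(structure(freqs[0], no_editing = TRUE))
  }
  mx <- max(freqs, na.rm = TRUE)
  if (mx <= 0) {
    return(structure(stats::setNames(rep(NA_real_, length(freqs)), names(freqs)),
                     no_editing = TRUE))
  }
  structure(freqs / mx, no_editing = FALSE)
}

#' Per-sgRNA editing scope
#'
#' The set of C positions edited at or above the raw-frequency threshold
#' (inclusive: a position at exactly the threshold is in scope).
#'
#' @param freqs Named numeric vector of raw C->T frequencies by position.
#' @param threshold Raw frequency threshold (default 0.40).
#' @return Sorted integer vector of in-scope positions.
#' @export
editing_scope <- function(freqs, threshold = 0.40) {
  sel <- !is.na(freqs) & freqs >= threshold
  sort(as.integer(names(freqs)[sel]))
}

#' Comprehensive editing window across an sgRNA panel
#'
#' For each position, the normalized values are averaged across the sgRNAs
#' that carry a reference C there (missing positions are excluded from the
#' mean, not averaged in as zero); the CEW is the set of positions whose mean
#' strictly exceeds the threshold. sgRNAs flagged `no_editing` are excluded.
#'
#' @param norm_list List of normalized maps from [normalize_sgrna()], one per
#'   sgRNA.
#' @param threshold CEW threshold on the mean normalized efficiency
#'   (default 0.6; membership is strict, `> threshold`).
#' @return List with `mean` (named numeric: per-position mean over covering
#'   sgRNAs), `cew` (sorted integer vector), `n_sgrnas` (number contributing).
#' @export
comprehensive_window <- function(norm_list, threshold = 0.6) {
  active <- Filter(function(x) !isTRUE(attr(x, "no_editing")), norm_list)
  if (length(active) == 0L) {
    return(list(mean = stats::setNames(numeric(0), character(0)),
                cew = integer(0), n_sgrnas = 0L))
  }
  all_cp <- sort(unique(unlist(lapply(active, function(x) as.integer(names(x))))))
  means <- vapply(all_cp, function(p) {
    v <- unlist(lapply(active, function(x) x[as.character(p)]))
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  names(means) <- all_cp
  means <- means[!is.na(means)]
  cew <- sort(as.integer(names(means)[means > threshold]))
  list(mean = means, cew = cew, n_sgrnas = length(active))
}

#' Classify an editor by the location of its comprehensive editing window
#'
#' With `a = min(cew)` and `b = max(cew)`: an empty window is `inactive`; a
#' window spanning at least `broad_span` positions, or reaching both ends
#' (`a <= broad_start_max` and `b >= broad_end_min`), is broad-range
#' (`BRCBE`); otherwise a window starting at or beyond `backward_start_min`
#' is backward-shifted (`BSCBE`), and anything else is forward-shifted
#' (`FSCBE`).
#'
#' @param cew Integer vector of CEW positions (may be empty).
#' @param broad_span Minimum span `b - a + 1` for a broad-range call
#'   (default 12).
#' @param broad_start_max,broad_end_min Alternative broad-range rule: window
#'   starts at or before `broad_start_max` and ends at or after
#'   `broad_end_min` (defaults 2 and 9).
#' @param backward_start_min Minimum window start for a backward-shifted call
#'   (default 7).
#' @return One of `"FSCBE"`, `"BSCBE"`, `"BRCBE"`, `"inactive"`.
#' @export
classify_editor <- function(cew, broad_span = 12L, broad_start_max = 2L,
                            broad_end_min = 9L, backward_start_min = 7L) {
  if (length(cew) == 0L) return("inactive")
  a <- min(cew); b <- max(cew)
  if ((b - a + 1L) >= broad_span || (a <= broad_start_max && b >= broad_end_min)) {
    return("BRCBE")
  }
  if (a >= backward_start_min) return("BSCBE")
  "FSCBE"
}

#' Editing-window analysis for one editor over an sgRNA panel
#'
#' Runs normalization, per-sgRNA editing scope, the comprehensive editing
#' window, and window-location classification.
#'
#' @param freq_maps Named list (one element per sgRNA) of raw C->T frequency
#'   maps (named numeric by signed position), e.g. from
#'   [conversion_frequencies()].
#' @param editor_id Editor identifier carried into the result.
#' @param scope_threshold Raw-frequency scope threshold (default 0.40,
#'   inclusive).
#' @param cew_threshold Mean-normalized CEW threshold (default 0.6, strict).
#' @param ... Classification parameters passed to [classify_editor()].
#' @return A `window_result`: list with `editor_id`, `raw`, `norm`, `scope`
#'   (per-sgRNA), `mean_norm`, `cew`, `class_label`.
#' @export
analyze_windows <- function(freq_maps, editor_id = "editor",
                            scope_threshold = 0.40, cew_threshold = 0.6, ...) {
  stopifnot(is.list(freq_maps), length(freq_maps) >= 1L)
  if (is.null(names(freq_maps))) {
    names(freq_maps) <- sprintf("sgRNA%02d", seq_along(freq_maps))
  }
  norm <- lapply(freq_maps, normalize_sgrna)
  scope <- lapply(freq_maps, editing_scope, threshold = scope_threshold)
  cw <- comprehensive_window(norm, threshold = cew_threshold)
  structure(
    list(editor_id = editor_id, raw = freq_maps, norm = norm, scope = scope,
         mean_norm = cw$mean, cew = cw$cew, n_sgrnas = cw$n_sgrnas,
         class_label = classify_editor(cw$cew, ...)),
    class = "window_result")
}

#' @export
print.window_result <- function(x, ...) {
  cat(sprintf("window_result '%s': %d sgRNAs, CEW {%s}, class %s\n",
              x$editor_id, x$n_sgrnas, paste(x$cew, collapse = ","),
              x$class_label))
  invisible(x)
}

#' Write a window result as TSV
#'
#' One row per position with the mean normalized efficiency and CEW
#' membership, plus the class label.
#'
#' @param result A `window_result` from [analyze_windows()].
#' @param path TSV path.
#' @export
write_window_result <- function(result, path) {
  cps <- as.integer(names(result$mean_norm))
  write_tsv_file(data.frame(
    editor_id = result$editor_id, cp = cps,
    mean_norm = unname(result$mean_norm),
    in_cew = cps %in% result$cew,
    class_label = result$class_label, stringsAsFactors = FALSE), path)
}
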