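# Substrate (sequence-context) preference: select high-activity C sites,
# group by the upstream NC / downstream CN dinucleotide, test by one-way
# ANOVA, and emit a ranked preference string.

#' Per-site table of positions, contexts and normalized frequencies
#'
#' Convenience builder joining a conversion table with its site's dinucleotide
#' contexts and a normalized frequency map, one row per reference-C window
#' position.
#'
#' @param site A [target_site()].
#' @param norm Named numeric vector of normalized frequencies by position
#'   (from [normalize_sgrna()]).
#' @return Data frame with columns `site_id`, `cp`, `upstream_di`,
#'   `downstream_di`, `norm`.
#' @export
site_context_table <- function(site, norm) {
  cps <- as.integer(names(norm))
  if (length(cps) == 0L) {
    return(data.frame(site_id = character(0), cp = integer(0),
                      upstream_di = character(0), downstream_di = character(0),
                      norm = numeric(0), stringsAsFactors = FALSE))
  }
  ctx <- lapply(cps, context_at, site = site)
  data.frame(
    site_id = site$site_id, cp = cps,
    upstream_di = vapply(ctx, `[[`, character(1), "upstream_di"),
    downstream_di = vapply(ctx, `[[`, character(1), "downstream_di"),
    norm = unname(norm), stringsAsFactors = FALSE)
}

#' Select high-activity C sites for preference analysis
#'
#' A position class (the same signed position across sgRNAs) qualifies when
#' at least one C site there reaches the normalized-frequency threshold; all
#' C sites at qualifying positions are returned with their contexts.
#'
#' @param sites_df Data frame as from [site_context_table()], rows pooled
#'   over the sgRNA panel.
#' @param min_norm Normalized-frequency selection threshold (default 0.8,
#'   inclusive).
#' @return The qualifying rows of `sites_df`; zero rows (with attribute
#'   `no_qualifying = TRUE`) when no position qualifies.
#' @export
select_sites <- function(sites_df, min_norm = 0.8) {
  ok <- !is.na(sites_df$norm)
  qual_cp <- unique(sites_df$cp[ok & sites_df$norm >= min_norm])
  out <- sites_df[ok & sites_df$cp %in% qual_cp, , drop = FALSE]
  if (nrow(out) == 0L) attr(out, "no_qualifying") <- TRUE
  out
}

#' Group selected sites by dinucleotide context
#'
#' @param sites_df Selected sites from [select_sites()].
#' @param direction `"upstream"` (NC contexts AC/CC/GC/TC) or `"downstream"`
#'   (CN contexts CA/CC/CG/CT).
#' @return Named list of numeric vectors (normalized frequencies); contexts
#'   with no sites are reported as zero-length vectors (and are excluded from
#'   ANOVA by [one_way_anova()]'s caller).
#' @export
group_by_context <- function(sites_df, direction = c("upstream", "downstream")) {
  direction <- match.arg(direction)
  levels <- if (direction == "upstream") c("AC", "CC", "GC", "TC")
            else c("CA", "CC", "CG", "CT")
  col <- if (direction == "upstream") "upstream_di" else "downstream_di"
  f <- factor(sites_df[[col]], levels = levels)
  split(sites_df$norm, f)
}

#' Classical fixed-effects one-way ANOVA
#'
#' `F = (SSB / (k - 1)) / (SSW / (N - k))` with the p-value from the F
#' distribution on `(k - 1, N - k)` degrees of freedom (computed via
#' [stats::aov()]). Requires at least
#' two groups with at least one value each and total within-group df >= 1.
#' Zero within-group variance with unequal means yields `F = Inf`, `p = 0`,
#' flagged `degenerate`.
#'
#' @param groups List of >= 2 numeric vectors.
#' @return List with `F`, `p`, `df1`, `df2`, `degenerate`.
#' @export
one_way_anova <- function(groups) {
  groups <- Filter(length, groups)
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  if (k < 2L || N - k < 1L) {
    stop("analysis undefined: need >= 2 non-empty groups and within-group df >= 1")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), n))
  ssw <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  if (ssw == 0) {
    means <- vapply(groups, mean, numeric(1))
    if (max(means) - min(means) > 0) {
      return(list(F = Inf, p = 0, df1 = k - 1L, df2 = N - k, degenerate = TRUE))
    }
    return(list(F = 0, p = 1, df1 = k - 1L, df2 = N - k, degenerate = TRUE))
  }
  at <- stats::anova(stats::aov(y ~ g))
  list(F = at[["F value"]][1], p = at[["Pr(>F)"]][1],
       df1 = at[["Df"]][1], df2 = at[["Df"]][2], degenerate = FALSE)
}

#' Ranked substrate-preference string
#'
#' Contexts are sorted by group mean (descending); consecutive contexts whose
#' means differ by less than `tie_tol` are joined into one `/`-tier, and
#' tiers are separated by `>`. When an ANOVA p-value is supplied and is not
#' significant at `alpha`, the string `"N.S."` is returned instead.
#'
#' @param groups Named list of numeric vectors (non-empty groups only).
#' @param p Optional ANOVA p-value.
#' @param tie_tol Absolute tie tolerance on group means (default 0.05).
#' @param alpha Significance level (default 0.05).
#' @return Character scalar such as `"TC/AC>CC>GC"`, or `"N.S."`.
#' @export
preference_ordering <- function(groups, p = NULL, tie_tol = 0.05, alpha = 0.05) {
  groups <- Filter(length, groups)
  if (length(groups) < 2L) stop("need >= 2 non-empty groups to rank")
  if (!is.null(p) && !is.na(p) && p >= alpha) return("N.S.")
  means <- sort(vapply(groups, mean, numeric(1)), decreasing = TRUE)
  tiers <- list(names(means)[1])
  for (i in seq_along(means)[-1]) {
    if (means[i - 1] - means[i] < tie_tol) {
      tiers[[length(tiers)]] <- c(tiers[[length(tiers)]], names(means)[i])
    } else {
      tiers[[length(tiers) + 1L]] <- names(means)[i]
    }
  }
  paste(vapply(tiers, paste, character(1), collapse = "/"), collapse = ">")
}

#' Substrate-preference analysis for one editor
#'
#' Pools the per-sgRNA context tables, applies the high-activity selection
#' rule, and — separately for the upstream (NC) and downstream (CN)
#' direction — groups by context, runs one-way ANOVA and ranks the contexts.
#'
#' @param site_tables List of data frames from [site_context_table()], one
#'   per sgRNA (values already normalized per sgRNA).
#' @param editor_id Editor identifier carried into the result.
#' @param min_norm Selection threshold (default 0.8).
#' @param tie_tol,alpha Ranking parameters (see [preference_ordering()]).
#' @return A `preference_result`: list with one element per direction, each
#'   holding `groups`, `n`, `means`, `F`, `p`, `df`, `ordering`,
#'   `significant`, plus `selected` (the pooled selected-site table).
#' @export
analyze_preference <- function(site_tables, editor_id = "editor",
                               min_norm = 0.8, tie_tol = 0.05, alpha = 0.05) {
  pooled <- do.call(rbind, site_tables)
  sel <- select_sites(pooled, min_norm = min_norm)
  res <- list(editor_id = editor_id, selected = sel)
  for (direction in c("upstream", "downstream")) {
    groups <- group_by_context(sel, direction)
    nonempty <- Filter(length, groups)
    entry <- list(groups = groups, n = lengths(groups),
                  means = vapply(nonempty, mean, numeric(1)),
                  F = NA_real_, p = NA_real_, df = c(NA_integer_, NA_integer_),
                  ordering = NA_character_, significant = NA)
    if (length(nonempty) >= 2L && sum(lengths(nonempty)) - length(nonempty) >= 1L) {
      av <- one_way_anova(nonempty)
      entry$F <- av$F; entry$p <- av$p; entry$df <- c(av$df1, av$df2)
      entry$ordering <- preference_ordering(nonempty, p = av$p,
                                            tie_tol = tie_tol, alpha = alpha)
      entry$significant <- av$p < alpha
    }
    res[[direction]] <- entry
  }
  structure(res, class = "preference_result")
}

#' @export
print.preference_result <- function(x, ...) {
  cat(sprintf("preference_result '%s': %d selected sites\n",
              x$editor_id, nrow(x$selected)))
  for (d in c("upstream", "downstream")) {
    cat(sprintf("  %-10s F = %.3g, p = %.3g, ordering %s\n",
                d, x[[d]]$F, x[[d]]$p, x[[d]]$ordering))
  }
  invisible(x)
}

#' Write a preference result as TSV
#'
#' One row per direction x context with group size and mean, plus the shared
#' F, p and ordering.
#'
#' @param result A `preference_result`.
#' @param path TSV path.
#' @export
write_preference_result <- function(result, path) {
  rows <- do.call(rbind, lapply(c("upstream", "downstream"), function(d) {
    e <- result[[d]]
    data.frame(editor_id = result$editor_id, direction = d,
               context = names(e$n), n = unname(e$n),
               mean = unname(e$means[names(e$n)]),
               F = e$F, p = e$p, ordering = e$ordering,
               stringsAsFactors = FALSE)
  }))
  write_tsv_file(rows, path)
}
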