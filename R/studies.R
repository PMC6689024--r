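# Replicated simulation studies: the validation experiments that the
# analysis scripts and the acceptance checks run. Each study derives all of
# its randomness from one master seed.

#' Brute-force one-way ANOVA by explicit sums of squares
#'
#' Independent reference route for [one_way_anova()]: computes the between-
#' and within-group sums of squares directly from their textbook definitions
#' and the p-value from [stats::pf()]. Kept deliberately naive (explicit
#' loops over groups) so it shares no code path with the main routine.
#'
#' @param groups List of >= 2 numeric vectors.
#' @return List with `F`, `p`, `df1`, `df2`, `ssb`, `ssw`.
#' @export
anova_bruteforce <- function(groups) {
  groups <- Filter(length, groups)
  k <- length(groups)
  N <- sum(lengths(groups))
  grand <- mean(unlist(groups, use.names = FALSE))
  ssb <- 0; ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    for (v in g) ssw <- ssw + (v - mean(g))^2
  }
  Fv <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fv, p = stats::pf(Fv, k - 1, N - k, lower.tail = FALSE),
       df1 = k - 1L, df2 = N - k, ssb = ssb, ssw = ssw)
}

#' Frequency-recovery study
#'
#' For each built-in archetype profile, simulates reads on a window-panel
#' site, runs the full quantification pipeline (trim, place, tabulate), and
#' compares the observed C->T frequency at every reference-C window position
#' with the closed-form expectation, expressing the deviation in binomial
#' standard deviations of the realized depth.
#'
#' @param n_reads Reads per sample (default 20000).
#' @param seed Master seed.
#' @return Data frame with one row per (profile, position): `editor_id`,
#'   `cp`, `expected`, `observed`, `depth`, `sd`, `z` (abs deviation / sd).
#' @export
frequency_recovery_study <- function(n_reads = 20000L, seed = 1L) {
  site <- window_panel_sites(seed = derive_seed(seed, 1L), n_sites = 1L)[[1]]
  profiles <- make_profile_library()
  rows <- lapply(seq_along(profiles), function(i) {
    prof <- profiles[[i]]
    sim <- simulate_reads(site, prof, n_reads, seed = derive_seed(seed, 10L + i))
    q <- quantify_sample(sim$reads, site)
    obs <- conversion_frequencies(q$table)
    depth <- stats::setNames(q$table$depth[q$table$ref_base == "C"],
                             q$table$cp[q$table$ref_base == "C"])
    tr <- sim$truth
    exp_f <- tr$expected_freq
    obs_f <- unname(obs[as.character(tr$cp)])
    d <- unname(depth[as.character(tr$cp)])
    sd <- sqrt(pmax(exp_f * (1 - exp_f), 1e-12) / d)
    data.frame(editor_id = prof$editor_id, cp = tr$cp, expected = exp_f,
               observed = obs_f, depth = d, sd = sd,
               z = abs(obs_f - exp_f) / sd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Comprehensive-editing-window recovery study
#'
#' An editor with editing probability `p_in` at positions 4-8 and `p_out`
#' elsewhere in the window is simulated over the 9-sgRNA window panel; each
#' seed's run is scored a success when the recovered CEW is exactly
#' \{4,...,8\} under the strict `> 0.6` rule.
#'
#' @param n_seeds Number of independent seeded runs (default 20).
#' @param n_reads Reads per sgRNA sample (default 10000).
#' @param p_in,p_out Editing probabilities inside/outside positions 4-8
#'   (defaults 0.6 and 0.05).
#' @param seed Master seed.
#' @param read_level Simulate at read level (`TRUE`, default) or at count
#'   level via [simulate_site_counts()].
#' @return List with `successes`, `n_seeds`, `cews` (list of recovered CEWs).
#' @export
cew_recovery_study <- function(n_seeds = 20L, n_reads = 10000L, p_in = 0.6,
                               p_out = 0.05, seed = 1L, read_level = TRUE) {
  sites <- window_panel_sites(seed = derive_seed(seed, 1L))
  win <- quantification_window(sites[[1]])
  p_edit <- stats::setNames(rep(p_out, length(win)), win)
  p_edit[as.character(4:8)] <- p_in
  prof <- editor_profile("cew_probe", p_edit)
  cews <- lapply(seq_len(n_seeds), function(r) {
    freq_maps <- lapply(seq_along(sites), function(j) {
      s <- derive_seed(seed, 1000L * r + j)
      tab <- if (read_level) {
        sim <- simulate_reads(sites[[j]], prof, n_reads, seed = s)
        quantify_sample(sim$reads, sites[[j]])$table
      } else {
        simulate_site_counts(sites[[j]], prof, n_reads, seed = s)
      }
      conversion_frequencies(tab)
    })
    analyze_windows(freq_maps, editor_id = "cew_probe")$cew
  })
  list(successes = sum(vapply(cews, identical, logical(1), y = 4:8)),
       n_seeds = n_seeds, cews = cews)
}

#' Editor-classification recovery study
#'
#' Simulates the forward, backward and broad archetypes over a 4-sgRNA
#' subset of the window panel and classifies each run from its recovered
#' CEW; reports the per-archetype success rate against the expected labels
#' FSCBE / BSCBE / BRCBE.
#'
#' @param n_runs Seeded runs per archetype (default 100).
#' @param n_reads Reads per sgRNA sample (default 10000).
#' @param n_sgrnas Panel size per run (default 4).
#' @param seed Master seed.
#' @param read_level Read-level (`TRUE`, default) or count-level simulation.
#' @return Data frame with `editor_id`, `expected_class`, `n_runs`,
#'   `n_correct`, `rate`.
#' @export
classification_study <- function(n_runs = 100L, n_reads = 10000L,
                                 n_sgrnas = 4L, seed = 1L, read_level = TRUE) {
  sites <- window_panel_sites(seed = derive_seed(seed, 1L), n_sites = n_sgrnas)
  profiles <- make_profile_library()[c("forward", "backward", "broad")]
  expected <- c(forward = "FSCBE", backward = "BSCBE", broad = "BRCBE")
  rows <- lapply(names(profiles), function(nm) {
    prof <- profiles[[nm]]
    labels <- vapply(seq_len(n_runs), function(r) {
      freq_maps <- lapply(seq_along(sites), function(j) {
        s <- derive_seed(seed, 97L * match(nm, names(profiles)) + 1000L * r + j)
        tab <- if (read_level) {
          sim <- simulate_reads(sites[[j]], prof, n_reads, seed = s)
          quantify_sample(sim$reads, sites[[j]])$table
        } else {
          simulate_site_counts(sites[[j]], prof, n_reads, seed = s)
        }
        conversion_frequencies(tab)
      })
      analyze_windows(freq_maps, editor_id = nm)$class_label
    }, character(1))
    data.frame(editor_id = nm, expected_class = expected[[nm]],
               n_runs = n_runs, n_correct = sum(labels == expected[[nm]]),
               rate = mean(labels == expected[[nm]]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# internal: one preference analysis over the balanced context panel
run_preference_once <- function(sites, prof, n_reads, seed, read_level) {
  site_tables <- lapply(seq_along(sites), function(j) {
    s <- derive_seed(seed, j)
    tab <- if (read_level) {
      sim <- simulate_reads(sites[[j]], prof, n_reads, seed = s)
      quantify_sample(sim$reads, sites[[j]])$table
    } else {
      simulate_site_counts(sites[[j]], prof, n_reads, seed = s)
    }
    site_context_table(sites[[j]], normalize_sgrna(conversion_frequencies(tab)))
  })
  analyze_preference(site_tables, editor_id = prof$editor_id)
}

#' Substrate-preference recovery study (GC-averse editor)
#'
#' Simulates the GC-averse archetype (upstream GC multiplier 0.1 vs 1
#' elsewhere) over the balanced context panel and scores each run a success
#' when the upstream-direction ANOVA is significant at 0.05 and GC ranks
#' last.
#'
#' @param n_runs Seeded runs (default 100).
#' @param n_reads Reads per sgRNA sample (default 10000).
#' @param seed Master seed.
#' @param read_level Read-level (`TRUE`, default) or count-level simulation.
#' @return List with `successes`, `n_runs`, `details` (data frame of p and
#'   last-ranked context per run).
#' @export
preference_recovery_study <- function(n_runs = 100L, n_reads = 10000L,
                                      seed = 1L, read_level = TRUE) {
  sites <- preference_panel_sites(seed = derive_seed(seed, 1L))
  prof <- make_profile_library()$gc_averse
  details <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
    res <- run_preference_once(sites, prof, n_reads,
                               seed = derive_seed(seed, 1000L * r),
                               read_level = read_level)
    up <- res$upstream
    means <- up$means
    data.frame(run = r, p = up$p,
               last_context = names(means)[which.min(means)],
               ordering = up$ordering, stringsAsFactors = FALSE)
  }))
  ok <- !is.na(details$p) & details$p < 0.05 & details$last_context == "GC"
  list(successes = sum(ok), n_runs = n_runs, details = details)
}

#' Type-I error of the preference ANOVA under a null editor
#'
#' A null editor (flat editing probability, all context multipliers equal)
#' is simulated repeatedly over the balanced context panel at count level;
#' the study reports how often the upstream-direction ANOVA is significant
#' at the nominal 0.05 level. Under the null every context group has the
#' same value distribution, so the rejection rate estimates the test's
#' type-I error.
#'
#' @param n_reps Replicates (default 1000).
#' @param n_reads Reads per sgRNA sample (default 10000).
#' @param p_edit_flat Editing probability at every protospacer position
#'   (default 0.6).
#' @param seed Master seed.
#' @return List with `rejections`, `n_reps`, `rate`.
#' @export
preference_type1_study <- function(n_reps = 1000L, n_reads = 10000L,
                                   p_edit_flat = 0.6, seed = 1L) {
  sites <- preference_panel_sites(seed = derive_seed(seed, 1L))
  prof <- editor_profile(
    "null_editor", stats::setNames(rep(p_edit_flat, 14), 1:14))
  ps <- vapply(seq_len(n_reps), function(r) {
    res <- run_preference_once(sites, prof, n_reads,
                               seed = derive_seed(seed, 1000L * r),
                               read_level = FALSE)
    res$upstream$p
  }, numeric(1))
  rej <- sum(!is.na(ps) & ps < 0.05)
  list(rejections = rej, n_reps = n_reps, rate = rej / n_reps)
}

#' Specificity-recovery study
#'
#' Simulates an on-target site edited at probability `q_on` and an off-target
#' edited at `q_off` (no sequencing error), quantifies both through the full
#' read pipeline, and computes the specificity score, whose expectation is
#' `(q_on - q_off) / q_on`.
#'
#' @param n_reads Reads per site (default 20000).
#' @param q_on,q_off Editing probabilities (defaults 0.5 and 0.1).
#' @param seed Master seed.
#' @return List with `expected`, `observed`, `onCh`, `offCh`, `label`.
#' @export
specificity_recovery_study <- function(n_reads = 20000L, q_on = 0.5,
                                       q_off = 0.1, seed = 1L) {
  panel <- specificity_panel_sites(seed = derive_seed(seed, 1L), n_off = 1L)
  mk <- function(id, q) editor_profile(id, stats::setNames(rep(q, 14), 1:14),
                                       seq_error = 0)
  tabs <- list(
    on_target = {
      sim <- simulate_reads(panel$sites$on_target, mk("on", q_on), n_reads,
                            seed = derive_seed(seed, 2L))
      quantify_sample(sim$reads, panel$sites$on_target)$table
    },
    off_target01 = {
      sim <- simulate_reads(panel$sites$off_target01, mk("off", q_off), n_reads,
                            seed = derive_seed(seed, 3L))
      quantify_sample(sim$reads, panel$sites$off_target01)$table
    })
  res <- specificity_panel(tabs, panel$pairs[1, , drop = FALSE],
                           editor_id = "probe")
  list(expected = (q_on - q_off) / q_on,
       observed = res$pairs$specificity[1],
       onCh = res$pairs$onCh[1], offCh = res$pairs$offCh[1],
       label = res$pairs$label[1])
}
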