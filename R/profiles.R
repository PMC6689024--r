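# Generative editor profiles and the amplicon read simulator.
#
# A profile is a per-position C->T editing probability plus dinucleotide
# context multipliers. Reads are simulated on the protospacer strand across
# the quantification window (plus flanks), with independent per-position
# editing, uniform substitution sequencing error, and constant Phred
# qualities (optionally with a low-quality 3' tail for trim testing).

BASES <- c("A", "C", "G", "T")

#' Construct an editor profile
#'
#' @param editor_id Character scalar.
#' @param p_edit Named numeric vector: baseline per-position C->T editing
#'   probability, names are signed protospacer positions. Positions absent
#'   from the map have probability 0.
#' @param context_mult Named multipliers for the upstream dinucleotide
#'   (`AC`, `CC`, `GC`, `TC`), all >= 0. The effective editing probability at
#'   a C is `min(1, p_edit * context_mult[NC] * context_mult_down[CN])`;
#'   clipping events are counted by the simulator.
#' @param context_mult_down Optional multipliers for the downstream
#'   dinucleotide (`CA`, `CC`, `CG`, `CT`); default all 1.
#' @param seq_error Per-base uniform substitution probability (< 0.25).
#' @param base_quality Phred score assigned to simulated bases (default 37).
#' @param low_q_tail_len Number of 3' bases given `low_q_score` (default 0).
#' @param low_q_score Phred score of the low-quality tail (default 2).
#' @return An object of class `editor_profile`.
#' @export
editor_profile <- function(editor_id, p_edit,
                           context_mult = c(AC = 1, CC = 1, GC = 1, TC = 1),
                           context_mult_down = c(CA = 1, CC = 1, CG = 1, CT = 1),
                           seq_error = 0.001, base_quality = 37L,
                           low_q_tail_len = 0L, low_q_score = 2L) {
  stopifnot(is.character(editor_id), length(editor_id) == 1L)
  p_edit <- unlist(p_edit)
  if (length(p_edit) && is.null(names(p_edit))) {
    stop("p_edit must be named by signed protospacer position")
  }
  if (any(p_edit < 0 | p_edit > 1)) stop("p_edit values must lie in [0, 1]")
  if (any(as.integer(names(p_edit)) == 0L)) stop("p_edit has an entry at position 0")
  cm <- c(AC = 1, CC = 1, GC = 1, TC = 1); cm[names(context_mult)] <- context_mult
  cmd <- c(CA = 1, CC = 1, CG = 1, CT = 1); cmd[names(context_mult_down)] <- context_mult_down
  if (any(cm < 0) || any(cmd < 0)) stop("context multipliers must be >= 0")
  if (seq_error < 0 || seq_error >= 0.25) stop("seq_error must lie in [0, 0.25)")
  structure(
    list(editor_id = editor_id, p_edit = p_edit, context_mult = cm,
         context_mult_down = cmd, seq_error = seq_error,
         base_quality = as.integer(base_quality),
         low_q_tail_len = as.integer(low_q_tail_len),
         low_q_score = as.integer(low_q_score)),
    class = "editor_profile")
}

#' @export
print.editor_profile <- function(x, ...) {
  sup <- names(x$p_edit)[x$p_edit > 0]
  cat(sprintf("editor_profile '%s': p_edit > 0 at {%s}, seq_error %g\n",
              x$editor_id, paste(sup, collapse = ","), x$seq_error))
  cat("  upstream context multipliers:",
      paste(sprintf("%s=%g", names(x$context_mult), x$context_mult), collapse = " "), "\n")
  invisible(x)
}

# internal: effective (clipped) editing probability at a reference C
edit_prob <- function(profile, site, cp) {
  p <- profile$p_edit[as.character(cp)]
  p <- if (is.na(p)) 0 else unname(p)
  ctx <- context_at(site, cp)
  q_raw <- p * profile$context_mult[[ctx$upstream_di]] *
    profile$context_mult_down[[ctx$downstream_di]]
  list(q = min(1, q_raw), clipped = q_raw > 1)
}

#' Expected observed T frequency at a reference C
#'
#' Closed-form expectation under the generative model: with effective editing
#' probability `q` and uniform substitution error `e`, the expected fraction
#' of reads showing T at the position is `q (1 - e) + (1 - q) e / 3`.
#'
#' @param profile An [editor_profile()].
#' @param site A [target_site()].
#' @param cp Signed protospacer position; must carry a reference C on the
#'   protospacer strand.
#' @return Probability in `[0, 1]`.
#' @export
expected_t_frequency <- function(profile, site, cp) {
  q <- edit_prob(profile, site, cp)$q
  e <- profile$seq_error
  q * (1 - e) + (1 - q) * e / 3
}

#' Simulate amplicon sequencing reads for one sample
#'
#' Generates `n_reads` reads on the protospacer strand spanning the full
#' quantification window plus flanks (clipped to the amplicon). Independently
#' per read and per reference-C window position, C->T conversion occurs with
#' the profile's effective probability; every base is then substituted
#' uniformly to one of the other three bases with probability `seq_error`.
#' Output is deterministic for a fixed seed.
#'
#' @param site A [target_site()].
#' @param profile An [editor_profile()].
#' @param n_reads Number of reads (>= 0).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param barcode Optional sample barcode prepended to every read.
#' @param flank5,flank3 Extra bases beyond the window at the protospacer-
#'   strand 5' and 3' ends (defaults 25 and 12; clipped to the amplicon).
#' @return A list with `reads` (data frame `id`, `seq`, `qual`), `truth`
#'   (data frame `site_id`, `cp`, `expected_freq`, `n_reads`, `seed`: the
#'   closed-form expected T frequency at every reference-C window position)
#'   and `clipped_events` (number of positions whose context-multiplied
#'   probability was clipped at 1).
#' @export
simulate_reads <- function(site, profile, n_reads, seed, barcode = "",
                           flank5 = 25L, flank3 = 12L) {
  stopifnot(inherits(site, "target_site"), inherits(profile, "editor_profile"))
  if (n_reads < 0) stop("n_reads must be >= 0")
  n_reads <- as.integer(n_reads)
  win <- quantification_window(site)
  win_off <- cp_to_offset(win)
  amp_len <- nchar(site$amplicon_seq)
  # admissible offsets along the protospacer strand, clipped to the amplicon
  off_bounds <- if (site$strand == "+") {
    c(-site$protospacer_start, amp_len - 1L - site$protospacer_start)
  } else {
    c(site$protospacer_start - amp_len + 1L, site$protospacer_start)
  }
  offs <- seq.int(max(min(win_off) - as.integer(flank5), off_bounds[1]),
                  min(max(win_off) + as.integer(flank3), off_bounds[2]))
  cps <- offset_to_cp(offs)
  template <- protospacer_base(site, cps)
  L <- length(template)

  # effective editing probability at each reference-C window position
  c_cols <- which(template == "C" & cps %in% win)
  probs <- lapply(c_cols, function(j) edit_prob(profile, site, cps[j]))
  qs <- vapply(probs, `[[`, numeric(1), "q")
  clipped <- sum(vapply(probs, `[[`, logical(1), "clipped"))

  truth_cp <- cps[c_cols]
  truth <- data.frame(
    site_id = site$site_id,
    cp = truth_cp,
    expected_freq = if (length(truth_cp)) {
      vapply(truth_cp, function(p) expected_t_frequency(profile, site, p), numeric(1))
    } else numeric(0),
    n_reads = n_reads, seed = as.integer(seed),
    stringsAsFactors = FALSE)

  if (n_reads == 0L) {
    reads <- data.frame(id = character(0), seq = character(0),
                        qual = character(0), stringsAsFactors = FALSE)
    return(list(reads = reads, truth = truth, clipped_events = clipped))
  }

  seqs <- with_seed(seed, {
    s <- rep(paste(template, collapse = ""), n_reads)
    for (k in seq_along(c_cols)) {
      if (qs[k] > 0) {
        hit <- stats::runif(n_reads) < qs[k]
        substring(s[hit], c_cols[k], c_cols[k]) <- "T"
      }
    }
    e <- profile$seq_error
    if (e > 0) {
      err <- which(stats::runif(n_reads * L) < e)  # read-major grid
      if (length(err)) {
        # substitute uniformly to one of the other three bases
        alt <- matrix(c("C", "G", "T",  "A", "G", "T",
                        "A", "C", "T",  "A", "C", "G"), nrow = 3)
        pick <- sample.int(3L, length(err), replace = TRUE)
        rows <- (err - 1L) %/% L + 1L
        cols <- (err - 1L) %% L + 1L
        for (j in unique(cols)) {
          sel <- cols == j
          cur <- substring(s[rows[sel]], j, j)
          substring(s[rows[sel]], j, j) <- alt[cbind(pick[sel], match(cur, BASES))]
        }
      }
    }
    s
  })

  qhi <- intToUtf8(profile$base_quality + 33L)
  qual <- if (profile$low_q_tail_len > 0L) {
    tl <- min(profile$low_q_tail_len, L)
    paste0(strrep(qhi, L - tl), strrep(intToUtf8(profile$low_q_score + 33L), tl))
  } else {
    strrep(qhi, L)
  }
  qual <- rep(qual, n_reads)
  if (nzchar(barcode)) {
    seqs <- paste0(barcode, seqs)
    qual <- paste0(strrep(qhi, nchar(barcode)), qual)
  }
  reads <- data.frame(
    id = sprintf("%s|%s|read%06d", site$site_id, profile$editor_id, seq_len(n_reads)),
    seq = seqs, qual = qual, stringsAsFactors = FALSE)
  list(reads = reads, truth = truth, clipped_events = clipped)
}

#' Simulate per-position conversion counts directly
#'
#' Count-level companion to [simulate_reads()]: for each window position it
#' draws the observed A/C/G/T counts from the same multinomial model that
#' read-level simulation followed by placement and tabulation induces when
#' every read spans the full window. Used for large replicate studies where
#' generating reads would add nothing but run time.
#'
#' @inheritParams simulate_reads
#' @return A `conversion_table` (see [tabulate_reads()]).
#' @export
simulate_site_counts <- function(site, profile, n_reads, seed) {
  stopifnot(inherits(site, "target_site"), inherits(profile, "editor_profile"))
  ref <- window_ref_bases(site)
  win <- as.integer(names(ref))
  e <- profile$seq_error
  counts <- with_seed(seed, {
    t(vapply(seq_along(win), function(i) {
      pr <- stats::setNames(rep(e / 3, 4), BASES)
      if (ref[i] == "C") {
        q <- edit_prob(profile, site, win[i])$q
        pr["T"] <- q * (1 - e) + (1 - q) * e / 3
        pr["C"] <- (1 - q) * (1 - e) + q * e / 3
        pr["A"] <- pr["G"] <- e / 3
      } else {
        pr[ref[i]] <- 1 - e
      }
      as.numeric(stats::rmultinom(1, n_reads, pr))
    }, numeric(4)))
  })
  colnames(counts) <- BASES
  new_conversion_table(site, win, ref, counts)
}

#' Built-in editor profile archetypes
#'
#' Four profiles whose high-activity regions mimic the canonical window
#' shapes seen across characterized cytosine base editors: `forward`
#' (positions 1-8, PAM-distal), `backward` (9-13, PAM-proximal), `broad`
#' (1-14), and `gc_averse` (broad support with a strongly disfavoured GC
#' upstream context, multiplier 0.1 vs 1 elsewhere).
#'
#' @param p_high Editing probability inside the support (default 0.6).
#' @param seq_error Per-base substitution error (default 0.001).
#' @return Named list of [editor_profile()] objects.
#' @export
make_profile_library <- function(p_high = 0.6, seq_error = 0.001) {
  flat <- function(cps) stats::setNames(rep(p_high, length(cps)), cps)
  list(
    forward  = editor_profile("forward",  flat(1:8),  seq_error = seq_error),
    backward = editor_profile("backward", flat(9:13), seq_error = seq_error),
    broad    = editor_profile("broad",    flat(1:14), seq_error = seq_error),
    gc_averse = editor_profile("gc_averse", flat(1:14),
                               context_mult = c(AC = 1, CC = 1, GC = 0.1, TC = 1),
                               seq_error = seq_error))
}

#' Write / read a simulation truth table
#'
#' @param truth Data frame as returned in `simulate_reads()$truth`.
#' @param path TSV path.
#' @name truth_io
#' @export
write_truth <- function(truth, path) write_tsv_file(truth, path)

#' @rdname truth_io
#' @export
read_truth <- function(path) read_tsv_file(path)
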