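# Built-in synthetic target-site panels. Each panel is a deterministic set
# of sgRNA target sites whose protospacer cytosine layout is designed for a
# specific analysis: scattered C sites for editing-window work, balanced
# dinucleotide contexts for substrate-preference work. Amplicon flanks are
# random filler (seeded), checked for unique protospacer and read-seed
# placement so quantification is unambiguous.

# internal: random DNA of length n from the given alphabet
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Build a synthetic target site around a designed protospacer
#'
#' Wraps a 20-nt protospacer and PAM in seeded random flanks wide enough to
#' hold the full quantification window plus simulator read flanks, and
#' verifies that the protospacer and the simulator's read-seed region place
#' uniquely on the amplicon (re-drawing the flanks if not).
#'
#' @param site_id Site identifier.
#' @param protospacer 20-nt protospacer sequence (protospacer strand).
#' @param seed Integer seed for the flank filler.
#' @param pam PAM sequence appended 3' of the protospacer (default `"AGG"`).
#' @param strand Orientation of the constructed annotation; for `"-"` the
#'   amplicon is reverse-complemented and the coordinates mirrored, so the
#'   protospacer-strand content is identical to the `"+"` construction.
#' @param flank5,flank3 Flank lengths (defaults 45 and 35).
#' @return A [target_site()].
#' @export
synth_target_site <- function(site_id, protospacer, seed, pam = "AGG",
                              strand = "+", flank5 = 45L, flank3 = 35L) {
  protospacer <- toupper(protospacer)
  stopifnot(!grepl("[^ACGT]", protospacer))
  with_seed(seed, {
    for (attempt in 1:50) {
      amp <- paste0(random_dna(flank5), protospacer, pam, random_dna(flank3))
      ps_start <- flank5
      # unique protospacer placement on both strands
      n_hits <- function(q, s) {
        h <- gregexpr(q, s, fixed = TRUE)[[1]]; sum(h > 0L)
      }
      hits <- n_hits(protospacer, amp) + n_hits(protospacer, revcomp(amp))
      # the simulator's default read start (window start - 25) must also be a
      # unique 20-mer so seed placement is unambiguous
      read_start <- ps_start - 30L - 5L  # window start (-30 from PAM) minus flank5 of reads
      seed20 <- substr(amp, read_start + 1L, read_start + 20L)
      hits2 <- n_hits(seed20, amp) + n_hits(seed20, revcomp(amp))
      if (hits == 1L && hits2 == 1L) {
        if (strand == "+") {
          return(target_site(site_id, amp, ps_start, strand = "+"))
        }
        # mirror: same double-stranded locus annotated on the other strand
        ramp <- revcomp(amp)
        ps_start_rev <- nchar(amp) - 1L - ps_start
        return(target_site(site_id, ramp, ps_start_rev, strand = "-"))
      }
    }
    stop("could not construct an unambiguous amplicon for site '", site_id, "'")
  })
}

# internal: 20-nt protospacer with C only at c_at; upstream_base[i] (if given)
# is written at position c_at[i] - 1. Filler avoids C so contexts are exact.
design_protospacer <- function(c_at, upstream_base = NULL, seed = 1L) {
  with_seed(seed, {
    for (attempt in 1:100) {
      p <- sample(c("A", "G", "T"), 20, replace = TRUE)
      p[c_at] <- "C"
      if (!is.null(upstream_base)) {
        for (i in seq_along(c_at)) {
          if (!is.na(upstream_base[i]) && c_at[i] > 1L) {
            p[c_at[i] - 1L] <- upstream_base[i]
          }
        }
      }
      if (identical(which(p == "C"), as.integer(sort(unique(
            c(c_at, c_at[which(!is.na(upstream_base) & upstream_base == "C")] - 1L)))))) {
        return(paste(p, collapse = ""))
      }
    }
    stop("could not satisfy the protospacer design constraints")
  })
}

#' sgRNA panel for editing-window analysis
#'
#' Nine target sites with multiple scattered protospacer cytosines; every
#' site carries at least one C in positions 4-8 and the panel covers each of
#' positions 4-8 at least twice, mirroring how editing-window panels are
#' chosen in practice (multiple, scattered C sites per sgRNA).
#'
#' @param seed Integer seed for the flank filler (default 101).
#' @param n_sites Number of sites, up to 9 (default 9).
#' @return Named list of [target_site()] objects.
#' @export
window_panel_sites <- function(seed = 101L, n_sites = 9L) {
  layouts <- list(c(4, 9, 14), c(5, 10, 1), c(6, 11, 2), c(7, 12, 3),
                  c(8, 13, 1), c(4, 6, 10), c(5, 7, 12), c(6, 8, 14),
                  c(4, 8, 11))
  n_sites <- min(as.integer(n_sites), length(layouts))
  sites <- lapply(seq_len(n_sites), function(i) {
    proto <- design_protospacer(layouts[[i]], seed = derive_seed(seed, i))
    synth_target_site(sprintf("win_sg%02d", i), proto,
                      seed = derive_seed(seed, 100L + i))
  })
  stats::setNames(sites, vapply(sites, `[[`, character(1), "site_id"))
}

#' sgRNA panel for substrate-preference analysis
#'
#' Five target sites, each carrying exactly one protospacer C per upstream
#' dinucleotide context (AC, CC, GC, TC) within positions 1-14 — the CC
#' context is realized as an `ACC` run so its leading C is the AC site — so
#' the pooled panel provides five sites per context in a balanced layout.
#'
#' @param seed Integer seed for the flank filler (default 202).
#' @return Named list of [target_site()] objects.
#' @export
preference_panel_sites <- function(seed = 202L) {
  # (AC position, GC position, TC position); CC sits at AC position + 1
  layouts <- list(c(ac = 4, gc = 10, tc = 14),
                  c(ac = 7, gc = 2, tc = 12),
                  c(ac = 11, gc = 5, tc = 2),
                  c(ac = 2, gc = 8, tc = 13),
                  c(ac = 9, gc = 13, tc = 5))
  sites <- lapply(seq_along(layouts), function(i) {
    lay <- layouts[[i]]
    c_at <- c(lay[["ac"]], lay[["ac"]] + 1L, lay[["gc"]], lay[["tc"]])
    up <- c("A", NA, "G", "T")  # the CC site's upstream C is c_at[1] itself
    proto <- design_protospacer(c_at, upstream_base = up,
                                seed = derive_seed(seed, i))
    synth_target_site(sprintf("pref_sg%02d", i), proto,
                      seed = derive_seed(seed, 100L + i))
  })
  stats::setNames(sites, vapply(sites, `[[`, character(1), "site_id"))
}

#' On/off-target site pair for specificity analysis
#'
#' One on-target site and `n_off` off-target sites sharing the protospacer C
#' layout (as imperfectly matched protospacers, each with its own amplicon),
#' plus the pairing table.
#'
#' @param seed Integer seed (default 303).
#' @param n_off Number of off-target sites (default 2).
#' @return List with `sites` (named list of [target_site()]) and `pairs`
#'   (data frame `on_site_id`, `off_site_id`).
#' @export
specificity_panel_sites <- function(seed = 303L, n_off = 2L) {
  on <- synth_target_site(
    "on_target", design_protospacer(c(5, 8, 12), seed = derive_seed(seed, 1L)),
    seed = derive_seed(seed, 101L))
  offs <- lapply(seq_len(n_off), function(i) {
    synth_target_site(
      sprintf("off_target%02d", i),
      design_protospacer(c(5, 8, 12), seed = derive_seed(seed, 1L + i)),
      seed = derive_seed(seed, 101L + i))
  })
  sites <- c(list(on), offs)
  names(sites) <- vapply(sites, `[[`, character(1), "site_id")
  list(sites = sites,
       pairs = data.frame(on_site_id = "on_target",
                          off_site_id = names(sites)[-1],
                          stringsAsFactors = FALSE))
}
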