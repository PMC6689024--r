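# Protospacer coordinate system and quantification window.
#
# Positions on the protospacer strand are numbered 1..protospacer_len 5'->3',
# the PAM occupies protospacer_len+1 .. protospacer_len+pam_len (21..23 for
# SpCas9 defaults), positions downstream of the PAM continue 24, 25, ... and
# positions upstream of the protospacer are -1, -2, ... with -1 immediately
# 5' of position 1. There is no position 0.

# internal: signed protospacer position <-> contiguous 0-based offset along
# the protospacer strand (offset 0 == position 1, offset -1 == position -1)
cp_to_offset <- function(cp) {
  cp <- as.integer(cp)
  if (any(cp == 0L)) stop("invalid protospacer position: 0 (no position 0 exists)")
  ifelse(cp > 0L, cp - 1L, cp)
}

offset_to_cp <- function(off) {
  off <- as.integer(off)
  ifelse(off >= 0L, off + 1L, off)
}

#' Construct a target site
#'
#' A target site couples an amplicon reference sequence with an annotated
#' protospacer/PAM and fixes the coordinate map between 0-based amplicon
#' indices and signed protospacer positions. All downstream quantification is
#' reported on the protospacer strand: for a site annotated on the `-` strand
#' a C->T event in protospacer coordinates is a G->A event on the amplicon
#' forward strand.
#'
#' @param site_id Character scalar identifying the site.
#' @param amplicon_seq Amplicon reference sequence (A/C/G/T only; IUPAC
#'   ambiguity codes are rejected).
#' @param protospacer_start 0-based index on the amplicon forward strand of
#'   protospacer position 1.
#' @param strand `"+"` or `"-"`: orientation of the protospacer on the
#'   amplicon.
#' @param pam_len PAM length in nt (default 3, SpCas9 NGG).
#' @param protospacer_len Protospacer length in nt (default 20).
#' @param window_upstream,window_downstream Extent of the quantification
#'   window: `window_upstream` nt 5' of the PAM start through
#'   `window_downstream` nt 3' of the PAM end (defaults 30 and 10, i.e. a
#'   43-bp window for the SpCas9 defaults).
#' @return An object of class `target_site`.
#' @export
target_site <- function(site_id, amplicon_seq, protospacer_start,
                        strand = c("+", "-"), pam_len = 3L,
                        protospacer_len = 20L,
                        window_upstream = 30L, window_downstream = 10L) {
  strand <- match.arg(strand)
  stopifnot(is.character(site_id), length(site_id) == 1L, nzchar(site_id))
  amplicon_seq <- toupper(as.character(amplicon_seq))
  if (grepl("[^ACGT]", amplicon_seq)) {
    stop("amplicon_seq for site '", site_id,
         "' contains characters other than A/C/G/T (ambiguity codes are rejected)")
  }
  pam_len <- as.integer(pam_len)
  protospacer_len <- as.integer(protospacer_len)
  if (pam_len < 1L || protospacer_len < 1L) {
    stop("pam_len and protospacer_len must both be >= 1")
  }
  site <- structure(
    list(site_id = site_id,
         amplicon_seq = amplicon_seq,
         protospacer_start = as.integer(protospacer_start),
         strand = strand,
         pam_len = pam_len,
         protospacer_len = protospacer_len,
         window_upstream = as.integer(window_upstream),
         window_downstream = as.integer(window_downstream)),
    class = "target_site")
  # the full quantification window must fit on the amplicon
  win <- quantification_window(site)
  invisible(vapply(win, function(cp) cp_to_amplicon_index(site, cp), integer(1)))
  site
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("target_site '%s': %d-bp amplicon, protospacer %d nt at index %d (%s strand), PAM %d nt\n",
              x$site_id, nchar(x$amplicon_seq), x$protospacer_len,
              x$protospacer_start, x$strand, x$pam_len))
  invisible(x)
}

#' Quantification window positions
#'
#' Returns every protospacer position from `window_upstream` nt upstream of
#' the PAM 5' end through `window_downstream` nt downstream of the PAM 3'
#' end, in 5'->3' protospacer order. For the SpCas9 defaults (20-nt
#' protospacer, 3-nt PAM, 30 nt up / 10 nt down) this is the 43 positions
#' -10..-1, 1..33.
#'
#' @param site A [target_site()].
#' @return Integer vector of signed protospacer positions.
#' @export
quantification_window <- function(site) {
  stopifnot(inherits(site, "target_site"))
  pam_start_off <- site$protospacer_len            # offset of PAM 5' base
  offs <- seq.int(pam_start_off - site$window_upstream,
                  pam_start_off + site$pam_len + site$window_downstream - 1L)
  offset_to_cp(offs)
}

#' Map a protospacer position to a 0-based amplicon index
#'
#' Position 1 maps to `protospacer_start`; consecutive positions (skipping 0)
#' map to consecutive indices, increasing along the amplicon forward strand
#' for `+` sites and decreasing for `-` sites so that positions always
#' increase 5'->3' along the protospacer strand.
#'
#' @param site A [target_site()].
#' @param cp Signed protospacer position(s); 0 is invalid.
#' @return Integer 0-based amplicon index (vectorized over `cp`).
#' @export
cp_to_amplicon_index <- function(site, cp) {
  stopifnot(inherits(site, "target_site"))
  off <- cp_to_offset(cp)
  idx <- if (site$strand == "+") site$protospacer_start + off
         else site$protospacer_start - off
  bad <- idx < 0L | idx >= nchar(site$amplicon_seq)
  if (any(bad)) {
    stop(sprintf("position %d of site '%s' falls outside the amplicon (index %d, amplicon length %d)",
                 cp[bad][1], site$site_id, idx[bad][1], nchar(site$amplicon_seq)))
  }
  as.integer(idx)
}

#' Map a 0-based amplicon index back to a protospacer position
#'
#' Inverse of [cp_to_amplicon_index()].
#'
#' @inheritParams cp_to_amplicon_index
#' @param index 0-based amplicon index (vectorized).
#' @return Integer signed protospacer position.
#' @export
amplicon_index_to_cp <- function(site, index) {
  stopifnot(inherits(site, "target_site"))
  index <- as.integer(index)
  if (any(index < 0L | index >= nchar(site$amplicon_seq))) {
    stop("amplicon index outside amplicon bounds for site '", site$site_id, "'")
  }
  off <- if (site$strand == "+") index - site$protospacer_start
         else site$protospacer_start - index
  offset_to_cp(off)
}

# internal: base(s) at protospacer position(s), read on the protospacer strand
protospacer_base <- function(site, cp) {
  idx <- cp_to_amplicon_index(site, cp)
  b <- substring(site$amplicon_seq, idx + 1L, idx + 1L)
  if (site$strand == "-") b <- chartr("ACGT", "TGCA", b)
  b
}

#' Reference bases across the quantification window
#'
#' @param site A [target_site()].
#' @return Named character vector of protospacer-strand reference bases, one
#'   per window position; names are the signed positions.
#' @export
window_ref_bases <- function(site) {
  win <- quantification_window(site)
  stats::setNames(protospacer_base(site, win), win)
}

#' Dinucleotide sequence context of a cytosine
#'
#' Returns the upstream (`NC`: the base 5' of the edited C, then C) and
#' downstream (`CN`: C, then the base 3') dinucleotides, both read on the
#' protospacer strand. The position must carry a reference C on the
#' protospacer strand.
#'
#' @param site A [target_site()].
#' @param cp Signed protospacer position of the cytosine.
#' @return A list of class `sequence_context` with elements `upstream_di` and
#'   `downstream_di`.
#' @export
context_at <- function(site, cp) {
  stopifnot(inherits(site, "target_site"), length(cp) == 1L)
  base <- protospacer_base(site, cp)
  if (base != "C") {
    stop(sprintf("position %d of site '%s' is not a C on the protospacer strand (found %s)",
                 as.integer(cp), site$site_id, base))
  }
  off <- cp_to_offset(cp)
  up <- protospacer_base(site, offset_to_cp(off - 1L))
  dn <- protospacer_base(site, offset_to_cp(off + 1L))
  structure(list(upstream_di = paste0(up, "C"), downstream_di = paste0("C", dn)),
            class = "sequence_context")
}

#' Read target-site annotations from TSV + FASTA
#'
#' The annotation TSV must have columns `site_id`, `fasta_id`,
#' `protospacer_seq`, `pam_seq`, `strand`. Each protospacer is located in its
#' FASTA record by exact match (on the forward strand for `+` sites, of its
#' reverse complement for `-` sites); zero or multiple matches are an error.
#' The PAM annotation (IUPAC codes allowed, e.g. `NGG`) is checked against
#' the located PAM.
#'
#' @param tsv_path Path to the annotation TSV.
#' @param fasta_path Path to the multi-record amplicon FASTA.
#' @param ... Further arguments passed to [target_site()] (e.g. window size).
#' @return Named list of [target_site()] objects.
#' @export
read_sites <- function(tsv_path, fasta_path, ...) {
  ann <- read_tsv_file(tsv_path)
  need <- c("site_id", "fasta_id", "protospacer_seq", "pam_seq", "strand")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols)) {
    stop("site annotation file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  refs <- read_fasta(fasta_path)
  sites <- lapply(seq_len(nrow(ann)), function(i) {
    row <- ann[i, ]
    if (!row$fasta_id %in% names(refs)) {
      stop("FASTA record '", row$fasta_id, "' (site '", row$site_id, "') not found")
    }
    amp <- refs[[row$fasta_id]]
    proto <- toupper(row$protospacer_seq)
    query <- if (row$strand == "+") proto else revcomp(proto)
    hits <- gregexpr(query, amp, fixed = TRUE)[[1]]
    hits <- hits[hits > 0L]
    if (length(hits) != 1L) {
      stop(sprintf("protospacer of site '%s' matches amplicon '%s' %d times (need exactly 1)",
                   row$site_id, row$fasta_id, length(hits)))
    }
    plen <- nchar(proto)
    pam_len <- nchar(row$pam_seq)
    if (row$strand == "+") {
      ps_start <- as.integer(hits - 1L)
      pam_obs <- substr(amp, hits + plen, hits + plen + pam_len - 1L)
    } else {
      ps_start <- as.integer(hits - 1L + plen - 1L)
      pam_obs <- revcomp(substr(amp, hits - pam_len, hits - 1L))
    }
    if (!iupac_match(row$pam_seq, pam_obs)) {
      stop(sprintf("PAM mismatch at site '%s': annotated %s, found %s",
                   row$site_id, row$pam_seq, pam_obs))
    }
    target_site(site_id = row$site_id, amplicon_seq = amp,
                protospacer_start = ps_start, strand = row$strand,
                pam_len = pam_len, protospacer_len = plen, ...)
  })
  stats::setNames(sites, ann$site_id)
}

# internal: does observed sequence match an IUPAC pattern of equal length?
iupac_match <- function(pattern, observed) {
  pattern <- toupper(pattern); observed <- toupper(observed)
  if (nchar(pattern) != nchar(observed)) return(FALSE)
  codes <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
             W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
             V = "ACG", N = "ACGT")
  p <- strsplit(pattern, "")[[1]]
  o <- strsplit(observed, "")[[1]]
  all(mapply(function(pc, oc) grepl(oc, codes[[pc]], fixed = TRUE), p, o))
}
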