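# Shared fixtures, all built in code: a small deterministic target site and
# a convenience constructor for hand-laid-out amplicons.

# site with known protospacer C layout (positions 4, 6, 9, 12)
fixture_site <- function(strand = "+") {
  bescope:::synth_target_site(
    "fix1", bescope:::design_protospacer(c(4, 6, 9, 12), seed = 5),
    seed = 7, strand = strand)
}

# target site from an explicit amplicon laid out as flank5 | proto | pam | flank3
manual_site <- function(proto, flank5, flank3, pam = "AGG", strand = "+",
                        id = "manual") {
  amp <- paste0(flank5, proto, pam, flank3)
  if (strand == "+") {
    target_site(id, amp, nchar(flank5), strand = "+")
  } else {
    ramp <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(amp)))
    target_site(id, ramp, nchar(amp) - 1L - nchar(flank5), strand = "-")
  }
}

# uniform-quality read data frame
make_reads <- function(seqs, q = 37L, ids = NULL) {
  data.frame(
    id = if (is.null(ids)) sprintf("r%03d", seq_along(seqs)) else ids,
    seq = seqs,
    qual = vapply(nchar(seqs), function(n) strrep(intToUtf8(q + 33L), n),
                  character(1)),
    stringsAsFactors = FALSE)
}
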