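test_that("quantification window has the expected extent and length", {
  site <- fixture_site()
  win <- quantification_window(site)
  expect_length(win, 43L)
  expect_identical(win[1], -10L)
  expect_identical(win[length(win)], 33L)
  expect_false(any(win == 0L))

  # window length is 30 + pam_len + 10 for any PAM length; a 4-nt PAM site
  # has 44 positions (counted by enumeration: 30 upstream + 4 + 10 downstream)
  amp <- paste0(strrep("A", 45), strrep("G", 59))
  site4 <- target_site("pam4", amp, 45, pam_len = 4L)
  expect_length(quantification_window(site4), 44L)
  for (pl in c(1L, 2L, 5L)) {
    s <- target_site("pamN", amp, 45, pam_len = pl)
    expect_length(quantification_window(s), 30L + pl + 10L)
  }
})

test_that("position-to-index mapping follows the no-zero convention", {
  amp <- paste0(strrep("A", 50), strrep("G", 60))
  site <- target_site("m", amp, 50)
  expect_identical(cp_to_amplicon_index(site, 1), 50L)
  expect_identical(cp_to_amplicon_index(site, -1), 49L)  # no position 0
  # 20 protospacer bases then the PAM start: enumerate 1..20 -> 50..69, 21 -> 70
  expect_identical(cp_to_amplicon_index(site, 21), 70L)
  expect_error(cp_to_amplicon_index(site, 0), "position 0")
  expect_error(cp_to_amplicon_index(site, 10000), "outside the amplicon")
})

test_that("index mapping round-trips across the window on both strands", {
  for (strand in c("+", "-")) {
    site <- fixture_site(strand)
    win <- quantification_window(site)
    idx <- vapply(win, function(p) cp_to_amplicon_index(site, p), integer(1))
    expect_false(any(duplicated(idx)))  # bijective over the window
    expect_identical(amplicon_index_to_cp(site, idx), win)
  }
})

test_that("dinucleotide contexts are read on the protospacer strand", {
  # protospacer ...TACG...: the C at position 5 has upstream AC, downstream CG
  proto <- "GGTACGTTAGTTAGTTAGTT"
  site <- manual_site(proto, strrep("A", 40), strrep("G", 40))
  ctx <- context_at(site, 5)
  expect_identical(ctx$upstream_di, "AC")
  expect_identical(ctx$downstream_di, "CG")

  # the same double-stranded locus annotated on the minus strand gives the
  # same protospacer-strand contexts
  site_m <- manual_site(proto, strrep("A", 40), strrep("G", 40), strand = "-")
  ctx_m <- context_at(site_m, 5)
  expect_identical(ctx_m$upstream_di, "AC")
  expect_identical(ctx_m$downstream_di, "CG")

  expect_error(context_at(site, 4), "not a C")
})

test_that("context multisets agree between strand annotations of one locus", {
  layouts <- list(c(2, 5, 9, 13), c(3, 6, 10, 14), c(4, 7, 11, 12),
                  c(2, 8, 13, 14), c(5, 6, 7, 8))
  for (seed in seq_along(layouts)) {
    proto <- bescope:::design_protospacer(layouts[[seed]], seed = seed)
    sp <- manual_site(proto, strrep("A", 40), strrep("G", 40))
    sm <- manual_site(proto, strrep("A", 40), strrep("G", 40), strand = "-")
    cs <- which(strsplit(proto, "")[[1]] == "C")
    up_p <- vapply(cs, function(p) context_at(sp, p)$upstream_di, character(1))
    up_m <- vapply(cs, function(p) context_at(sm, p)$upstream_di, character(1))
    expect_identical(sort(up_p), sort(up_m))
  }
})

test_that("invalid sites are rejected", {
  expect_error(target_site("bad", "ACGTNACGT", 2), "A/C/G/T")
  expect_error(target_site("bad", "ACGT", 0), "outside the amplicon")
  expect_error(target_site("bad", strrep("A", 200), 50, pam_len = 0),
               ">= 1")
})

test_that("site annotations load from TSV + FASTA with exact-match location", {
  site <- fixture_site()
  proto <- substr(site$amplicon_seq, site$protospacer_start + 1L,
                  site$protospacer_start + 20L)
  fa <- file.path(tempdir(), "sites.fa")
  tsv <- file.path(tempdir(), "sites.tsv")
  write_fasta(stats::setNames(site$amplicon_seq, "amp1"), fa)
  write_tsv_file(data.frame(site_id = "s1", fasta_id = "amp1",
                            protospacer_seq = proto, pam_seq = "NGG",
                            strand = "+", stringsAsFactors = FALSE), tsv)
  sites <- read_sites(tsv, fa)
  expect_length(sites, 1L)
  expect_identical(sites$s1$protospacer_start, site$protospacer_start)
  expect_identical(window_ref_bases(sites$s1), window_ref_bases(site))

  # a protospacer absent from the record is an error
  write_tsv_file(data.frame(site_id = "s1", fasta_id = "amp1",
                            protospacer_seq = strrep("T", 20), pam_seq = "NGG",
                            strand = "+", stringsAsFactors = FALSE), tsv)
  expect_error(read_sites(tsv, fa), "matches amplicon")
})
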