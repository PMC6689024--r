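test_that("demultiplexing assigns by exact prefix and conserves counts", {
  reads <- make_reads(c("ACGTAAAA", "ACGTCCCC", "TTTTGGGG", "GGGGAAAA"))
  dm <- demultiplex(reads, c(ACGT = "s1", TTTT = "s2"))
  expect_identical(nrow(dm$samples$s1), 2L)
  expect_identical(nrow(dm$samples$s2), 1L)
  expect_identical(dm$unassigned, 1L)
  # barcode is stripped from sequence and quality
  expect_identical(dm$samples$s1$seq, c("AAAA", "CCCC"))
  expect_identical(nchar(dm$samples$s1$qual), c(4L, 4L))
  # conservation: assigned + unassigned = input
  expect_identical(sum(vapply(dm$samples, nrow, integer(1))) + dm$unassigned,
                   nrow(reads))
  # degenerate map: everything passes through under one default sample
  dm0 <- demultiplex(reads, character(0))
  expect_identical(dm0$samples$default, reads)
  expect_identical(dm0$unassigned, 0L)
  expect_error(demultiplex(reads, c(ACGT = "s1", ACGT = "s2")), "duplicate")
  expect_error(demultiplex(reads, c(ACGT = "s1", TT = "s2")), "equal length")
})

test_that("quality trimming removes sub-threshold 3' bases", {
  q37 <- intToUtf8(37L + 33L); q2 <- intToUtf8(2L + 33L)
  reads <- data.frame(
    id = c("a", "b", "c"),
    seq = c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC"),
    qual = c(strrep(q37, 10),
             paste0(strrep(q37, 5), strrep(q2, 5)),
             strrep(q2, 10)),
    stringsAsFactors = FALSE)
  out <- quality_trim(reads, q_min = 15L)
  expect_identical(out$seq, c("ACGTACGTAC", "ACGTA", ""))
  expect_identical(nchar(out$qual), nchar(out$seq))
  # an interior low-quality base survives (trimming is 3'-anchored)
  r <- data.frame(id = "d", seq = "ACGTACGTAC",
                  qual = paste0(strrep(q37, 2), q2, strrep(q37, 7)),
                  stringsAsFactors = FALSE)
  expect_identical(quality_trim(r)$seq, "ACGTACGTAC")
  bad <- data.frame(id = "e", seq = "ACGT", qual = "!!!", stringsAsFactors = FALSE)
  expect_error(quality_trim(bad), "lengths differ")
})

test_that("reads place by unique seed match on either strand", {
  site <- fixture_site()
  amp <- site$amplicon_seq
  sub <- substr(amp, 8, 8 + 39)  # exact 40-mer at 0-based offset 7
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  reads <- make_reads(c(sub, rc, strrep("A", 40)))
  pl <- place_reads(reads, site)
  expect_identical(pl$stats[["placed"]], 2L)
  expect_identical(pl$stats[["unplaced"]], 1L)
  expect_identical(pl$placed$offset, c(7L, 7L))  # both in forward orientation
  expect_identical(pl$placed$seq[2], sub)

  # mismatch fraction above the cap rejects the placement
  noisy <- paste0(substr(sub, 1, 20), strrep("A", 20))
  frac_mm <- mean(strsplit(noisy, "")[[1]] != strsplit(sub, "")[[1]])
  stopifnot(frac_mm > 0.2)
  pl2 <- place_reads(make_reads(noisy), site)
  expect_identical(pl2$stats[["placed"]], 0L)

  # an ambiguous seed (two placements) discards the read
  amp2 <- paste0(strrep("A", 25), strrep("G", 60), strrep("A", 25))
  site2 <- target_site("amb", amp2, 40)
  pl3 <- place_reads(make_reads(strrep("A", 25)), site2)
  expect_identical(pl3$stats[["ambiguous"]], 1L)
})

test_that("tabulation counts observed bases and computes frequencies", {
  site <- fixture_site()
  win_start_idx <- cp_to_amplicon_index(site, -10)
  # reads carry a 25-nt 5' flank (clean placement seed) and stop at position
  # 28, leaving the tail of the window uncovered
  full <- substr(site$amplicon_seq, win_start_idx + 1 - 25,
                 cp_to_amplicon_index(site, 28) + 1)
  # 80 reference reads + 20 reads carrying C->T at position 4
  idx4 <- cp_to_amplicon_index(site, 4)
  pos4 <- idx4 - (win_start_idx - 25) + 1
  edited <- full
  substr(edited, pos4, pos4) <- "T"
  reads <- make_reads(c(rep(full, 80), rep(edited, 20)))
  tab <- quantify_sample(reads, site)$table
  expect_identical(unname(tab$depth[tab$cp == 4]), 100L)
  # Frequency = base conversion reads / total reads = 20/100
  expect_equal(conversion_frequency(tab, 4), 0.2)
  expect_equal(conversion_frequency(tab, 6), 0)
  # positions outside read coverage have depth 0 and a missing frequency
  expect_identical(unname(tab$depth[tab$cp == 33]), 0L)
  f33 <- conversion_frequency(tab, 33)
  expect_true(is.na(f33))
  expect_identical(attr(f33, "status"), "no_coverage")
  # querying a non-C reference position for a C conversion is not applicable
  f5 <- conversion_frequency(tab, 5)
  expect_identical(attr(f5, "status"), "not_applicable")
  expect_error(conversion_frequency(tab, 99), "outside the quantification window")
})

test_that("quantification is invariant to the annotated strand", {
  prof <- make_profile_library()$forward
  site_p <- fixture_site("+")
  site_m <- fixture_site("-")
  sim <- simulate_reads(site_p, prof, 3000, seed = 13)
  tp <- quantify_sample(sim$reads, site_p)$table
  tm <- quantify_sample(sim$reads, site_m)$table
  cols <- c("cp", "ref_base", "A", "C", "G", "T", "depth")
  expect_identical(tp[, cols], tm[, cols])
})

test_that("simulate -> quantify recovers the expected frequency at every C", {
  site <- fixture_site()
  prof <- make_profile_library()$forward
  sim <- simulate_reads(site, prof, 20000, seed = 17)
  q <- quantify_sample(sim$reads, site)
  obs <- conversion_frequencies(q$table)
  depth <- stats::setNames(q$table$depth[q$table$ref_base == "C"],
                           q$table$cp[q$table$ref_base == "C"])
  for (i in seq_len(nrow(sim$truth))) {
    cp <- as.character(sim$truth$cp[i])
    exp_f <- sim$truth$expected_freq[i]
    sd <- sqrt(max(exp_f * (1 - exp_f), 1e-12) / depth[[cp]])
    expect_lt(abs(obs[[cp]] - exp_f), 4 * sd)
  }
})

test_that("conversion tables round-trip through TSV", {
  site <- fixture_site()
  prof <- make_profile_library()$forward
  sim <- simulate_reads(site, prof, 500, seed = 19)
  tab <- quantify_sample(sim$reads, site)$table
  path <- file.path(tempdir(), "conv.tsv")
  write_conversion_table(tab, path, sample_id = "sampleA")
  back <- read_conversion_table(path)
  expect_identical(back$sample_id[1], "sampleA")
  expect_identical(back$cp, tab$cp)
  expect_identical(back$depth, tab$depth)
  isc <- tab$ref_base == "C" & tab$depth > 0
  expect_equal(back$freq_C_to_T[isc], tab$T[isc] / tab$depth[isc])
  expect_true(all(is.na(back$freq_C_to_T[!isc])))
})
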