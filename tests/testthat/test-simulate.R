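test_that("expected T frequency follows the closed form", {
  site <- fixture_site()
  # q = 0, e = 0: nothing to observe but the reference C
  prof0 <- editor_profile("p0", c(`4` = 0), seq_error = 0)
  expect_identical(expected_t_frequency(prof0, site, 4), 0)
  # q = 1, e = 0: every read shows T
  prof1 <- editor_profile("p1", c(`4` = 1), seq_error = 0)
  expect_identical(expected_t_frequency(prof1, site, 4), 1)
  # q = 0.5, e = 0.003: 0.5 * 0.997 + 0.5 * 0.001 = 0.499 exactly
  prof <- editor_profile("p", c(`4` = 0.5), seq_error = 0.003)
  expect_equal(expected_t_frequency(prof, site, 4), 0.499, tolerance = 1e-12)
  expect_error(expected_t_frequency(prof, site, 5), "not a C")
})

test_that("closed form agrees with a Monte-Carlo oracle", {
  # direct simulation of the generative model at one position, independent of
  # the read machinery: edit with probability q, then substitute uniformly
  q <- 0.5; e <- 0.003; n <- 4e5
  set.seed(99)
  base <- ifelse(stats::runif(n) < q, "T", "C")
  err <- stats::runif(n) < e
  base[err] <- vapply(base[err], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  mc <- mean(base == "T")
  site <- fixture_site()
  prof <- editor_profile("p", c(`4` = q), seq_error = e)
  expect_lt(abs(expected_t_frequency(prof, site, 4) - mc),
            4 * sqrt(0.25 / n))
})

test_that("context multipliers scale the editing probability with clipping", {
  site <- fixture_site()
  # position 6 of the fixture has upstream TC (see design)
  up6 <- context_at(site, 6)$upstream_di
  prof <- editor_profile("p", c(`6` = 0.4),
                         context_mult = stats::setNames(2, up6), seq_error = 0)
  expect_equal(expected_t_frequency(prof, site, 6), 0.8)
  prof_clip <- editor_profile("p", c(`6` = 0.8),
                              context_mult = stats::setNames(2, up6),
                              seq_error = 0)
  expect_equal(expected_t_frequency(prof_clip, site, 6), 1)  # clipped at 1
  sim <- simulate_reads(site, prof_clip, 10, seed = 1)
  expect_gte(sim$clipped_events, 1L)
})

test_that("simulation is byte-deterministic and honours n_reads = 0", {
  site <- fixture_site()
  prof <- make_profile_library()$forward
  s1 <- simulate_reads(site, prof, 200, seed = 11)
  s2 <- simulate_reads(site, prof, 200, seed = 11)
  expect_identical(s1, s2)
  f1 <- file.path(tempdir(), "a.fastq"); f2 <- file.path(tempdir(), "b.fastq")
  write_fastq(s1$reads, f1); write_fastq(s2$reads, f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  s3 <- simulate_reads(site, prof, 200, seed = 12)
  expect_false(identical(s1$reads$seq, s3$reads$seq))

  s0 <- simulate_reads(site, prof, 0, seed = 11)
  expect_identical(nrow(s0$reads), 0L)
  expect_true(all(s0$truth$n_reads == 0L))
})

test_that("observed T fraction matches the editing probability binomially", {
  site <- fixture_site()
  prof <- editor_profile("p", c(`4` = 0.5), seq_error = 0)
  sim <- simulate_reads(site, prof, 10000, seed = 21)
  # reads start 25 nt 5' of the window start; position of cp 4 within a read
  read_start_off <- bescope:::cp_to_offset(quantification_window(site)[1]) - 25L
  pos <- bescope:::cp_to_offset(4L) - read_start_off + 1L
  tfrac <- mean(substr(sim$reads$seq, pos, pos) == "T")
  expect_lt(abs(tfrac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("non-C positions show T at the sequencing-error floor", {
  site <- fixture_site()
  prof <- editor_profile("p", c(`4` = 0.5), seq_error = 0.01)
  sim <- simulate_reads(site, prof, 20000, seed = 31)
  tab <- quantify_sample(sim$reads, site)$table
  nonc <- tab[tab$ref_base %in% c("A", "G"), ]
  tfreq <- sum(nonc$T) / sum(nonc$depth)
  floor <- 0.01 / 3
  expect_lt(abs(tfreq - floor),
            4 * sqrt(floor * (1 - floor) / sum(nonc$depth)))
})

test_that("profile archetypes have the documented supports and preferences", {
  lib <- make_profile_library()
  sup <- function(p) sort(as.integer(names(p$p_edit)[p$p_edit > 0]))
  expect_true(all(sup(lib$forward) %in% 1:8))
  expect_true(all(sup(lib$backward) %in% 9:13))
  expect_true(all(sup(lib$broad) %in% 1:14))
  expect_lt(lib$gc_averse$context_mult[["GC"]],
            lib$gc_averse$context_mult[["TC"]])
  expect_error(editor_profile("bad", c(`4` = 0.5), seq_error = 0.3), "0.25")
  expect_error(editor_profile("bad", c(`4` = 1.5)), "\\[0, 1\\]")
})

test_that("count-level simulation matches the read-level distribution", {
  site <- fixture_site()
  prof <- make_profile_library()$forward
  tab_c <- simulate_site_counts(site, prof, 20000, seed = 41)
  expect_true(all(tab_c$depth == 20000))
  expect_true(all(tab_c$A + tab_c$C + tab_c$G + tab_c$T == tab_c$depth))
  f <- conversion_frequencies(tab_c)
  for (p in c(4, 6)) {
    exp_f <- expected_t_frequency(prof, site, p)
    expect_lt(abs(f[as.character(p)] - exp_f),
              4 * sqrt(exp_f * (1 - exp_f) / 20000))
  }
})
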