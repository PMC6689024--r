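#!/usr/bin/env Rscript
# Substrate-preference analysis: does an editor favour particular bases
# immediately 5' (NC) or 3' (CN) of the edited cytosine? High-activity C
# sites (normalized frequency >= 0.8 at the position class) are grouped by
# context and compared by one-way ANOVA. Uses a context-balanced 5-sgRNA
# panel so every upstream dinucleotide is represented equally.

suppressMessages(library(bescope))

seed <- 20260926L
n_reads <- 10000L
out_dir <- "results/04_preference"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

sites <- preference_panel_sites(seed = seed)
profiles <- make_profile_library()[c("broad", "gc_averse")]

for (ed in names(profiles)) {
  site_tables <- lapply(seq_along(sites), function(j) {
    sim <- simulate_reads(sites[[j]], profiles[[ed]], n_reads,
                          seed = bescope:::derive_seed(seed, 100L + j))
    tab <- quantify_sample(sim$reads, sites[[j]])$table
    site_context_table(sites[[j]],
                       normalize_sgrna(conversion_frequencies(tab)))
  })
  res <- analyze_preference(site_tables, editor_id = ed)
  write_preference_result(res, file.path(out_dir, sprintf("preference_%s.tsv", ed)))
  up <- res$upstream
  cat(sprintf("%-10s upstream: F = %.2f, p = %.3g -> %s\n",
              ed, up$F, up$p, up$ordering))
}
cat(sprintf("preference results -> %s\n", out_dir))
cat("expected: the GC-averse editor ranks GC last with p << 0.05 and a clear\n")
cat("GC tier break; the context-neutral broad editor's means collapse into a\n")
cat("single tier (within the 0.05 tie tolerance), with rejections only at\n")
cat("about the nominal 5% rate.\n")
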