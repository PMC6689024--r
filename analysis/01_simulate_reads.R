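#!/usr/bin/env Rscript
# Simulate multiplexed amplicon sequencing for four editor archetypes over a
# 9-sgRNA panel, writing FASTQ + ground-truth tables under results/.
#
# The archetypes mimic the canonical editing-window shapes of characterized
# cytosine base editors: forward-shifted (positions 1-8), backward-shifted
# (9-13), broad-range (1-14), and a broad editor with a strongly disfavoured
# GC upstream context.

suppressMessages(library(bescope))

seed <- 20260926L
n_reads <- 10000L
# raw reads are bulky intermediates: they go under scratch/, only the small
# reference/truth tables and downstream results live under results/
out_dir <- "scratch/01_simulated"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

sites <- bescope:::window_panel_sites(seed = seed)
profiles <- make_profile_library()

# persist the references so later stages re-load them from disk
write_fasta(vapply(sites, `[[`, character(1), "amplicon_seq"),
            file.path(out_dir, "amplicons.fasta"))
ann <- do.call(rbind, lapply(sites, function(s) {
  data.frame(site_id = s$site_id, fasta_id = s$site_id,
             protospacer_seq = substr(s$amplicon_seq, s$protospacer_start + 1,
                                      s$protospacer_start + s$protospacer_len),
             pam_seq = "NGG", strand = s$strand, stringsAsFactors = FALSE)
}))
write_tsv_file(ann, file.path(out_dir, "sites.tsv"))

k <- 0L
truth_all <- list()
for (ed in names(profiles)) {
  for (sid in names(sites)) {
    k <- k + 1L
    sim <- simulate_reads(sites[[sid]], profiles[[ed]], n_reads,
                          seed = bescope:::derive_seed(seed, k))
    write_fastq(sim$reads, file.path(out_dir, sprintf("%s_%s.fastq", ed, sid)))
    truth_all[[k]] <- sim$truth
    truth_all[[k]]$editor_id <- ed
  }
}
write_truth(do.call(rbind, truth_all), file.path(out_dir, "truth.tsv"))

cat(sprintf("simulated %d samples x %d reads (%d editors, %d sgRNAs) -> %s\n",
            k, n_reads, length(profiles), length(sites), out_dir))
cat("reads span the 43-bp quantification window plus flanks; ground truth\n")
cat("records the closed-form expected T frequency at every reference C.\n")
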