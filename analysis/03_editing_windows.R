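#!/usr/bin/env Rscript
# Editing-window analysis per editor: per-sgRNA normalization, editing scope
# (raw frequency >= 0.40), comprehensive editing window (mean normalized
# efficiency > 0.6) and FSCBE / BSCBE / BRCBE classification.

suppressMessages(library(bescope))

in_dir <- "results/02_tables"
out_dir <- "results/03_windows"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

files <- list.files(in_dir, pattern = "\\.tsv$", full.names = TRUE)
tabs <- lapply(files, read_conversion_table)
editors <- unique(vapply(tabs, function(t) t$sample_id[1], character(1)))

for (ed in editors) {
  sel <- which(vapply(tabs, function(t) t$sample_id[1] == ed, logical(1)))
  freq_maps <- lapply(tabs[sel], function(t) {
    stats::setNames(t$freq_C_to_T[t$ref_base == "C"], t$cp[t$ref_base == "C"])
  })
  names(freq_maps) <- vapply(tabs[sel], function(t) t$site_id[1], character(1))
  wr <- analyze_windows(freq_maps, editor_id = ed)
  write_window_result(wr, file.path(out_dir, sprintf("windows_%s.tsv", ed)))
  cat(sprintf("%-10s CEW {%s} over %d sgRNAs -> class %s\n",
              ed, paste(wr$cew, collapse = ","), wr$n_sgrnas, wr$class_label))
}
cat(sprintf("window results -> %s\n", out_dir))
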