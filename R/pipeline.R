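# End-to-end driver: simulate -> demultiplex -> quantify -> windows ->
# preference -> specificity, with one master seed, a threshold manifest and
# deterministic TSV outputs.

#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' All randomness downstream flows from `seed`; per-stage seeds are derived
#' deterministically from it.
#'
#' @param sites Named list of [target_site()] objects.
#' @param profiles Named list of [editor_profile()] objects.
#' @param n_reads Reads simulated per editor x site sample (default 10000).
#' @param seed Master seed (default 1).
#' @param q_min Phred trimming threshold (default 15).
#' @param scope_threshold Editing-scope raw-frequency threshold (default
#'   0.40, inclusive).
#' @param cew_threshold CEW mean-normalized threshold (default 0.6, strict).
#' @param pref_min_norm Preference selection threshold (default 0.8).
#' @param min_activity Minimum on-target activity for a specificity score
#'   (default 0.05).
#' @param min_depth Minimum depth to report a frequency (default 1).
#' @param barcodes Optional named character vector barcode -> sample id used
#'   to exercise multiplexing; when `NULL`, samples are kept separate.
#' @param pairs Optional on/off pairing data frame (`on_site_id`,
#'   `off_site_id`) enabling the specificity stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sites, profiles, n_reads = 10000L, seed = 1L,
                       q_min = 15L, scope_threshold = 0.40,
                       cew_threshold = 0.6, pref_min_norm = 0.8,
                       min_activity = 0.05, min_depth = 1L,
                       barcodes = NULL, pairs = NULL) {
  stopifnot(is.list(sites), length(sites) >= 1L,
            all(vapply(sites, inherits, logical(1), "target_site")),
            is.list(profiles), length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "editor_profile")))
  for (th in c(scope_threshold, cew_threshold, pref_min_norm, min_activity)) {
    if (th < 0 || th > 1) stop("thresholds must lie within [0, 1]")
  }
  if (q_min < 0) stop("q_min must be >= 0")
  structure(list(sites = sites, profiles = profiles,
                 n_reads = as.integer(n_reads), seed = as.integer(seed),
                 q_min = as.integer(q_min), scope_threshold = scope_threshold,
                 cew_threshold = cew_threshold, pref_min_norm = pref_min_norm,
                 min_activity = min_activity, min_depth = as.integer(min_depth),
                 barcodes = barcodes, pairs = pairs),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Simulates reads for every editor x site sample, optionally multiplexes
#' and demultiplexes them by barcode, quantifies each sample, then runs the
#' editing-window, substrate-preference and (when pairings are configured)
#' specificity analyses. All outputs are TSVs under `out_dir`; a
#' `manifest.tsv` records the seed, every threshold and per-stage read
#' counts. Re-running with an identical configuration reproduces
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`tables`,
#'   `windows`, `preference`, `specificity`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sites <- config$sites
  profiles <- config$profiles
  manifest <- list(seed = config$seed, n_reads = config$n_reads,
                   q_min = config$q_min,
                   scope_threshold = config$scope_threshold,
                   cew_threshold = config$cew_threshold,
                   pref_min_norm = config$pref_min_norm,
                   min_activity = config$min_activity,
                   min_depth = config$min_depth,
                   n_sites = length(sites), n_editors = length(profiles))

  # --- simulate ------------------------------------------------------------
  k <- 0L
  sim <- list()  # sim[[editor]][[site]] = reads
  for (ed in names(profiles)) {
    sim[[ed]] <- list()
    for (sid in names(sites)) {
      k <- k + 1L
      bc <- if (!is.null(config$barcodes)) {
        names(config$barcodes)[match(paste(ed, sid, sep = "."),
                                     unname(config$barcodes))]
      } else NULL
      out <- simulate_reads(sites[[sid]], profiles[[ed]], config$n_reads,
                            seed = derive_seed(config$seed, k),
                            barcode = if (is.null(bc) || is.na(bc)) "" else bc)
      sim[[ed]][[sid]] <- out$reads
    }
  }

  # --- multiplex / demultiplex --------------------------------------------
  total_in <- sum(vapply(sim, function(x) sum(vapply(x, nrow, integer(1))),
                         integer(1)))
  manifest$reads_simulated <- total_in
  if (!is.null(config$barcodes)) {
    pool <- do.call(rbind, unlist(sim, recursive = FALSE))
    write_fastq(pool, file.path(out_dir, "multiplexed.fastq"))
    dm <- demultiplex(read_fastq(file.path(out_dir, "multiplexed.fastq")),
                      config$barcodes)
    manifest$reads_unassigned <- dm$unassigned
    get_reads <- function(ed, sid) dm$samples[[paste(ed, sid, sep = ".")]]
  } else {
    manifest$reads_unassigned <- 0L
    get_reads <- function(ed, sid) sim[[ed]][[sid]]
  }

  # --- quantify ------------------------------------------------------------
  tables <- list(); placed_total <- 0L; discarded_total <- 0L
  for (ed in names(profiles)) {
    tables[[ed]] <- list()
    for (sid in names(sites)) {
      q <- quantify_sample(get_reads(ed, sid), sites[[sid]],
                           q_min = config$q_min)
      placed_total <- placed_total + q$stats[["placed"]]
      discarded_total <- discarded_total +
        sum(q$stats[c("unplaced", "ambiguous", "too_short", "empty")])
      tables[[ed]][[sid]] <- q$table
      write_conversion_table(q$table,
                             file.path(out_dir, sprintf("conversion_%s_%s.tsv", ed, sid)),
                             sample_id = ed, min_depth = config$min_depth)
    }
  }
  manifest$reads_placed <- placed_total
  manifest$reads_discarded <- discarded_total

  # --- editing windows -----------------------------------------------------
  windows <- list()
  for (ed in names(profiles)) {
    freq_maps <- lapply(tables[[ed]], conversion_frequencies,
                        min_depth = config$min_depth)
    wr <- analyze_windows(freq_maps, editor_id = ed,
                          scope_threshold = config$scope_threshold,
                          cew_threshold = config$cew_threshold)
    windows[[ed]] <- wr
    write_window_result(wr, file.path(out_dir, sprintf("windows_%s.tsv", ed)))
    scope_rows <- do.call(rbind, lapply(names(wr$scope), function(sg) {
      if (length(wr$scope[[sg]]) == 0L) return(NULL)
      data.frame(editor_id = ed, sgrna = sg, cp = wr$scope[[sg]],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(scope_rows)) {
      scope_rows <- data.frame(editor_id = character(0), sgrna = character(0),
                               cp = integer(0))
    }
    write_tsv_file(scope_rows, file.path(out_dir, sprintf("scope_%s.tsv", ed)))
  }

  # --- substrate preference ------------------------------------------------
  preference <- list()
  for (ed in names(profiles)) {
    site_tables <- lapply(names(sites), function(sid) {
      site_context_table(sites[[sid]],
                         windows[[ed]]$norm[[sid]])
    })
    pr <- analyze_preference(site_tables, editor_id = ed,
                             min_norm = config$pref_min_norm)
    preference[[ed]] <- pr
    write_preference_result(pr, file.path(out_dir, sprintf("preference_%s.tsv", ed)))
  }

  # --- specificity ---------------------------------------------------------
  specificity <- NULL
  if (!is.null(config$pairs)) {
    specificity <- list()
    for (ed in names(profiles)) {
      sp <- specificity_panel(tables[[ed]], config$pairs, editor_id = ed,
                              min_activity = config$min_activity,
                              min_depth = config$min_depth)
      specificity[[ed]] <- sp
      write_tsv_file(sp$pairs, file.path(out_dir, sprintf("specificity_%s.tsv", ed)))
      write_tsv_file(sp$summary,
                     file.path(out_dir, sprintf("specificity_summary_%s.tsv", ed)))
    }
  }

  manifest_df <- data.frame(key = names(manifest),
                            value = vapply(manifest, function(v)
                              format(v, scientific = FALSE), character(1)),
                            stringsAsFactors = FALSE)
  write_tsv_file(manifest_df, file.path(out_dir, "manifest.tsv"))
  invisible(list(tables = tables, windows = windows, preference = preference,
                 specificity = specificity, manifest = manifest))
}
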