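# FASTQ reads -> per-position base-conversion frequency tables:
# demultiplex -> 3' quality trim -> seed placement -> tabulate -> frequency,
# with Frequency = base conversion reads / total reads at each position.

#' Demultiplex reads by exact barcode prefix
#'
#' A read is assigned to the sample whose barcode exactly matches its prefix;
#' the barcode is then stripped from sequence and quality. Non-matching reads
#' are counted as unassigned. With an empty barcode map all reads pass
#' through under a single `default` sample.
#'
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @param barcode_map Named character vector mapping barcode -> sample id
#'   (names are the barcodes, all of equal length and unique).
#' @return List with `samples` (named list of read data frames) and
#'   `unassigned` (count).
#' @export
demultiplex <- function(reads, barcode_map = character(0)) {
  if (length(barcode_map) == 0L) {
    return(list(samples = list(default = reads), unassigned = 0L))
  }
  bc <- names(barcode_map)
  if (is.null(bc) || any(!nzchar(bc))) stop("barcode_map must be named by barcode")
  if (anyDuplicated(bc)) stop("duplicate barcodes in barcode_map")
  if (length(unique(nchar(bc))) != 1L) stop("barcodes must all have equal length")
  bl <- nchar(bc[1])
  prefix <- substr(reads$seq, 1L, bl)
  hit <- match(prefix, bc)
  assigned <- !is.na(hit)
  stripped <- reads[assigned, , drop = FALSE]
  stripped$seq <- substr(stripped$seq, bl + 1L, nchar(stripped$seq))
  stripped$qual <- substr(stripped$qual, bl + 1L, nchar(stripped$qual))
  samples <- lapply(stats::setNames(seq_along(bc), unname(barcode_map)),
                    function(i) stripped[hit[assigned] == i, , drop = FALSE])
  list(samples = samples, unassigned = sum(!assigned))
}

#' Trim low-quality 3' ends
#'
#' Bases are removed from the 3' end while their Phred score is below
#' `q_min`; the surviving prefix is kept (it may be empty; empty reads are
#' discarded downstream).
#'
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @param q_min Phred threshold (default 15).
#' @return The reads data frame with trimmed `seq`/`qual`.
#' @export
quality_trim <- function(reads, q_min = 15L) {
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("malformed record: sequence and quality lengths differ")
  }
  if (nrow(reads) == 0L) return(reads)
  # quality strings are highly repetitive; trim each distinct one once
  uq <- unique(reads$qual)
  ulen <- vapply(uq, function(q) {
    s <- utf8ToInt(q) - 33L
    ok <- which(s >= q_min)
    if (length(ok)) max(ok) else 0L
  }, integer(1), USE.NAMES = FALSE)
  keep_len <- ulen[match(reads$qual, uq)]
  reads$seq <- substr(reads$seq, 1L, keep_len)
  reads$qual <- substr(reads$qual, 1L, keep_len)
  reads
}

#' Place reads on the amplicon by exact seed match
#'
#' Each read is placed by exact match of its seed (first `seed_len` bases)
#' against the amplicon forward strand or its reverse complement. Reads whose
#' seed matches at two or more locations (either strand) are discarded as
#' ambiguous. A unique seed hit is extended to a full-length comparison;
#' placement is accepted when the mismatch fraction is at most `max_mm`.
#' Reverse-strand placements are reverse-complemented into forward
#' orientation.
#'
#' @param reads Data frame with columns `id`, `seq`, `qual` (trimmed).
#' @param site A [target_site()].
#' @param seed_len Seed length (default 20); shorter reads are unplaced.
#' @param max_mm Maximum mismatch fraction over the full read (default 0.2).
#' @return List with `placed` (data frame `id`, `seq` in forward orientation,
#'   `offset` 0-based) and `stats` (named counts: `placed`, `unplaced`,
#'   `ambiguous`, `too_short`, `empty`).
#' @export
place_reads <- function(reads, site, seed_len = 20L, max_mm = 0.2) {
  stopifnot(inherits(site, "target_site"))
  amp <- site$amplicon_seq
  amp_len <- nchar(amp)
  ramp <- revcomp(amp)

  stats <- c(placed = 0L, unplaced = 0L, ambiguous = 0L, too_short = 0L, empty = 0L)
  empty <- nchar(reads$seq) == 0L
  stats["empty"] <- sum(empty)
  short <- !empty & nchar(reads$seq) < seed_len
  stats["too_short"] <- sum(short)
  reads <- reads[!empty & !short, , drop = FALSE]
  if (nrow(reads) == 0L) {
    return(list(placed = data.frame(id = character(0), seq = character(0),
                                    offset = integer(0), stringsAsFactors = FALSE),
                stats = stats))
  }

  seeds <- substr(reads$seq, 1L, seed_len)
  useeds <- unique(seeds)
  find_hits <- function(seed, subject) {
    h <- gregexpr(seed, subject, fixed = TRUE)[[1]]
    h[h > 0L] - 1L  # 0-based
  }
  fwd_hits <- lapply(useeds, find_hits, subject = amp)
  rev_hits <- lapply(useeds, find_hits, subject = ramp)
  si <- match(seeds, useeds)

  n <- nrow(reads)
  nf <- lengths(fwd_hits); nr <- lengths(rev_hits)
  nhits <- (nf + nr)[si]
  rl <- nchar(reads$seq)

  status <- rep("unplaced", n)
  status[nhits >= 2L] <- "ambiguous"
  cand <- which(nhits == 1L)

  out_seq <- character(n); out_off <- rep(NA_integer_, n)
  is_fwd <- nf[si] == 1L
  # forward candidates align at the seed hit; reverse candidates are
  # reverse-complemented into forward orientation, where their *last*
  # seed_len bases sit at the (strand-flipped) hit
  ufo <- vapply(fwd_hits, function(h) if (length(h) == 1L) h else NA_integer_, integer(1))
  uro <- vapply(rev_hits, function(h) if (length(h) == 1L) h else NA_integer_, integer(1))
  out_off[cand] <- ifelse(is_fwd[cand], ufo[si[cand]],
                          amp_len - uro[si[cand]] - rl[cand])
  out_seq[cand] <- reads$seq[cand]
  rev_cand <- cand[!is_fwd[cand]]
  if (length(rev_cand)) out_seq[rev_cand] <- revcomp(reads$seq[rev_cand])
  oob <- cand[out_off[cand] < 0L | out_off[cand] + rl[cand] > amp_len]
  cand <- setdiff(cand, oob)

  # mismatch fractions, grouped by (offset, length) so each group compares
  # against one reference substring via a single integer comparison
  for (grp in split(cand, paste(out_off[cand], rl[cand]))) {
    off <- out_off[grp[1]]; L <- rl[grp[1]]
    refint <- utf8ToInt(substr(amp, off + 1L, off + L))
    big <- utf8ToInt(paste(out_seq[grp], collapse = ""))
    mm <- colSums(matrix(big != refint, nrow = L))
    status[grp[mm / L <= max_mm]] <- "placed"
  }
  keep <- status == "placed"
  stats["placed"] <- sum(keep)
  stats["unplaced"] <- stats["unplaced"] + sum(status == "unplaced")
  stats["ambiguous"] <- sum(status == "ambiguous")
  list(placed = data.frame(id = reads$id[keep], seq = out_seq[keep],
                           offset = out_off[keep], stringsAsFactors = FALSE),
       stats = stats)
}

# internal constructor shared by tabulate_reads and simulate_site_counts
new_conversion_table <- function(site, win, ref, counts) {
  tab <- data.frame(
    site_id = site$site_id, cp = win, ref_base = unname(ref),
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"], T = counts[, "T"],
    stringsAsFactors = FALSE)
  tab$depth <- tab$A + tab$C + tab$G + tab$T
  structure(tab, class = c("conversion_table", "data.frame"),
            strand = site$strand)
}

#' Tabulate placed reads into a conversion table
#'
#' For every quantification-window position covered by a placed read, the
#' observed base — read on the protospacer strand — increments the
#' corresponding count. Depth varies by position when reads are partial
#' (e.g. after 3' trimming); uncovered positions have depth 0.
#'
#' @param placed Data frame from [place_reads()] (`seq` forward-oriented,
#'   `offset` 0-based).
#' @param site A [target_site()].
#' @return A `conversion_table`: data frame with columns `site_id`, `cp`,
#'   `ref_base`, `A`, `C`, `G`, `T`, `depth`, one row per window position.
#' @export
tabulate_reads <- function(placed, site) {
  stopifnot(inherits(site, "target_site"))
  ref <- window_ref_bases(site)
  win <- as.integer(names(ref))
  counts <- matrix(0L, nrow = length(win), ncol = 4,
                   dimnames = list(NULL, BASES))
  if (nrow(placed) > 0L) {
    rl <- nchar(placed$seq)
    idx <- vapply(win, function(p) cp_to_amplicon_index(site, p), integer(1))
    base_codes <- utf8ToInt("ACGT")
    if (site$strand == "-") base_codes <- rev(base_codes)  # complement lookup
    # group reads sharing (offset, length): one integer matrix per group
    for (grp in split(seq_len(nrow(placed)), paste(placed$offset, rl))) {
      off <- placed$offset[grp[1]]; L <- rl[grp[1]]
      chars <- matrix(utf8ToInt(paste(placed$seq[grp], collapse = "")), nrow = L)
      pos <- idx - off + 1L                    # 1-based position within read
      inside <- which(pos >= 1L & pos <= L)
      for (i in inside) {
        counts[i, ] <- counts[i, ] +
          tabulate(match(chars[pos[i], ], base_codes), nbins = 4L)
      }
    }
  }
  new_conversion_table(site, win, ref, counts)
}

#' Base-conversion frequency at one position
#'
#' `count(to_base) / depth` at position `cp` when the reference base there is
#' `from_base` and depth is positive. Returns `NA` with attribute
#' `status = "no_coverage"` at depth 0 (never 0%), and `NA` with
#' `status = "not_applicable"` when the reference base differs from
#' `from_base`.
#'
#' @param table A `conversion_table`.
#' @param cp Signed protospacer position (must lie in the window).
#' @param from_base,to_base Conversion of interest (default C->T).
#' @return Numeric frequency, or `NA` with a `status` attribute.
#' @export
conversion_frequency <- function(table, cp, from_base = "C", to_base = "T") {
  i <- match(as.integer(cp), table$cp)
  if (is.na(i)) stop("position ", cp, " is outside the quantification window")
  if (table$ref_base[i] != from_base) {
    return(structure(NA_real_, status = "not_applicable"))
  }
  if (table$depth[i] == 0) return(structure(NA_real_, status = "no_coverage"))
  table[[to_base]][i] / table$depth[i]
}

#' Conversion frequencies across the window
#'
#' @param table A `conversion_table`.
#' @param from_base,to_base Conversion of interest (default C->T).
#' @param min_depth Minimum depth to report a frequency; positions below it
#'   are `NA` (default 1).
#' @return Named numeric vector over positions whose reference base is
#'   `from_base` (names are signed positions); `NA` where depth < `min_depth`.
#' @export
conversion_frequencies <- function(table, from_base = "C", to_base = "T",
                                   min_depth = 1L) {
  sel <- table$ref_base == from_base
  f <- ifelse(table$depth[sel] >= max(1L, min_depth),
              table[[to_base]][sel] / table$depth[sel], NA_real_)
  stats::setNames(f, table$cp[sel])
}

#' Quantify one sample end to end
#'
#' Runs quality trimming, placement and tabulation for one sample of reads on
#' one target site.
#'
#' @param reads Data frame with columns `id`, `seq`, `qual` (already
#'   demultiplexed).
#' @param site A [target_site()].
#' @param q_min Phred trimming threshold (default 15).
#' @param seed_len,max_mm Placement parameters (see [place_reads()]).
#' @return List with `table` (a `conversion_table`) and `stats` (read counts
#'   per placement outcome).
#' @export
quantify_sample <- function(reads, site, q_min = 15L, seed_len = 20L,
                            max_mm = 0.2) {
  trimmed <- quality_trim(reads, q_min = q_min)
  pl <- place_reads(trimmed, site, seed_len = seed_len, max_mm = max_mm)
  list(table = tabulate_reads(pl$placed, site), stats = pl$stats)
}

#' Write / read a conversion table as TSV
#'
#' Columns: `site_id`, `sample_id`, `cp`, `ref_base`, `A`, `C`, `G`, `T`,
#' `depth`, `freq_C_to_T` (missing frequencies written as `NA`).
#'
#' @param table A `conversion_table`.
#' @param path TSV path.
#' @param sample_id Sample identifier recorded in the table.
#' @param min_depth Minimum depth to report a frequency (default 1).
#' @name conversion_table_io
#' @export
write_conversion_table <- function(table, path, sample_id = "default",
                                   min_depth = 1L) {
  out <- as.data.frame(table)
  out$sample_id <- sample_id
  fr <- rep(NA_real_, nrow(out))
  isc <- out$ref_base == "C" & out$depth >= max(1L, min_depth)
  fr[isc] <- out$T[isc] / out$depth[isc]
  out$freq_C_to_T <- fr
  write_tsv_file(out[, c("site_id", "sample_id", "cp", "ref_base",
                         "A", "C", "G", "T", "depth", "freq_C_to_T")], path)
}

#' @rdname conversion_table_io
#' @export
read_conversion_table <- function(path) {
  x <- read_tsv_file(path)
  structure(x, class = c("conversion_table", "data.frame"))
}
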