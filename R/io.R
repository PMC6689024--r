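# Format handlers: FASTA (via Biostrings), 4-line FASTQ (Phred+33), TSV.
# All tables are written as UTF-8 TSV with a mandatory header row and "NA"
# for missing values.

#' Read a (possibly line-wrapped) multi-record FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a 4-line FASTQ file (Phred+33)
#'
#' Malformed records (truncated record, missing `@`/`+` markers, or a quality
#' string whose length differs from the sequence) raise an error naming the
#' offending record index.
#'
#' @param path FASTQ file path.
#' @return A data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record at record index ", length(lines) %/% 4L + 1L,
         " in ", path)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad)) stop("malformed FASTQ record at record index ", bad[1], " in ", path)
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("FASTQ record ", bad[1], " in ", path,
         ": sequence and quality lengths differ")
  }
  data.frame(id = sub("^@", "", hdr), seq = toupper(seqs), qual = qual,
             stringsAsFactors = FALSE)
}

#' Write reads as 4-line FASTQ (Phred+33)
#'
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence and quality lengths differ; refusing to write malformed FASTQ")
  }
  con <- file(path, open = "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    out <- rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)
    writeLines(as.vector(out), con, sep = "\n")
  }
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("TSV file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE, comment.char = "")
}

#' TSV input/output
#'
#' Tab-separated tables with a mandatory header row; missing values written
#' as `"NA"`; never quoted.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @name tsv_io
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# internal: vectorized reverse complement
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# internal: run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# internal: derive the i-th stream seed from a master seed, kept < 2^31
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 9973) %% 2147483629) + 1L
}
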