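#' Read a FASTA file
#'
#' Reads sequence records via Biostrings, folds sequences to upper case and
#' validates the record set: ids must be non-empty and unique, sequences
#' non-empty and restricted to the A/C/G/T/N alphabet. Any line wrapping is
#' accepted.
#'
#' @param path path to a FASTA file.
#' @return a data.frame with columns `id`, `description`, `sequence`, in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("failed to parse FASTA ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0) stop("no records in FASTA file: ", path)
  nm <- names(set)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  seqs <- toupper(as.character(set))
  if (any(id == ""))
    stop("malformed header (empty id) at record ", which(id == "")[1])
  if (anyDuplicated(id))
    stop("duplicate record id: ", id[duplicated(id)][1])
  if (any(nchar(seqs) == 0))
    stop("empty sequence for record ", id[nchar(seqs) == 0][1])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ch <- regmatches(seqs[bad][1], regexpr("[^ACGTN]", seqs[bad][1]))
    stop("record ", id[bad][1], " contains non-ACGTN character '", ch, "'")
  }
  data.frame(id = unname(id), description = unname(desc),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param x a data.frame with `id`/`sequence` (optionally `description`)
#'   columns, or a named character vector of sequences.
#' @param path output path.
#' @param width line width for sequence wrapping (default 70).
#' @return the path, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  df <- if (is.data.frame(x)) x else as_seq_df(x)
  hdr <- df$id
  if (!is.null(df$description)) {
    has_desc <- !is.na(df$description) & df$description != ""
    hdr[has_desc] <- paste(df$id[has_desc], df$description[has_desc])
  }
  set <- Biostrings::BStringSet(setNames(as.character(df$sequence), hdr))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (sequences only)
#'
#' @param path path to a FASTQ file.
#' @return a data.frame with columns `id`, `description`, `sequence`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  nm <- names(set)
  data.frame(id = sub("\\s.*$", "", nm),
             description = ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), ""),
             sequence = toupper(as.character(set)), stringsAsFactors = FALSE)
}

#' Write sequences to a FASTQ file with uniform qualities
#'
#' @param x a data.frame with `id`/`sequence` columns or a named character
#'   vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(x, path) {
  df <- if (is.data.frame(x)) x else as_seq_df(x)
  seqs <- Biostrings::DNAStringSet(setNames(as.character(df$sequence), df$id))
  quals <- Biostrings::PhredQuality(strrep("I", nchar(df$sequence)))
  qs <- Biostrings::QualityScaledDNAStringSet(seqs, quals)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Assembly summary statistics
#'
#' Computes the usual assembly summary: number of sequences, total and
#' largest length, N50 (the largest L such that sequences of length >= L
#' contain at least half of the total bases), GC fraction over determined
#' (non-N) bases, and the number of N gap bases.
#'
#' @param x sequences as a data.frame (`id`, `sequence`) or named character
#'   vector.
#' @return a list with `n_seqs`, `total_len`, `largest_len`, `n50`,
#'   `gc_fraction`, `n_gap_bases`.
#' @export
assembly_stats <- function(x) {
  v <- as_seq_vector(x)
  if (length(v) == 0) stop("assembly_stats: empty sequence set")
  lens <- nchar(v)
  total <- sum(lens)
  sl <- sort(lens, decreasing = TRUE)
  n50 <- unname(sl[which(cumsum(sl) >= total / 2)[1]])
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(v))
  gc <- sum(freq[, c("G", "C")])
  at <- sum(freq[, c("A", "T")])
  nn <- sum(freq[, "N"])
  list(n_seqs = length(v),
       total_len = total,
       largest_len = max(lens),
       n50 = n50,
       gc_fraction = if (gc + at > 0) gc / (gc + at) else NA_real_,
       n_gap_bases = nn)
}

#' Write intervals as a BED file
#'
#' Internal coordinates in this package are 1-based closed; BED output is
#' converted to the standard 0-based half-open convention.
#'
#' @param df data.frame with columns `seq_id`, `start`, `end` (1-based
#'   closed) and optionally `name`, `score`, `strand`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$seq_id, start = df$start - 1L, end = df$end,
                    stringsAsFactors = FALSE)
  if (!is.null(df$name)) {
    out$name <- df$name
    out$score <- if (is.null(df$score)) 0L else df$score
    out$strand <- if (is.null(df$strand)) "." else df$strand
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
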