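#' @title Local alignment via BLAST+
#' @description Long-read-vs-contig and plastome-vs-mitogenome comparisons
#'   use BlastN through the NCBI BLAST+ command line tools, which must be on
#'   the PATH (`blastn`, `makeblastdb`).
#' @name blast
NULL

check_blast <- function() {
  if (Sys.which("blastn") == "" || Sys.which("makeblastdb") == "")
    stop("NCBI BLAST+ (blastn/makeblastdb) not found on PATH")
  invisible(TRUE)
}

# run blastn query-vs-subject, return a hit table with 1-based closed
# coordinates; subject coordinates are normalized to lo <= hi with a strand
# column
run_blastn <- function(query, subject, min_identity = 0,
                       task = "megablast", word_size = NULL) {
  check_blast()
  qd <- as_seq_df(query)
  sd <- as_seq_df(subject)
  td <- tempfile("blast")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- file.path(td, "query.fa")
  sf <- file.path(td, "subject.fa")
  write_fasta(qd, qf)
  write_fasta(sd, sf)
  db <- file.path(td, "db")
  system2("makeblastdb", c("-in", sf, "-dbtype", "nucl", "-out", db),
          stdout = FALSE, stderr = FALSE)
  outf <- file.path(td, "hits.tsv")
  args <- c("-query", qf, "-db", db, "-task", task,
            "-dust", "no", "-soft_masking", "false",
            "-outfmt", shQuote(paste("6 qseqid sseqid pident length mismatch",
                                     "gapopen qstart qend sstart send evalue",
                                     "bitscore")),
            "-out", outf)
  if (!is.null(word_size)) args <- c(args, "-word_size", word_size)
  status <- system2("blastn", args, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("blastn failed with exit status ", status)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.info(outf)$size == 0) {
    h <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    h$pident <- numeric(0); h$length <- integer(0)
    h$qstart <- integer(0); h$qend <- integer(0)
    h$sstart <- integer(0); h$send <- integer(0)
    h$bitscore <- numeric(0)
  } else {
    h <- read.delim(outf, header = FALSE, col.names = cols,
                    stringsAsFactors = FALSE)
  }
  strand <- ifelse(h$send >= h$sstart, "+", "-")
  data.frame(read_id = h$qseqid, contig_id = h$sseqid,
             identity = h$pident / 100, aln_len = h$length,
             qlo = h$qstart, qhi = h$qend,
             slo = pmin(h$sstart, h$send), shi = pmax(h$sstart, h$send),
             strand = strand, bitscore = h$bitscore,
             stringsAsFactors = FALSE)[h$pident / 100 >= min_identity, ,
                                       drop = FALSE]
}

#' Align reads to contigs with BlastN, keeping the best hit per pair
#'
#' Local alignment of each read against each contig on both strands; per
#' (read, contig) pair only the best hit is kept (highest bitscore, ties
#' broken by higher identity, longer alignment, then contig id). Hits below
#' `min_identity` are discarded.
#'
#' @param reads read sequences (data.frame or named character vector).
#' @param contigs contig sequences.
#' @param min_identity minimum alignment identity (default 0.9).
#' @return data.frame of local hits with read and contig intervals (1-based
#'   closed), strand and identity.
#' @export
align_read_to_contigs <- function(reads, contigs, min_identity = 0.9) {
  h <- run_blastn(reads, contigs, min_identity = min_identity)
  if (nrow(h) == 0) return(h)
  o <- order(h$read_id, h$contig_id, -h$bitscore, -h$identity, -h$aln_len)
  h <- h[o, , drop = FALSE]
  keep <- !duplicated(paste(h$read_id, h$contig_id, sep = "\r"))
  h <- h[keep, , drop = FALSE]
  rownames(h) <- NULL
  h
}
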