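#' @useDynLib mitoscaff, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif rlnorm setNames cor.test aggregate
#' @importFrom utils head tail read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence at a target GC content
#'
#' Draws i.i.d. bases with P(G) = P(C) = gc/2. Uses the current RNG state, so
#' wrap calls in a seed for reproducibility.
#'
#' @param n sequence length in bp.
#' @param gc target GC fraction in \[0, 1\].
#' @return a single DNA string.
#' @export
random_dna <- function(n, gc = 0.46) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# accept either a data.frame with id/sequence columns or a named character
# vector; return the named character vector form
as_seq_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    setNames(as.character(x$sequence), as.character(x$id))
  } else if (is.character(x)) {
    if (is.null(names(x)) && length(x) > 0)
      names(x) <- paste0("seq", seq_along(x))
    x
  } else {
    stop("expected a data.frame with id/sequence columns or a named character vector")
  }
}

as_seq_df <- function(x) {
  v <- as_seq_vector(x)
  data.frame(id = names(v), description = rep("", length(v)),
             sequence = unname(v), stringsAsFactors = FALSE)
}

# substitution/indel mutator; rates are per-base probabilities
mutate_seq <- function(seq, sub_rate = 0, ins_rate = 0, del_rate = 0) {
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  bases <- c("A", "C", "G", "T")
  if (sub_rate > 0) {
    hit <- which(runif(n) < sub_rate)
    if (length(hit)) {
      repl <- sample(bases, length(hit), replace = TRUE)
      same <- repl == ch[hit]
      while (any(same)) {
        repl[same] <- sample(bases, sum(same), replace = TRUE)
        same <- repl == ch[hit]
      }
      ch[hit] <- repl
    }
  }
  if (del_rate > 0) {
    keep <- runif(length(ch)) >= del_rate
    ch <- ch[keep]
  }
  if (ins_rate > 0) {
    n2 <- length(ch)
    ins_at <- which(runif(n2) < ins_rate)
    if (length(ins_at)) {
      ins_b <- sample(bases, length(ins_at), replace = TRUE)
      out <- character(n2 + length(ins_at))
      pos <- rep(1, n2)
      # insert after the chosen positions
      idx <- sort(ins_at)
      res <- character(0)
      last <- 0
      for (t in seq_along(idx)) {
        res <- c(res, ch[(last + 1):idx[t]], ins_b[t])
        last <- idx[t]
      }
      if (last < n2) res <- c(res, ch[(last + 1):n2])
      ch <- res
    }
  }
  paste(ch, collapse = "")
}

# substring of a circular sequence (1-based start, may wrap)
circ_substr <- function(seq, start, len) {
  n <- nchar(seq)
  stopifnot(len <= n)
  start <- ((start - 1) %% n) + 1
  if (start + len - 1 <= n) return(substr(seq, start, start + len - 1))
  paste0(substr(seq, start, n), substr(seq, 1, start + len - 1 - n))
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# write a data.frame as TSV (no quoting, no row names)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
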