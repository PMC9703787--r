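#' Find interspersed repeats by exact maximal-repeat enumeration
#'
#' Enumerates all maximal repeated substrings of length `min_len` or more
#' occurring at least twice across the sequence set, on both strands, via a
#' suffix array with LCP intervals (right-maximality) and BWT character
#' diversity (left-maximality). A repeat and its reverse complement form one
#' family (strand recorded per copy); self-hits are removed. Runs of
#' directly adjacent copies (gap at most `tandem_gap`) are collapsed as
#' tandem, and families with fewer than two non-tandem placements are
#' excluded from the interspersed set.
#'
#' @param x sequences (data.frame with `id`/`sequence` or named character
#'   vector).
#' @param min_len minimum repeat unit length (24 and 50 bp are the two
#'   conventional reporting tiers).
#' @param tandem_gap maximum gap (bp) between copies collapsed as tandem
#'   (default 0 = directly adjacent).
#' @return list of class `repeat_set`: `families` (family_id, unit_length,
#'   copy_number), `copies` (family_id, seq_id, start, end, strand; 1-based
#'   closed), `units` (named character vector of unit sequences), and the
#'   total sequence length scanned.
#' @export
find_repeats <- function(x, min_len = 50, tandem_gap = 0) {
  v <- as_seq_vector(x)
  total_len <- sum(nchar(v))
  if (total_len < min_len) stop("total sequence length below min_len")
  n <- length(v)
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)
  enc <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    unname(code[ch])
  }
  # region table: forward then reverse-complement copies of each sequence,
  # each followed by a unique separator symbol
  pieces <- list(); regions <- list(); sep <- 10L
  offset <- 0L
  for (i in seq_len(n)) {
    e <- enc(v[[i]])
    pieces[[length(pieces) + 1]] <- c(e, sep)
    regions[[length(regions) + 1]] <-
      list(seq = i, strand = "+", start = offset, len = length(e))
    offset <- offset + length(e) + 1L
    sep <- sep + 1L
  }
  for (i in seq_len(n)) {
    e <- enc(revcomp(v[[i]]))
    pieces[[length(pieces) + 1]] <- c(e, sep)
    regions[[length(regions) + 1]] <-
      list(seq = i, strand = "-", start = offset, len = length(e))
    offset <- offset + length(e) + 1L
    sep <- sep + 1L
  }
  text <- unlist(pieces)
  reps <- cpp_maximal_repeats(text, as.integer(min_len))
  reg_start <- vapply(regions, `[[`, numeric(1), "start")
  reg_len <- vapply(regions, `[[`, numeric(1), "len")

  fam <- new.env(parent = emptyenv())
  seq_ids <- names(v)
  for (rp in reps) {
    len <- rp$len
    occ <- rp$occ
    ri <- findInterval(occ, reg_start)
    # occurrences crossing a separator are impossible; map to loci
    first <- occ[1]
    fr <- ri[1]
    off1 <- first - reg_start[fr]
    src <- regions[[fr]]
    unit <- if (src$strand == "+")
      substr(v[[src$seq]], off1 + 1, off1 + len)
    else substr(revcomp(v[[src$seq]]), off1 + 1, off1 + len)
    if (grepl("N", unit, fixed = TRUE)) next
    rcu <- revcomp(unit)
    cu <- if (unit <= rcu) unit else rcu
    ustr <- if (unit == cu) "+" else "-"
    loci <- vector("list", length(occ))
    for (t in seq_along(occ)) {
      r <- regions[[ri[t]]]
      off <- occ[t] - reg_start[ri[t]]
      if (r$strand == "+") {
        loci[[t]] <- c(r$seq, off + 1, off + len, ustr)
      } else {
        L <- reg_len[ri[t]]
        loci[[t]] <- c(r$seq, L - (off + len) + 1, L - off,
                       flip_strand(ustr))
      }
    }
    key <- cu
    prev <- if (!is.null(fam[[key]])) fam[[key]] else list()
    fam[[key]] <- c(prev, loci)
  }

  units <- ls(fam)
  fam_rows <- list(); copy_rows <- list(); unit_seqs <- character(0)
  fi <- 0
  # deterministic family order: unit length desc, then unit sequence
  if (length(units)) {
    units <- units[order(-nchar(units), units)]
  }
  for (cu in units) {
    loci <- unique(lapply(fam[[cu]], function(z) z))
    df <- do.call(rbind, lapply(loci, function(z)
      data.frame(seq = as.integer(z[1]), start = as.integer(z[2]),
                 end = as.integer(z[3]), strand = z[4],
                 stringsAsFactors = FALSE)))
    # palindromic units match both strands at one locus: count once
    df <- df[order(df$seq, df$start, df$strand), , drop = FALSE]
    df <- df[!duplicated(paste(df$seq, df$start)), , drop = FALSE]
    if (nrow(df) < 2) next
    # tandem collapse: runs of adjacent copies count as one placement
    grp <- integer(nrow(df)); g <- 1; grp[1] <- 1
    if (nrow(df) > 1) for (i in 2:nrow(df)) {
      adj <- df$seq[i] == df$seq[i - 1] &&
        df$start[i] - df$end[i - 1] - 1 <= tandem_gap
      if (!adj) g <- g + 1
      grp[i] <- g
    }
    if (max(grp) < 2) next # tandem-only: excluded from interspersed tier
    fi <- fi + 1
    fid <- sprintf("RF%04d", fi)
    unit_seqs[fid] <- cu
    fam_rows[[fi]] <- data.frame(family_id = fid, unit_length = nchar(cu),
                                 copy_number = nrow(df),
                                 n_placements = max(grp),
                                 stringsAsFactors = FALSE)
    copy_rows[[fi]] <- data.frame(family_id = fid,
                                  seq_id = seq_ids[df$seq],
                                  start = df$start, end = df$end,
                                  strand = df$strand,
                                  stringsAsFactors = FALSE)
  }
  families <- if (fi) do.call(rbind, fam_rows) else
    data.frame(family_id = character(0), unit_length = integer(0),
               copy_number = integer(0), n_placements = integer(0))
  copies <- if (fi) do.call(rbind, copy_rows) else
    data.frame(family_id = character(0), seq_id = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  rownames(families) <- rownames(copies) <- NULL
  structure(list(families = families, copies = copies, units = unit_seqs,
                 min_len = min_len, total_len = total_len,
                 seq_ids = seq_ids),
            class = "repeat_set")
}

#' Proportion of repetitive elements
#'
#' The ratio of total repeat length to sequence length. Under the default
#' `union` accounting, total repeat length is the length of the union of all
#' copy intervals; `family_sum` sums one unit length per family;
#' `all_copies` sums unit length times copy number.
#'
#' @param rep_set a `repeat_set` from [find_repeats()].
#' @param mode accounting mode.
#' @return proportion (in \[0, 1\] for `union` mode).
#' @export
repeat_proportion <- function(rep_set, mode = c("union", "family_sum",
                                                "all_copies")) {
  mode <- match.arg(mode)
  total <- rep_set$total_len
  if (nrow(rep_set$families) == 0) return(0)
  switch(mode,
    union = {
      cp <- rep_set$copies
      w <- 0
      for (s in unique(cp$seq_id)) {
        iv <- IRanges::reduce(IRanges::IRanges(start = cp$start[cp$seq_id == s],
                                               end = cp$end[cp$seq_id == s]))
        w <- w + sum(IRanges::width(iv))
      }
      w / total
    },
    family_sum = sum(rep_set$families$unit_length) / total,
    all_copies = sum(rep_set$families$unit_length *
                       rep_set$families$copy_number) / total)
}

#' Summarize repeat families
#'
#' @param rep_set a `repeat_set`.
#' @param min_len restrict to families with unit length at least this value
#'   (default 50 bp, the interspersed-repeat reporting tier).
#' @param breaks histogram bin boundaries over unit length (left-closed).
#' @return list with `count`, `mean_unit_length`, `mean_copy_number` and
#'   `size_histogram` (data.frame bin/count).
#' @export
repeat_summary <- function(rep_set, min_len = 50,
                           breaks = c(50, 200, 1000, 10000, Inf)) {
  f <- rep_set$families[rep_set$families$unit_length >= min_len, ,
                        drop = FALSE]
  if (nrow(f) == 0)
    return(list(count = 0, mean_unit_length = NA_real_,
                mean_copy_number = NA_real_,
                size_histogram = data.frame(bin = character(0),
                                            count = integer(0))))
  bins <- cut(f$unit_length, breaks = breaks, right = FALSE,
              include.lowest = TRUE)
  hist <- data.frame(bin = levels(bins), count = as.integer(table(bins)),
                     stringsAsFactors = FALSE)
  list(count = nrow(f),
       mean_unit_length = mean(f$unit_length),
       mean_copy_number = mean(f$copy_number),
       size_histogram = hist)
}

#' Detect plastid-derived regions (MTPTs)
#'
#' BlastN alignment of the plastome against the mitochondrial sequences on
#' both strands; hits longer than `min_len` with identity above
#' `min_identity` are kept and overlapping or near-adjacent
#' (within `merge_gap` bp) mitochondrial intervals are merged into distinct
#' regions.
#'
#' @param mito_seqs mitochondrial sequences (data.frame or named vector).
#' @param plastome plastome sequence.
#' @param min_len minimum hit length (bp), exclusive bound (default 50).
#' @param min_identity minimum identity, exclusive bound (default 0.90).
#' @param merge_gap mito-side hits within this many bp are one region.
#' @return list with `regions` (data.frame: seq_id, start, end, identity,
#'   strand, p_start, p_end) and `proportion` (summed region length over
#'   total mitochondrial length).
#' @export
find_mtpts <- function(mito_seqs, plastome, min_len = 50, min_identity = 0.90,
                       merge_gap = 10) {
  mito <- as_seq_df_keep(if (is.character(mito_seqs)) as_seq_df(mito_seqs)
                         else mito_seqs)
  pl <- as_seq_df_keep(if (is.character(plastome)) as_seq_df(plastome)
                       else plastome)
  total <- sum(nchar(mito$sequence))
  h <- run_blastn(pl, mito, min_identity = 0)
  h <- h[h$aln_len > min_len & h$identity > min_identity, , drop = FALSE]
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), identity = numeric(0),
                      strand = character(0), p_start = integer(0),
                      p_end = integer(0))
  if (nrow(h) == 0) return(list(regions = empty, proportion = 0))
  rows <- list()
  for (s in unique(h$contig_id)) {
    hs <- h[h$contig_id == s, , drop = FALSE]
    iv <- IRanges::IRanges(start = hs$slo, end = hs$shi)
    red <- IRanges::reduce(iv, min.gapwidth = merge_gap + 1)
    ov <- IRanges::findOverlaps(iv, red)
    for (r in seq_along(red)) {
      comp <- hs[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == r], ,
                 drop = FALSE]
      best <- comp[which.max(comp$aln_len), ]
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = s, start = IRanges::start(red)[r],
        end = IRanges::end(red)[r],
        identity = sum(comp$identity * comp$aln_len) / sum(comp$aln_len),
        strand = best$strand, p_start = best$qlo, p_end = best$qhi,
        stringsAsFactors = FALSE)
    }
  }
  regions <- do.call(rbind, rows)
  regions <- regions[order(regions$seq_id, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  list(regions = regions,
       proportion = sum(regions$end - regions$start + 1) / total)
}
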