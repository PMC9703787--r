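#' Short-read mapping parameters
#'
#' The mapping contract mirrors the CLC-style parameters used throughout
#' the pipeline: a read counts only where it aligns over at least
#' `length_fraction` of its length at `similarity` identity or better, and
#' each read contributes to its single best location (equal best scores at
#' two or more loci discard the read as ambiguous).
#'
#' @param length_fraction minimum aligned fraction of the read (default 0.9).
#' @param similarity minimum identity of the aligned region (0.90 in polish
#'   pass 1, 0.95 in pass 2 and coverage runs).
#' @param include_decoys whether decoy references (chloroplast genome) are
#'   included during mapping.
#' @return list of class `map_params`.
#' @export
map_params <- function(length_fraction = 0.9, similarity = 0.95,
                       include_decoys = TRUE) {
  stopifnot(length_fraction > 0, length_fraction <= 1,
            similarity > 0, similarity <= 1)
  structure(list(length_fraction = length_fraction, similarity = similarity,
                 include_decoys = include_decoys), class = "map_params")
}

combine_reads <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(do.call(rbind, lapply(unname(x), function(d)
    d[, c("id", "sequence"), drop = FALSE])))
  as_seq_df(x)
}

#' Map short reads and build per-reference pileups
#'
#' K-mer seeded banded alignment of every read (both strands) against the
#' references. Each accepted read contributes base, deletion and insertion
#' counts to the pileup of its best reference location.
#'
#' @param reads read sequences (data.frame, list of paired data.frames, or
#'   named character vector).
#' @param references reference sequences.
#' @param params a [map_params()] object.
#' @param k seed k-mer length.
#' @param band alignment band half-width (bp).
#' @return named list of pileups (one per reference), each a list with
#'   `ref_id`, `ref_len`, `counts` (5 x L matrix: A, C, G, T, deletion) and
#'   `insertions` (data.frame pos/seq/count). The attribute `read_map` holds
#'   the per-read assignment (reference, strand, start, identity, mapped and
#'   ambiguous flags).
#' @export
map_short_reads <- function(reads, references, params = map_params(),
                            k = 15, band = 20) {
  refs <- as_seq_df_keep(if (is.character(references)) as_seq_df(references)
                         else references)
  if (nrow(refs) == 0) stop("empty reference set")
  rd <- combine_reads(reads)
  res <- cpp_map_short_reads(rd$sequence, refs$sequence, as.integer(k),
                             params$similarity, params$length_fraction,
                             as.integer(band), 24L)
  pl <- list()
  for (i in seq_len(nrow(refs))) {
    cm <- res$counts[[i]]
    rownames(cm) <- c("A", "C", "G", "T", "del")
    sel <- res$ins_ref == i
    pl[[refs$id[i]]] <- structure(list(
      ref_id = refs$id[i], ref_len = nchar(refs$sequence[i]), counts = cm,
      insertions = data.frame(pos = res$ins_pos[sel], seq = res$ins_seq[sel],
                              count = res$ins_count[sel],
                              stringsAsFactors = FALSE)), class = "pileup")
  }
  read_map <- data.frame(
    id = rd$id,
    ref = ifelse(res$read_ref > 0, refs$id[pmax(res$read_ref, 1)],
                 NA_character_),
    mapped = res$read_ref > 0,
    ambiguous = res$read_ref == -1,
    strand = ifelse(is.na(res$read_strand), NA,
                    ifelse(res$read_strand > 0, "+", "-")),
    start = res$read_start,
    identity = res$read_identity,
    stringsAsFactors = FALSE)
  attr(pl, "read_map") <- read_map
  pl
}

#' Remove chloroplast-derived reads
#'
#' Maps reads to the plastome under the stated contract and returns the
#' unmapped ones, emulating the a-priori exclusion of plastid reads before
#' mitogenome assembly.
#'
#' @param reads data.frame of reads or list of paired data.frames.
#' @param plastome plastome sequence.
#' @param params a [map_params()] object (length fraction 0.9, similarity
#'   0.95 by default).
#' @return object of the same shape as `reads`, restricted to unmapped
#'   reads.
#' @export
remove_plastid_reads <- function(reads, plastome,
                                 params = map_params(similarity = 0.95)) {
  pl_df <- as_seq_df_keep(if (is.character(plastome)) as_seq_df(plastome)
                          else plastome)
  filter_one <- function(df) {
    mp <- map_short_reads(df, pl_df, params)
    rm <- attr(mp, "read_map")
    df[!rm$mapped, , drop = FALSE]
  }
  if (is.data.frame(reads)) return(filter_one(reads))
  lapply(reads, filter_one)
}

#' Extract a consensus sequence from a pileup
#'
#' Positions with depth at or above `low_cov_threshold` take the majority
#' call (ties resolved toward the reference base); positions below the
#' threshold keep the reference base (or become `N` when
#' `low_cov_action = "n"`) and are reported as low-coverage intervals.
#' Deletions and insertions are applied when they are the majority call.
#'
#' @param pileup a pileup from [map_short_reads()].
#' @param reference the reference sequence (single string); defaults to
#'   none, in which case the pileup must carry `ref_seq`.
#' @param low_cov_threshold depth threshold for the low-coverage definition
#'   (default 5).
#' @param low_cov_action `"reference"` (default) or `"n"`.
#' @return list with `sequence`, `low_coverage` (data.frame of 1-based
#'   closed intervals on the reference), and `n_changes`.
#' @export
extract_consensus <- function(pileup, reference, low_cov_threshold = 5,
                              low_cov_action = c("reference", "n")) {
  low_cov_action <- match.arg(low_cov_action)
  cm <- pileup$counts
  L <- ncol(cm)
  stopifnot(nchar(reference) == L)
  ref_ch <- strsplit(reference, "", fixed = TRUE)[[1]]
  depth <- colSums(cm)
  code <- match(ref_ch, c("A", "C", "G", "T"))
  tc <- t(cm)
  maxc <- pmax(tc[, 1], tc[, 2], tc[, 3], tc[, 4], tc[, 5])
  ref_count <- ifelse(is.na(code), -1L, tc[cbind(seq_len(L), ifelse(is.na(code), 1L, code))])
  pick <- max.col(tc, ties.method = "first") # A<C<G<T<del preference order
  covered <- depth >= low_cov_threshold & depth > 0
  out <- ref_ch
  new_ch <- c("A", "C", "G", "T", "")[pick]
  change <- covered & ref_count < maxc
  out[change] <- new_ch[change]
  if (low_cov_action == "n") out[!covered] <- "N"
  n_changes <- sum(out != ref_ch)
  # insertions: applied when the most frequent inserted sequence at a
  # position is seen in more than half of the reads covering it
  ins <- pileup$insertions
  ins_after <- rep("", L + 1)
  if (!is.null(ins) && nrow(ins)) {
    ins <- ins[order(ins$pos, -ins$count), , drop = FALSE]
    ins <- ins[!duplicated(ins$pos), , drop = FALSE]
    for (i in seq_len(nrow(ins))) {
      p <- ins$pos[i]
      d <- if (p >= 1 && p <= L) depth[p] else depth[min(max(p, 1), L)]
      if (d >= low_cov_threshold && ins$count[i] > d / 2) {
        ins_after[p + 1] <- ins$seq[i]
        n_changes <- n_changes + nchar(ins$seq[i])
      }
    }
  }
  low <- which(!covered)
  low_iv <- if (length(low)) {
    r <- IRanges::reduce(IRanges::IRanges(start = low, width = 1))
    data.frame(start = IRanges::start(r), end = IRanges::end(r))
  } else data.frame(start = integer(0), end = integer(0))
  seq <- paste0(ins_after[1],
                paste(paste0(out, ins_after[-1]), collapse = ""))
  list(sequence = seq, low_coverage = low_iv, n_changes = n_changes)
}

#' Polish scaffolds with short reads
#'
#' Two-pass consensus polishing with the plastome as mapping decoy: pass 1
#' maps at similarity 0.90, pass 2 at 0.95 (both at length fraction 0.9),
#' each followed by consensus extraction with the low-coverage threshold.
#' The pass-2 map/consensus step is repeated until the sequences stop
#' changing (or `max_rounds` is reached), which in particular re-polishes
#' the read-derived junction spans.
#'
#' @param scaffolds a `scaffold_set` from [build_scaffolds()], or a
#'   data.frame with `id`, `sequence`.
#' @param short_reads reads (data.frame or list of paired data.frames).
#' @param plastome optional plastome decoy sequence.
#' @param low_cov_threshold low-coverage definition (default 5).
#' @param similarities per-pass similarity thresholds.
#' @param length_fraction mapping length fraction.
#' @param max_rounds maximum number of pass-2 rounds.
#' @details Short reads spanning the origin of a circular scaffold cannot
#'   map onto its linear representation, which would leave the first and
#'   last read-length of sequence under-covered. Scaffolds flagged circular
#'   (a `circular` column, or the flags of a `scaffold_set`) are therefore
#'   re-polished after rotation by half their length; when this
#'   origin-repolish changes nothing the unrotated sequence is returned, so
#'   already-perfect scaffolds are a fixed point, and otherwise the
#'   corrected sequence is reported at the rotated origin (the origin of a
#'   circular molecule is arbitrary).
#' @return list with `scaffolds` (data.frame id/sequence), `changes`
#'   (per-pass change log) and `low_coverage` intervals of the final pass.
#' @export
polish_scaffolds <- function(scaffolds, short_reads, plastome = NULL,
                             low_cov_threshold = 5,
                             similarities = c(0.90, 0.95),
                             length_fraction = 0.9, max_rounds = 4) {
  sc <- if (inherits(scaffolds, "scaffold_set"))
    data.frame(id = vapply(scaffolds$scaffolds, `[[`, character(1), "id"),
               sequence = vapply(scaffolds$scaffolds, `[[`, character(1),
                                 "sequence"),
               circular = vapply(scaffolds$scaffolds, `[[`, logical(1),
                                 "circular"), stringsAsFactors = FALSE)
  else as_seq_df_keep(scaffolds)
  if (is.null(sc$circular)) sc$circular <- FALSE
  reads <- combine_reads(short_reads)
  decoy <- if (!is.null(plastome))
    as_seq_df_keep(if (is.character(plastome)) as_seq_df(plastome)
                   else plastome) else NULL
  log <- list()
  lowiv <- NULL
  one_pass <- function(sc, sim, label) {
    refs <- sc[, c("id", "sequence")]
    if (!is.null(decoy))
      refs <- rbind(refs, decoy[, c("id", "sequence")])
    pl <- map_short_reads(reads, refs, map_params(length_fraction, sim))
    ivs <- list()
    for (i in seq_len(nrow(sc))) {
      cons <- extract_consensus(pl[[sc$id[i]]], sc$sequence[i],
                                low_cov_threshold)
      sc$sequence[i] <- cons$sequence
      log[[length(log) + 1]] <<- data.frame(pass = label, scaffold = sc$id[i],
                                            n_changes = cons$n_changes,
                                            stringsAsFactors = FALSE)
      if (nrow(cons$low_coverage)) {
        cons$low_coverage$seq_id <- sc$id[i]
        ivs[[length(ivs) + 1]] <- cons$low_coverage
      }
    }
    lowiv <<- if (length(ivs)) do.call(rbind, ivs) else
      data.frame(start = integer(0), end = integer(0), seq_id = character(0))
    sc
  }
  sc <- one_pass(sc, similarities[1], "pass1")
  for (r in seq_len(max_rounds)) {
    before <- sc$sequence
    sc <- one_pass(sc, similarities[length(similarities)],
                   paste0("pass2.", r))
    if (identical(before, sc$sequence)) break
  }
  if (any(sc$circular)) {
    rot <- function(s) {
      k <- nchar(s) %/% 2
      paste0(substr(s, k + 1, nchar(s)), substr(s, 1, k))
    }
    keep <- sc$sequence
    sc$sequence[sc$circular] <- vapply(sc$sequence[sc$circular], rot,
                                       character(1), USE.NAMES = FALSE)
    rotated <- sc$sequence
    sc <- one_pass(sc, similarities[1], "origin1")
    for (r in seq_len(max_rounds)) {
      before <- sc$sequence
      sc <- one_pass(sc, similarities[length(similarities)],
                     paste0("origin2.", r))
      if (identical(before, sc$sequence)) break
    }
    unchanged <- sc$circular & sc$sequence == rotated
    sc$sequence[unchanged] <- keep[unchanged]
  }
  list(scaffolds = sc[, c("id", "sequence", "circular")],
       changes = do.call(rbind, log), low_coverage = lowiv)
}
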