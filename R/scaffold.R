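#' Scaffolding parameters
#'
#' Defaults follow the long-read scaffolding procedure: only long reads of
#' at least 10 kb are used as framework, alignments must reach 90% identity,
#' a read anchors a contig when it covers the whole contig or at least 10 kb
#' (scaled to 90% of the contig for contigs shorter than 10 kb) at one of
#' its ends, and a connection requires support from at least three reads.
#'
#' @param min_read_len minimum long-read length (bp).
#' @param min_identity minimum alignment identity.
#' @param min_end_overlap partial end-overlap (bp) that qualifies a read as
#'   anchoring a contig.
#' @param min_support minimum number of supporting reads per connection.
#' @param small_contig_overlap_fraction for contigs shorter than
#'   `min_end_overlap`, the anchoring overlap is
#'   `small_contig_overlap_fraction * contig length`.
#' @param max_junction_gap maximum gap/overlap (bp) between the read
#'   projections of two adjacent contigs for the pair to count as a
#'   junction (rejects chimeric joins).
#' @param end_slop tolerance (bp) for an alignment to be considered to reach
#'   a contig end.
#' @return list of class `scaffold_params`.
#' @export
scaffold_params <- function(min_read_len = 10000, min_identity = 0.90,
                            min_end_overlap = 10000, min_support = 3,
                            small_contig_overlap_fraction = 0.9,
                            max_junction_gap = 1000, end_slop = 50) {
  stopifnot(min_support >= 1, min_identity > 0, min_identity <= 1)
  structure(list(min_read_len = min_read_len, min_identity = min_identity,
                 min_end_overlap = min_end_overlap, min_support = min_support,
                 small_contig_overlap_fraction = small_contig_overlap_fraction,
                 max_junction_gap = max_junction_gap, end_slop = end_slop),
            class = "scaffold_params")
}

# merge collinear fragments of the same (read, contig, strand) alignment
# that blast reports as separate local hits (typical for error-containing
# reads), then drop hits nested inside another hit's read interval
tidy_read_hits <- function(h, params) {
  if (nrow(h) == 0) return(h)
  out <- list()
  for (rid in unique(h$read_id)) {
    hr <- h[h$read_id == rid, , drop = FALSE]
    hr <- hr[order(hr$qlo, -hr$aln_len), , drop = FALSE]
    i <- 1
    while (i < nrow(hr)) {
      a <- hr[i, ]; b <- hr[i + 1, ]
      gap_q <- b$qlo - a$qhi - 1
      mergeable <- a$contig_id == b$contig_id && a$strand == b$strand &&
        gap_q <= params$max_junction_gap && gap_q >= -200 &&
        if (a$strand == "+") {
          gc <- b$slo - a$shi - 1
          b$slo > a$slo && abs(gc - gap_q) <= params$max_junction_gap
        } else {
          gc <- a$slo - b$shi - 1
          b$shi < a$shi && abs(gc - gap_q) <= params$max_junction_gap
        }
      if (mergeable) {
        tot <- a$aln_len + b$aln_len
        hr$identity[i] <- (a$identity * a$aln_len + b$identity * b$aln_len) / tot
        hr$aln_len[i] <- tot
        hr$qhi[i] <- max(a$qhi, b$qhi)
        hr$qlo[i] <- min(a$qlo, b$qlo)
        hr$slo[i] <- min(a$slo, b$slo)
        hr$shi[i] <- max(a$shi, b$shi)
        hr$bitscore[i] <- a$bitscore + b$bitscore
        hr <- hr[-(i + 1), , drop = FALSE]
      } else i <- i + 1
    }
    # drop hits nested within another hit's read interval
    if (nrow(hr) > 1) {
      nested <- vapply(seq_len(nrow(hr)), function(i) {
        any(hr$qlo[-i] <= hr$qlo[i] & hr$qhi[-i] >= hr$qhi[i] &
              hr$aln_len[-i] >= hr$aln_len[i])
      }, logical(1))
      hr <- hr[!nested, , drop = FALSE]
    }
    out[[rid]] <- hr
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# is a hit a strong anchor for its contig: full containment or a long
# contiguous overlap terminating at the given contig end ("5"/"3"/"any")
hit_is_strong <- function(hit, clen, params, end = "any") {
  slop <- params$end_slop
  full <- hit$slo <= 1 + slop && hit$shi >= clen - slop
  if (full) return(TRUE)
  need <- min(params$min_end_overlap,
              params$small_contig_overlap_fraction * clen)
  if (hit$shi - hit$slo + 1 < need) return(FALSE)
  at5 <- hit$slo <= 1 + slop
  at3 <- hit$shi >= clen - slop
  switch(end, "5" = at5, "3" = at3, at5 || at3)
}

hit_touches_end <- function(hit, clen, end, slop) {
  if (end == "5") hit$slo <= 1 + slop else hit$shi >= clen - slop
}

# per-read junction evidence: one row per adjacent pair of contigs on a
# read, in read orientation
read_chain_evidence <- function(hits, contig_len, params) {
  ev <- list(); tri <- list()
  for (rid in unique(hits$read_id)) {
    hr <- hits[hits$read_id == rid, , drop = FALSE]
    hr <- hr[order(hr$qlo), , drop = FALSE]
    if (nrow(hr) < 2) next
    for (i in seq_len(nrow(hr) - 1)) {
      a <- hr[i, ]; b <- hr[i + 1, ]
      la <- contig_len[[a$contig_id]]; lb <- contig_len[[b$contig_id]]
      gap_q <- b$qlo - a$qhi - 1
      if (abs(gap_q) > params$max_junction_gap) next
      # exit end of a (read direction): 3' if +, 5' if -
      exit_a <- if (a$strand == "+") "3" else "5"
      entry_b <- if (b$strand == "+") "5" else "3"
      if (!hit_touches_end(a, la, exit_a, params$end_slop)) next
      if (!hit_touches_end(b, lb, entry_b, params$end_slop)) next
      if (!(hit_is_strong(a, la, params, exit_a) ||
            hit_is_strong(b, lb, params, entry_b))) next
      ev[[length(ev) + 1]] <- data.frame(
        from = a$contig_id, s1 = a$strand, to = b$contig_id, s2 = b$strand,
        read = rid, q1lo = a$qlo, q1hi = a$qhi, s1lo = a$slo, s1hi = a$shi,
        q2lo = b$qlo, q2hi = b$qhi, s2lo = b$slo, s2hi = b$shi,
        jspan = b$qhi - a$qlo + 1, stringsAsFactors = FALSE)
    }
    if (nrow(hr) >= 3) {
      for (i in seq_len(nrow(hr) - 2)) {
        a <- hr[i, ]; r <- hr[i + 1, ]; b <- hr[i + 2, ]
        if (abs(r$qlo - a$qhi - 1) > params$max_junction_gap) next
        if (abs(b$qlo - r$qhi - 1) > params$max_junction_gap) next
        tri[[length(tri) + 1]] <- data.frame(
          a = a$contig_id, sa = a$strand, r = r$contig_id, sr = r$strand,
          b = b$contig_id, sb = b$strand, read = rid,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_ev <- data.frame(from = character(0), s1 = character(0),
                         to = character(0), s2 = character(0),
                         read = character(0), q1lo = integer(0),
                         q1hi = integer(0), s1lo = integer(0),
                         s1hi = integer(0), q2lo = integer(0),
                         q2hi = integer(0), s2lo = integer(0),
                         s2hi = integer(0), jspan = integer(0))
  empty_tri <- data.frame(a = character(0), sa = character(0),
                          r = character(0), sr = character(0),
                          b = character(0), sb = character(0),
                          read = character(0))
  list(ev = if (length(ev)) do.call(rbind, ev) else empty_ev,
       tri = if (length(tri)) do.call(rbind, tri) else empty_tri)
}

# partners reachable from (contig, ori) through its outgoing end, with
# per-partner support (distinct reads) and majority orientation
partners_of <- function(EV, contig, ori) {
  a <- EV[EV$from == contig & EV$s1 == ori, , drop = FALSE]
  b <- EV[EV$to == contig & EV$s2 == flip_strand(ori), , drop = FALSE]
  if (nrow(a) + nrow(b) == 0)
    return(data.frame(partner = character(0), p_ori = character(0),
                      support = integer(0)))
  d <- rbind(
    data.frame(partner = a$to, p_ori = a$s2, read = a$read,
               stringsAsFactors = FALSE),
    data.frame(partner = b$from, p_ori = flip_strand(b$s1), read = b$read,
               stringsAsFactors = FALSE))
  # support per (partner, orientation) as distinct reads
  key <- paste(d$partner, d$p_ori, sep = "\r")
  sup <- tapply(d$read, key, function(r) length(unique(r)))
  parts <- do.call(rbind, strsplit(names(sup), "\r", fixed = TRUE))
  po <- data.frame(partner = parts[, 1], p_ori = parts[, 2],
                   support = as.integer(sup), stringsAsFactors = FALSE)
  # per partner: majority orientation (ties toward "+")
  po <- po[order(po$partner, -po$support, po$p_ori), , drop = FALSE]
  tot <- tapply(po$support, po$partner, sum)
  po <- po[!duplicated(po$partner), , drop = FALSE]
  po$support <- as.integer(tot[po$partner])
  po <- po[order(-po$support, po$partner), , drop = FALSE]
  rownames(po) <- NULL
  po
}

# read-phased continuation beyond a repeat: contigs X seen on reads running
# prev(ori) -> rep(rori) -> X
phased_far_partners <- function(TRI, prev, pori, rep_id, rori) {
  f <- TRI[TRI$a == prev & TRI$sa == pori &
             TRI$r == rep_id & TRI$sr == rori, , drop = FALSE]
  r <- TRI[TRI$b == prev & TRI$sb == flip_strand(pori) &
             TRI$r == rep_id & TRI$sr == flip_strand(rori), , drop = FALSE]
  d <- rbind(data.frame(partner = f$b, p_ori = f$sb, read = f$read,
                        stringsAsFactors = FALSE),
             data.frame(partner = r$a, p_ori = flip_strand(r$sa),
                        read = r$read, stringsAsFactors = FALSE))
  if (nrow(d) == 0)
    return(data.frame(partner = character(0), p_ori = character(0),
                      support = integer(0)))
  key <- paste(d$partner, d$p_ori, sep = "\r")
  sup <- tapply(d$read, key, function(x) length(unique(x)))
  parts <- do.call(rbind, strsplit(names(sup), "\r", fixed = TRUE))
  po <- data.frame(partner = parts[, 1], p_ori = parts[, 2],
                   support = as.integer(sup), stringsAsFactors = FALSE)
  po[order(-po$support, po$partner), , drop = FALSE]
}

#' Collect long-read connection evidence for a seed contig
#'
#' Qualifying long reads (best hit to the seed at `min_identity` or better,
#' covering the entire seed or at least the configured end overlap at its 5'
#' or 3' end) are aligned to all contigs; adjacent contigs are read off the
#' collinear hit order on each read and aggregated per seed end.
#'
#' @param seed_id id of the seed contig.
#' @param contigs contig sequences (data.frame with `id`, `sequence`).
#' @param long_reads long-read sequences (data.frame).
#' @param params a [scaffold_params()] object.
#' @return data.frame of connections: seed end (5'/3'), partner, partner
#'   orientation, support and supporting reads.
#' @export
collect_connection_evidence <- function(seed_id, contigs, long_reads,
                                        params = scaffold_params()) {
  contigs <- as_seq_df_keep(contigs)
  long_reads <- long_reads[nchar(long_reads$sequence) >= params$min_read_len, ,
                           drop = FALSE]
  if (nrow(long_reads) == 0 || !seed_id %in% contigs$id)
    stop("no qualifying long reads or unknown seed contig")
  hits <- align_read_to_contigs(long_reads, contigs, params$min_identity)
  clen <- setNames(nchar(contigs$sequence), contigs$id)
  hits <- tidy_read_hits(hits, params)
  # qualifying reads: strong anchor on the seed
  seed_hits <- hits[hits$contig_id == seed_id, , drop = FALSE]
  ok_reads <- unique(seed_hits$read_id[vapply(seq_len(nrow(seed_hits)),
    function(i) hit_is_strong(seed_hits[i, ], clen[[seed_id]], params),
    logical(1))])
  hits <- hits[hits$read_id %in% ok_reads, , drop = FALSE]
  ch <- read_chain_evidence(hits, as.list(clen), params)
  out <- list()
  for (ori in c("+", "-")) {
    po <- partners_of(ch$ev, seed_id, ori)
    if (nrow(po)) {
      po$seed <- seed_id
      po$end <- if (ori == "+") "3'" else "5'"
      out[[ori]] <- po
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(partner = character(0), p_ori = character(0),
               support = integer(0), seed = character(0), end = character(0))
  rownames(res) <- NULL
  res[, c("seed", "end", "partner", "p_ori", "support")]
}

as_seq_df_keep <- function(x) {
  if (is.data.frame(x)) { stopifnot(all(c("id", "sequence") %in% names(x))); x }
  else as_seq_df(x)
}

#' Build scaffolds from selected contigs and long reads
#'
#' Seed-and-extend scaffolding: seeds are processed in descending length
#' order among unused non-repeat contigs; a connection is accepted when
#' supported by at least `min_support` reads and either the partner is the
#' only qualifying one or the top partner is a repeat-like contig. Extension
#' proceeds through a repeat-like contig only when the far side is
#' unambiguous (read-phased where possible); when a non-repeat end has two
#' or more qualifying partners, extension stops and the alternatives are
#' reported. Repeat-like contigs may be placed in several scaffolds; every
#' contig ends up in at least one scaffold. Junction sequence is filled from
#' the longest spanning read and terminal ends are tested for circularity.
#'
#' @param contigs data.frame with `id`, `sequence`, `copy_class` and
#'   `repeat_like` columns (from [assign_copy_class()]).
#' @param long_reads data.frame of long reads.
#' @param params a [scaffold_params()] object.
#' @return a list of class `scaffold_set` with elements `scaffolds` (list of
#'   per-scaffold lists: placements, circular flag, sequence, junction
#'   provenance), `summary` (data.frame), `adjacency_report` and `evidence`.
#' @export
build_scaffolds <- function(contigs, long_reads, params = scaffold_params()) {
  stopifnot(is.data.frame(contigs), all(c("id", "sequence") %in% names(contigs)))
  if (is.null(contigs$copy_class))
    stop("contigs lack copy_class; run assign_copy_class() first")
  if (is.null(contigs$repeat_like))
    contigs$repeat_like <- grepl("^(multiple|intermediate)", contigs$copy_class)
  reads <- long_reads[nchar(long_reads$sequence) >= params$min_read_len, ,
                      drop = FALSE]
  clen <- setNames(nchar(contigs$sequence), contigs$id)
  read_seq <- setNames(long_reads$sequence, long_reads$id)
  if (nrow(reads) > 0) {
    hits <- run_blastn(reads, contigs, min_identity = params$min_identity)
    hits <- tidy_read_hits(hits, params)
    ch <- read_chain_evidence(hits, as.list(clen), params)
  } else {
    ch <- read_chain_evidence(
      data.frame(read_id = character(0), contig_id = character(0),
                 identity = numeric(0), aln_len = integer(0),
                 qlo = integer(0), qhi = integer(0), slo = integer(0),
                 shi = integer(0), strand = character(0),
                 bitscore = numeric(0)), as.list(clen), params)
  }
  EV <- ch$ev; TRI <- ch$tri
  repeat_like <- setNames(contigs$repeat_like, contigs$id)

  used <- character(0)
  paths <- list()
  order_ids <- contigs$id[order(-nchar(contigs$sequence))]
  seeds <- order_ids[!repeat_like[order_ids]]

  extend_right <- function(path) {
    repeat {
      if (nrow(path) > 2 * nrow(contigs)) break
      C <- path$contig[nrow(path)]; p <- path$ori[nrow(path)]
      po <- partners_of(EV, C, p)
      q <- po[po$support >= params$min_support, , drop = FALSE]
      if (nrow(q) == 0) break
      top <- q[1, ]
      if (nrow(q) > 1 && !repeat_like[[top$partner]]) break # ambiguous end
      P <- top$partner; pori <- top$p_ori
      if (repeat_like[[P]]) {
        # place the repeat, then continue only if the far side is clear
        path <- rbind(path, data.frame(contig = P, ori = pori,
                                       stringsAsFactors = FALSE))
        ph <- phased_far_partners(TRI, C, p, P, pori)
        nxt <- NULL
        if (nrow(ph) >= 1 && (nrow(ph) == 1 ||
                              ph$support[1] > ph$support[2])) {
          nxt <- ph[1, ]
        } else if (nrow(ph) == 0) {
          far <- partners_of(EV, P, pori)
          farq <- far[far$support >= params$min_support, , drop = FALSE]
          if (nrow(farq) == 1) nxt <- farq[1, ]
        }
        if (is.null(nxt) || repeat_like[[nxt$partner]] ||
            nxt$partner %in% used || nxt$partner %in% path$contig) break
        path <- rbind(path, data.frame(contig = nxt$partner,
                                       ori = nxt$p_ori,
                                       stringsAsFactors = FALSE))
      } else {
        if (P %in% used || P %in% path$contig) break
        path <- rbind(path, data.frame(contig = P, ori = pori,
                                       stringsAsFactors = FALSE))
      }
    }
    path
  }
  reverse_path <- function(path)
    data.frame(contig = rev(path$contig), ori = flip_strand(rev(path$ori)),
               stringsAsFactors = FALSE)

  for (seed in seeds) {
    if (seed %in% used) next
    path <- data.frame(contig = seed, ori = "+", stringsAsFactors = FALSE)
    path <- extend_right(path)
    path <- reverse_path(extend_right(reverse_path(path)))
    # a repeat-like contig at both termini in the same orientation closes a
    # cycle through that repeat: emit the repeat once and flag the scaffold
    # circular (its wrap junction is the one that placed the trailing copy)
    if (nrow(path) > 2 && path$contig[1] == path$contig[nrow(path)] &&
        path$ori[1] == path$ori[nrow(path)] &&
        repeat_like[[path$contig[1]]]) {
      path <- path[-nrow(path), , drop = FALSE]
      attr(path, "circular") <- TRUE
    }
    used <- union(used, path$contig[!repeat_like[path$contig]])
    paths[[length(paths) + 1]] <- path
  }
  # leftover repeat contigs placed nowhere become singleton scaffolds
  placed <- unique(unlist(lapply(paths, function(p) p$contig)))
  for (cid in setdiff(contigs$id, placed))
    paths[[length(paths) + 1]] <- data.frame(contig = cid, ori = "+",
                                             stringsAsFactors = FALSE)

  cseq <- setNames(contigs$sequence, contigs$id)
  scaffolds <- list()
  for (i in seq_along(paths)) {
    path <- paths[[i]]
    circ <- isTRUE(attr(path, "circular")) || is_circular_path(EV, path, params)
    sc <- fill_junction_sequence(path, circ, EV, cseq, read_seq)
    sc$id <- sprintf("scaffold_%02d%s", i, if (circ) "_circ" else "")
    scaffolds[[i]] <- sc
  }
  # adjacency report: all supported partners per contig end
  rep_rows <- list()
  for (cid in contigs$id) {
    for (ori in c("+", "-")) {
      po <- partners_of(EV, cid, ori)
      if (nrow(po)) {
        po$contig <- cid
        po$end <- if (ori == "+") "3'" else "5'"
        rep_rows[[length(rep_rows) + 1]] <- po
      }
    }
  }
  adjacency <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(partner = character(0), p_ori = character(0),
               support = integer(0), contig = character(0),
               end = character(0))
  adjacency <- adjacency[, c("contig", "end", "partner", "p_ori", "support")]
  adjacency <- adjacency[order(adjacency$contig, adjacency$end,
                               -adjacency$support), , drop = FALSE]
  rownames(adjacency) <- NULL

  summary <- data.frame(
    id = vapply(scaffolds, `[[`, character(1), "id"),
    length = vapply(scaffolds, function(s) nchar(s$sequence), numeric(1)),
    n_contigs = vapply(scaffolds, function(s) nrow(s$placements), numeric(1)),
    circular = vapply(scaffolds, `[[`, logical(1), "circular"),
    stringsAsFactors = FALSE)
  structure(list(scaffolds = scaffolds, summary = summary,
                 adjacency_report = adjacency, evidence = EV,
                 params = params),
            class = "scaffold_set")
}

# does read evidence link the two termini of a path in consistent
# orientation with sufficient support
is_circular_path <- function(EV, path, params) {
  C2 <- path$contig[nrow(path)]; p2 <- path$ori[nrow(path)]
  C1 <- path$contig[1]; p1 <- path$ori[1]
  if (nrow(path) == 1) {
    self <- EV[EV$from == C1 & EV$to == C1 & EV$s1 == EV$s2, , drop = FALSE]
    return(length(unique(self$read)) >= params$min_support)
  }
  po <- partners_of(EV, C2, p2)
  hit <- po[po$partner == C1 & po$p_ori == p1, , drop = FALSE]
  nrow(hit) > 0 && hit$support[1] >= params$min_support
}

#' Test a scaffold for circularity
#'
#' A scaffold is flagged circular when at least `min_support` qualifying
#' long reads link its two terminal contig ends in consistent orientation.
#'
#' @param placements data.frame with `contig` and `ori` columns describing
#'   the scaffold path.
#' @param contigs contig sequences (data.frame).
#' @param long_reads long reads (data.frame).
#' @param params a [scaffold_params()] object.
#' @return logical flag.
#' @export
detect_circularity <- function(placements, contigs, long_reads,
                               params = scaffold_params()) {
  stopifnot(nrow(placements) >= 1)
  contigs <- as_seq_df_keep(contigs)
  reads <- long_reads[nchar(long_reads$sequence) >= params$min_read_len, ,
                      drop = FALSE]
  clen <- setNames(nchar(contigs$sequence), contigs$id)
  if (nrow(reads) == 0) return(FALSE)
  hits <- run_blastn(reads, contigs, min_identity = params$min_identity)
  hits <- tidy_read_hits(hits, params)
  ch <- read_chain_evidence(hits, as.list(clen), params)
  is_circular_path(ch$ev, placements, params)
}

# pick the junction row between (C1,p1)->(C2,p2) with the longest read span;
# returns the row plus whether it must be read in reverse
best_junction_row <- function(EV, C1, p1, C2, p2) {
  a <- EV[EV$from == C1 & EV$s1 == p1 & EV$to == C2 & EV$s2 == p2, ,
          drop = FALSE]
  b <- EV[EV$from == C2 & EV$s1 == flip_strand(p2) &
            EV$to == C1 & EV$s2 == flip_strand(p1), , drop = FALSE]
  if (nrow(a) + nrow(b) == 0) return(NULL)
  a$reversed <- rep(FALSE, nrow(a)); b$reversed <- rep(TRUE, nrow(b))
  d <- rbind(a, b)
  d[which.max(d$jspan), , drop = FALSE]
}

# junction geometry in scaffold orientation: returns the read-derived insert
# between the oriented end of C1 and the oriented start of C2, or the number
# of duplicated bases to trim from C2's start
junction_insert <- function(row, read_seq, len1, len2) {
  if (row$reversed) {
    L <- nchar(read_seq[[row$read]])
    rseq <- revcomp(read_seq[[row$read]])
    h1 <- list(qlo = L - row$q2hi + 1, qhi = L - row$q2lo + 1,
               slo = row$s2lo, shi = row$s2hi, strand = flip_strand(row$s2))
    h2 <- list(qlo = L - row$q1hi + 1, qhi = L - row$q1lo + 1,
               slo = row$s1lo, shi = row$s1hi, strand = flip_strand(row$s1))
  } else {
    rseq <- read_seq[[row$read]]
    h1 <- list(qlo = row$q1lo, qhi = row$q1hi, slo = row$s1lo,
               shi = row$s1hi, strand = row$s1)
    h2 <- list(qlo = row$q2lo, qhi = row$q2hi, slo = row$s2lo,
               shi = row$s2hi, strand = row$s2)
  }
  u1 <- if (h1$strand == "+") len1 - h1$shi else h1$slo - 1
  a2 <- if (h2$strand == "+") h2$slo - 1 else len2 - h2$shi
  r1 <- h1$qhi + u1
  r2 <- h2$qlo - a2
  if (r2 > r1 + 1)
    list(insert = substr(rseq, r1 + 1, r2 - 1), trim = 0L, read = row$read)
  else
    list(insert = "", trim = as.integer(r1 - r2 + 1), read = row$read)
}

# assemble the scaffold sequence for a path, filling junctions from the
# longest spanning read
fill_junction_sequence <- function(path, circular, EV, cseq, read_seq) {
  oriented <- function(i) {
    s <- cseq[[path$contig[i]]]
    if (path$ori[i] == "-") revcomp(s) else s
  }
  seq <- oriented(1)
  placements <- data.frame(contig = path$contig[1], orientation = path$ori[1],
                           start = 1L, end = nchar(seq),
                           stringsAsFactors = FALSE)
  junctions <- data.frame(after_contig = character(0), best_read = character(0),
                          ins_start = integer(0), ins_end = integer(0),
                          trim = integer(0), stringsAsFactors = FALSE)
  if (nrow(path) > 1) {
    for (i in seq_len(nrow(path) - 1)) {
      row <- best_junction_row(EV, path$contig[i], path$ori[i],
                               path$contig[i + 1], path$ori[i + 1])
      if (is.null(row))
        stop("no spanning read for junction ", path$contig[i], " -> ",
             path$contig[i + 1])
      len2 <- nchar(cseq[[path$contig[i + 1]]])
      j <- junction_insert(row, read_seq, nchar(cseq[[path$contig[i]]]), len2)
      cur <- nchar(seq)
      nxt <- substr(oriented(i + 1), j$trim + 1, len2)
      seq <- paste0(seq, j$insert, nxt)
      ins_len <- nchar(j$insert)
      junctions <- rbind(junctions, data.frame(
        after_contig = path$contig[i], best_read = j$read,
        ins_start = if (ins_len > 0) cur + 1L else NA_integer_,
        ins_end = if (ins_len > 0) cur + ins_len else NA_integer_,
        trim = j$trim, stringsAsFactors = FALSE))
      placements <- rbind(placements, data.frame(
        contig = path$contig[i + 1], orientation = path$ori[i + 1],
        start = cur + ins_len + 1L, end = cur + ins_len + len2 - j$trim,
        stringsAsFactors = FALSE))
    }
  }
  if (circular) {
    row <- best_junction_row(EV, path$contig[nrow(path)], path$ori[nrow(path)],
                             path$contig[1], path$ori[1])
    if (!is.null(row)) {
      len1 <- nchar(cseq[[path$contig[nrow(path)]]])
      len2 <- nchar(cseq[[path$contig[1]]])
      j <- junction_insert(row, read_seq, len1, len2)
      cur <- nchar(seq)
      if (nchar(j$insert) > 0) {
        seq <- paste0(seq, j$insert)
        junctions <- rbind(junctions, data.frame(
          after_contig = path$contig[nrow(path)], best_read = j$read,
          ins_start = cur + 1L, ins_end = cur + nchar(j$insert), trim = 0L,
          stringsAsFactors = FALSE))
      } else if (j$trim > 0) {
        # terminal bases duplicate the scaffold start; emit them once
        seq <- substr(seq, 1, nchar(seq) - j$trim)
        placements$end[nrow(placements)] <-
          min(placements$end[nrow(placements)], nchar(seq))
      }
    }
  }
  list(placements = placements, circular = circular, sequence = seq,
       junctions = junctions)
}

#' Compare scaffold adjacencies against a truth junction table
#'
#' Canonicalizes oriented adjacencies (an adjacency and its reverse
#' complement are the same junction) and computes recall and false
#' adjacencies of a scaffold set against the simulated truth.
#'
#' @param scaffold_set result of [build_scaffolds()].
#' @param truth a `mito_truth` object.
#' @return list with `recall`, `n_true`, `n_pred`, `false_adjacencies`,
#'   `missing` and `spurious` adjacency keys.
#' @export
scaffold_accuracy <- function(scaffold_set, truth) {
  canon <- function(a, oa, b, ob) {
    k1 <- paste(a, oa, b, ob)
    k2 <- paste(b, flip_strand(ob), a, flip_strand(oa))
    ifelse(k1 <= k2, k1, k2)
  }
  tj <- truth$junctions
  true_keys <- unique(canon(tj$from_id, tj$from_ori, tj$to_id, tj$to_ori))
  pred <- character(0)
  for (sc in scaffold_set$scaffolds) {
    p <- sc$placements
    if (nrow(p) > 1)
      pred <- c(pred, canon(p$contig[-nrow(p)], p$orientation[-nrow(p)],
                            p$contig[-1], p$orientation[-1]))
    if (sc$circular && nrow(p) >= 1)
      pred <- c(pred, canon(p$contig[nrow(p)], p$orientation[nrow(p)],
                            p$contig[1], p$orientation[1]))
  }
  pred <- unique(pred)
  list(recall = if (length(true_keys)) mean(true_keys %in% pred) else NA_real_,
       n_true = length(true_keys), n_pred = length(pred),
       false_adjacencies = sum(!pred %in% true_keys),
       missing = setdiff(true_keys, pred),
       spurious = setdiff(pred, true_keys))
}
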