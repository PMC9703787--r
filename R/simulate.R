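#' Simulation configuration for synthetic multipartite mitogenomes
#'
#' Builds the configuration consumed by [simulate_mitogenome()] and the read
#' simulators. Defaults emulate the structure reported for conifer
#' mitogenomes: a multipartite genome of unique segments and interspersed
#' repeat families, a GC content near 0.46, long reads with a mean length
#' around 14 kb, and 2 x 150 bp paired short reads. The default genome scale
#' (roughly 100-300 kb) keeps full test suites fast; all thresholds scale
#' with the configuration.
#'
#' @param seed integer seed; all generators are bit-reproducible given the
#'   seed.
#' @param gc_target target GC fraction of simulated sequence.
#' @param n_unique_segments number of unique (single-copy) segments.
#' @param unique_len_range length range (bp) for unique segments.
#' @param n_repeat_families number of interspersed repeat families.
#' @param repeat_len_mixture list with `p_bulk`, `bulk_range`, `tail_range`:
#'   repeat unit lengths are drawn from `bulk_range` (uniform) with
#'   probability `p_bulk` and from the heavy tail `tail_range` otherwise,
#'   mirroring the observed size mixture of interspersed repeats (bulk 50-200
#'   bp, rare copies of 10 kb and more).
#' @param repeat_copies genomic placements per repeat family (>= 2).
#' @param molecules `"random"` for an automatic layout, or a list of molecule
#'   specs `list(id=, circular=, copies=, layout = c("U01","R01",...))`.
#'   Element ids matching `^R` are repeat families.
#' @param n_molecules number of molecules for the random layout.
#' @param circular_molecules which molecules are circular in the random
#'   layout (indices; default the first).
#' @param stoichiometry per-molecule copy multipliers (>= 1) for the random
#'   layout; recycled.
#' @param n_alt_junctions number of repeat families whose placements are
#'   forced into different molecules, realizing alternative junctions
#'   (A-R-B and C-R-D).
#' @param mtpt_spec list `n_inserts`, `insert_len_range`, `identity` for
#'   [plant_mtpts()].
#' @param long_read_spec list `mean_len`, `sdlog`, `min_len`, `error_rate`,
#'   `depth` (see [simulate_long_reads()]). Errors are split between
#'   substitutions (50%) and insertions/deletions (25% each).
#' @param short_read_spec list `read_len`, `insert_size`, `insert_sd`,
#'   `depth`, `error_rate` (see [simulate_short_reads()]).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       gc_target = 0.46,
                       n_unique_segments = 10,
                       unique_len_range = c(8000, 25000),
                       n_repeat_families = 2,
                       repeat_len_mixture = list(p_bulk = 0.8,
                                                 bulk_range = c(50, 200),
                                                 tail_range = c(10000, 15000)),
                       repeat_copies = 2,
                       molecules = "random",
                       n_molecules = 2,
                       circular_molecules = 1,
                       stoichiometry = 1,
                       n_alt_junctions = 1,
                       mtpt_spec = list(n_inserts = 0,
                                        insert_len_range = c(200, 2000),
                                        identity = 1.0),
                       long_read_spec = list(mean_len = 14000, sdlog = 0.35,
                                             min_len = 1000, error_rate = 0,
                                             depth = 10,
                                             min_junction_depth = 0),
                       short_read_spec = list(read_len = 150, insert_size = 400,
                                              insert_sd = 40, depth = 30,
                                              error_rate = 0)) {
  cfg <- list(seed = as.integer(seed), gc_target = gc_target,
              n_unique_segments = n_unique_segments,
              unique_len_range = unique_len_range,
              n_repeat_families = n_repeat_families,
              repeat_len_mixture = repeat_len_mixture,
              repeat_copies = repeat_copies,
              molecules = molecules, n_molecules = n_molecules,
              circular_molecules = circular_molecules,
              stoichiometry = stoichiometry,
              n_alt_junctions = n_alt_junctions,
              mtpt_spec = mtpt_spec,
              long_read_spec = long_read_spec,
              short_read_spec = short_read_spec)
  stopifnot(cfg$n_unique_segments >= 0, cfg$n_repeat_families >= 0,
            cfg$repeat_copies >= 2 || cfg$n_repeat_families == 0,
            all(unlist(stoichiometry) >= 1),
            cfg$mtpt_spec$identity >= 0, cfg$mtpt_spec$identity <= 1,
            cfg$long_read_spec$error_rate >= 0, cfg$long_read_spec$error_rate <= 1,
            cfg$short_read_spec$error_rate >= 0, cfg$short_read_spec$error_rate <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# recompute molecule sequences, coordinates, junction table and repeat
# placements from element sequences and layouts
rebuild_molecules <- function(truth) {
  elements <- truth$elements
  etype <- truth$element_type
  mol_ids <- names(truth$layouts)
  seqs <- character(length(mol_ids))
  placements <- list()
  junctions <- list()
  offsets <- list()
  for (mi in seq_along(mol_ids)) {
    m <- mol_ids[mi]
    lay <- truth$layouts[[m]]
    lens <- nchar(elements[lay])
    starts <- cumsum(c(1, head(lens, -1)))
    ends <- starts + lens - 1
    seqs[mi] <- paste(elements[lay], collapse = "")
    offsets[[m]] <- data.frame(element = lay, start = starts, end = ends,
                               stringsAsFactors = FALSE)
    rep_i <- which(etype[lay] == "repeat")
    if (length(rep_i))
      placements[[m]] <- data.frame(family = lay[rep_i], molecule = m,
                                    start = starts[rep_i], end = ends[rep_i],
                                    strand = "+", stringsAsFactors = FALSE)
    if (length(lay) > 1) {
      junctions[[m]] <- data.frame(from_id = lay[-length(lay)], from_ori = "+",
                                   to_id = lay[-1], to_ori = "+",
                                   molecule = m, stringsAsFactors = FALSE)
    }
    if (isTRUE(truth$circular[[m]])) {
      wrap <- data.frame(from_id = lay[length(lay)], from_ori = "+",
                         to_id = lay[1], to_ori = "+", molecule = m,
                         stringsAsFactors = FALSE)
      junctions[[paste0(m, "_wrap")]] <- wrap
    }
  }
  truth$molecules <- data.frame(
    id = mol_ids,
    circular = unlist(truth$circular[mol_ids], use.names = FALSE),
    copies = unlist(truth$copies[mol_ids], use.names = FALSE),
    length = nchar(seqs), sequence = seqs, stringsAsFactors = FALSE)
  truth$element_offsets <- offsets
  truth$repeat_placements <- if (length(placements))
    do.call(rbind, unname(placements)) else
    data.frame(family = character(0), molecule = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  truth$junctions <- if (length(junctions))
    do.call(rbind, unname(junctions)) else
    data.frame(from_id = character(0), from_ori = character(0),
               to_id = character(0), to_ori = character(0),
               molecule = character(0))
  rownames(truth$junctions) <- NULL
  # molecule-level coordinates of planted MTPTs (tracked per segment)
  if (nrow(truth$mtpt_truth)) {
    mt <- truth$mtpt_truth
    mt$molecule <- NA_character_; mt$start <- NA_integer_; mt$end <- NA_integer_
    for (i in seq_len(nrow(mt))) {
      for (m in mol_ids) {
        off <- offsets[[m]]
        j <- which(off$element == mt$segment[i])
        if (length(j)) {
          mt$molecule[i] <- m
          mt$start[i] <- off$start[j[1]] + mt$seg_start[i] - 1L
          mt$end[i] <- off$start[j[1]] + mt$seg_end[i] - 1L
          break
        }
      }
    }
    truth$mtpt_truth <- mt
  }
  # expected relative coverage per element: genomic copies weighted by
  # molecule stoichiometry, normalized to single-copy = 1
  counts <- vapply(names(elements), function(e) {
    sum(vapply(mol_ids, function(m)
      sum(truth$layouts[[m]] == e) * truth$copies[[m]], numeric(1)))
  }, numeric(1))
  truth$contig_truth <- data.frame(id = names(elements),
                                   type = unname(etype[names(elements)]),
                                   expected_rel_cov = unname(counts),
                                   stringsAsFactors = FALSE)
  truth
}

#' Simulate a ground-truthed multipartite mitogenome
#'
#' Generates unique segments and interspersed repeat families, arranges them
#' into circular and linear molecules with per-molecule stoichiometry, and
#' returns the full ground truth (molecules, junction table, repeat
#' placements, expected relative coverages). Repeat copies are planted
#' verbatim, so the same repeat family between different unique-segment
#' pairs realizes alternative junctions.
#'
#' @param cfg a [sim_config()] object.
#' @return a list of class `mito_truth`.
#' @export
simulate_mitogenome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  explicit <- is.list(cfg$molecules)

  if (explicit) {
    mol_specs <- cfg$molecules
    ids <- vapply(seq_along(mol_specs), function(i)
      mol_specs[[i]]$id %||% paste0("mol", i), character(1))
    layouts <- setNames(lapply(mol_specs, function(s) s$layout), ids)
    circular <- setNames(lapply(mol_specs, function(s) isTRUE(s$circular)), ids)
    copies <- setNames(lapply(mol_specs, function(s) s$copies %||% 1), ids)
    el_ids <- unique(unlist(layouts))
    etype <- setNames(ifelse(grepl("^R", el_ids), "repeat", "unique"), el_ids)
  } else {
    nu <- cfg$n_unique_segments
    nr <- cfg$n_repeat_families
    nm <- cfg$n_molecules
    if (nu < nm) stop("config error: fewer unique segments than molecules")
    u_ids <- sprintf("U%02d", seq_len(nu))
    r_ids <- if (nr > 0) sprintf("R%02d", seq_len(nr)) else character(0)
    el_ids <- c(u_ids, r_ids)
    etype <- setNames(c(rep("unique", nu), rep("repeat", nr)), el_ids)
    # contiguous partition of unique segments over molecules
    cut <- sort(sample(seq_len(nu - 1), nm - 1)) # breakpoints
    grp <- findInterval(seq_len(nu), c(0, cut) + 1)
    ids <- sprintf("mol%d", seq_len(nm))
    layouts <- setNames(lapply(seq_len(nm), function(m) u_ids[grp == m]), ids)
    circular <- setNames(as.list(seq_len(nm) %in% cfg$circular_molecules), ids)
    copies <- setNames(as.list(rep_len(cfg$stoichiometry, nm)), ids)
    # repeat placement into inter-segment slots (one repeat per slot)
    if (nr > 0) {
      slots <- do.call(rbind, lapply(ids, function(m) {
        L <- length(layouts[[m]])
        if (L < 2) return(NULL)
        data.frame(molecule = m, after = seq_len(L - 1),
                   stringsAsFactors = FALSE)
      }))
      need <- nr * cfg$repeat_copies
      if (is.null(slots) || nrow(slots) < need)
        stop("config error: infeasible layout, not enough junction slots (",
             if (is.null(slots)) 0 else nrow(slots), ") for ", need,
             " repeat placements")
      slots <- slots[sample(nrow(slots)), , drop = FALSE]
      taken <- 0
      assign_rows <- list()
      for (f in seq_len(nr)) {
        fam <- r_ids[f]
        if (f <= cfg$n_alt_junctions && length(unique(slots$molecule)) > 1) {
          # force placements into >= 2 different molecules
          avail <- slots[(taken + 1):nrow(slots), , drop = FALSE]
          m1 <- avail$molecule[1]
          other <- which(avail$molecule != m1)
          if (length(other) == 0) {
            pick <- seq_len(cfg$repeat_copies)
          } else {
            pick <- c(1, other[1])
            if (cfg$repeat_copies > 2) {
              rest <- setdiff(seq_len(nrow(avail)), pick)
              pick <- c(pick, rest[seq_len(cfg$repeat_copies - 2)])
            }
          }
          sel <- avail[pick, , drop = FALSE]
          # compact remaining slots
          slots <- rbind(slots[seq_len(taken), , drop = FALSE],
                         avail[-pick, , drop = FALSE])
        } else {
          sel <- slots[(taken + 1):(taken + cfg$repeat_copies), , drop = FALSE]
          taken <- taken + cfg$repeat_copies
        }
        sel$family <- fam
        assign_rows[[f]] <- sel
      }
      assign_df <- do.call(rbind, assign_rows)
      # insert repeats into layouts, descending slot index per molecule so
      # earlier insertions do not shift later ones
      for (m in unique(assign_df$molecule)) {
        rows <- assign_df[assign_df$molecule == m, , drop = FALSE]
        rows <- rows[order(-rows$after), , drop = FALSE]
        lay <- layouts[[m]]
        for (i in seq_len(nrow(rows))) {
          a <- rows$after[i]
          lay <- append(lay, rows$family[i], after = a)
        }
        layouts[[m]] <- lay
      }
    }
  }

  # element sequences
  elements <- character(length(etype))
  names(elements) <- names(etype)
  for (e in names(etype)) {
    if (etype[[e]] == "unique") {
      len <- if (explicit) NA else
        sample(cfg$unique_len_range[1]:cfg$unique_len_range[2], 1)
      if (explicit)
        len <- sample(cfg$unique_len_range[1]:cfg$unique_len_range[2], 1)
      elements[[e]] <- random_dna(len, cfg$gc_target)
    } else {
      mx <- cfg$repeat_len_mixture
      len <- if (runif(1) < mx$p_bulk)
        sample(mx$bulk_range[1]:mx$bulk_range[2], 1)
      else sample(mx$tail_range[1]:mx$tail_range[2], 1)
      elements[[e]] <- random_dna(len, cfg$gc_target)
    }
  }

  truth <- list(config = cfg, elements = elements, element_type = etype,
                layouts = layouts, circular = circular, copies = copies,
                mtpt_truth = data.frame(segment = character(0),
                                        seg_start = integer(0),
                                        seg_end = integer(0),
                                        p_start = integer(0),
                                        p_end = integer(0),
                                        strand = character(0),
                                        identity = numeric(0)))
  truth <- rebuild_molecules(truth)
  class(truth) <- "mito_truth"
  truth
}

# pool of mitochondrial gene names used to label synthetic gene hits
MITO_GENES <- c("cox1", "cox2", "cox3", "nad1", "nad2", "nad3", "nad4",
                "nad5", "nad6", "nad7", "nad9", "atp1", "atp4", "atp6",
                "atp8", "atp9", "cob", "ccmB", "ccmC", "matR", "mttB",
                "rps3", "rps4", "rpl2", "rpl5", "rrn18", "rrn26", "trnM")

#' Decompose a simulated genome into assembler-style contigs
#'
#' Emulates the outcome of a short-read assembly on a repeat-bearing genome:
#' one contig per unique segment and one collapsed contig per repeat family,
#' with per-contig mean coverage equal to `base_depth` times the element's
#' expected relative coverage, perturbed by multiplicative Gaussian noise.
#' A subset of contigs is labelled with mitochondrial gene hits (truth
#' labels standing in for BLAST hits against other mitogenomes).
#'
#' @param truth a `mito_truth` object.
#' @param base_depth single-copy mean coverage (x).
#' @param noise_cv coefficient of variation of the multiplicative coverage
#'   noise (0 for noise-free coverage).
#' @param gene_frac fraction of contigs receiving a gene-hit label; the
#'   largest unique contig always receives one so that selection criterion 1
#'   is applicable.
#' @return list with `contigs` (data.frame: id, sequence, length, mean_cov,
#'   gene_hits) and `coverage` (data.frame: id, mean_cov).
#' @export
fragment_to_contigs <- function(truth, base_depth = 89, noise_cv = 0.05,
                                gene_frac = 0.5) {
  stopifnot(inherits(truth, "mito_truth"))
  set.seed(truth$config$seed + 1L)
  ct <- truth$contig_truth
  ct <- ct[ct$expected_rel_cov > 0, , drop = FALSE]
  noise <- if (noise_cv > 0) pmax(0.2, 1 + rnorm(nrow(ct), 0, noise_cv)) else
    rep(1, nrow(ct))
  cov <- base_depth * ct$expected_rel_cov * noise
  seqs <- truth$elements[ct$id]
  genes <- rep("", nrow(ct))
  hit <- runif(nrow(ct)) < gene_frac
  # ensure criterion 1 is applicable: largest unique contig gets a hit
  uni <- which(ct$type == "unique")
  if (length(uni)) hit[uni[which.max(nchar(seqs[uni]))]] <- TRUE
  genes[hit] <- MITO_GENES[((which(hit) - 1) %% length(MITO_GENES)) + 1]
  contigs <- data.frame(id = ct$id, sequence = unname(seqs),
                        length = nchar(seqs), mean_cov = round(cov, 1),
                        gene_hits = genes, stringsAsFactors = FALSE)
  list(contigs = contigs,
       coverage = data.frame(id = contigs$id, mean_cov = contigs$mean_cov,
                             stringsAsFactors = FALSE))
}

#' Simulate PacBio-style long reads from a simulated genome
#'
#' Reads are sampled proportionally to molecule length times stoichiometry;
#' lengths follow a log-normal distribution (truncated to
#' \[`min_len`, molecule length\]); reads from circular molecules may span
#' the origin; strands are uniform; substitution and indel errors are
#' applied at the configured rate (50% substitutions, 25% insertions, 25%
#' deletions).
#'
#' When `min_junction_depth` is positive, the sampler additionally
#' guarantees the stated study condition that every inter-segment junction
#' is spanned by at least that many reads carrying a full scaffolding
#' anchor (about 10.5 kb, or the whole flanking segment when shorter, on
#' the upstream side): junctions left under-covered by the random draw
#' receive deterministic top-up reads.
#'
#' @param truth a `mito_truth` object.
#' @param spec overrides for `truth$config$long_read_spec` (fields
#'   `mean_len`, `sdlog`, `min_len`, `error_rate`, `depth`,
#'   `min_junction_depth`).
#' @return data.frame with `id`, `description` (truth provenance),
#'   `sequence`.
#' @export
simulate_long_reads <- function(truth, spec = NULL) {
  stopifnot(inherits(truth, "mito_truth"))
  s <- utils::modifyList(truth$config$long_read_spec, spec %||% list())
  if (is.null(s$min_junction_depth)) s$min_junction_depth <- 0
  stopifnot(s$depth > 0)
  set.seed(truth$config$seed + 2L)
  mols <- truth$molecules
  if (all(s$mean_len > mols$length))
    stop("mean read length exceeds every molecule length")
  w <- mols$length * mols$copies
  total <- sum(w)
  n <- max(1L, round(s$depth * total / s$mean_len))
  meanlog <- log(s$mean_len) - s$sdlog^2 / 2
  mi <- sample(nrow(mols), n, replace = TRUE, prob = w)
  lens <- round(rlnorm(n, meanlog, s$sdlog))
  lens <- pmax(pmin(lens, mols$length[mi]), pmin(s$min_len, mols$length[mi]))
  starts <- integer(n)
  for (i in seq_len(n)) {
    starts[i] <- if (mols$circular[mi[i]]) sample.int(mols$length[mi[i]], 1)
    else sample.int(mols$length[mi[i]] - lens[i] + 1L, 1)
  }
  if (s$min_junction_depth > 0) {
    # junction coverage guarantee: a read counts for a junction when it
    # covers `left_need` bases upstream (full anchoring overlap) and
    # `margin_r` bases downstream of the boundary
    margin_l <- 10500; margin_r <- 600
    covers <- function(mm, st, ln, w_start, w_len, L, circ) {
      if (circ) ((w_start - st) %% L) + w_len <= ln
      else st <= w_start && st + ln - 1L >= w_start + w_len - 1L
    }
    for (m_i in seq_len(nrow(mols))) {
      m <- mols$id[m_i]; L <- mols$length[m_i]; circ <- mols$circular[m_i]
      off <- truth$element_offsets[[m]]
      bpos <- off$end
      if (!circ) bpos <- bpos[-length(bpos)]
      if (!length(bpos)) next
      for (b in bpos) {
        # a read anchors the upstream segment once it covers the whole
        # segment or 90% of it (whichever the scaffolding rule requires),
        # so the guaranteed window never needs more than ~92% of it
        len_up <- off$end[off$end == b] - off$start[off$end == b] + 1L
        left_need <- min(margin_l, b, ceiling(0.92 * len_up))
        right_need <- if (circ) margin_r else min(margin_r, L - b)
        w_start <- b - left_need + 1L
        w_len <- left_need + right_need
        if (circ) w_start <- ((w_start - 1L) %% L) + 1L
        idx <- which(mi == m_i)
        have <- sum(vapply(idx, function(i)
          covers(m_i, starts[i], lens[i], w_start, w_len, L, circ),
          logical(1)))
        n_add <- s$min_junction_depth - have
        if (n_add <= 0) next
        for (a in seq_len(n_add)) {
          lt <- min(L, w_len + 1500L + sample.int(1500L, 1))
          pad <- sample.int(max(1L, lt - w_len), 1) - 1L
          st <- b - left_need + 1L - pad
          if (circ) st <- ((st - 1L) %% L) + 1L
          else st <- max(1L, min(st, L - lt + 1L))
          mi <- c(mi, m_i); starts <- c(starts, st); lens <- c(lens, lt)
        }
      }
    }
    n <- length(mi)
  }
  strands <- sample(c("+", "-"), n, replace = TRUE)
  sub_r <- s$error_rate * 0.5; ind_r <- s$error_rate * 0.25
  seqs <- character(n)
  for (i in seq_len(n)) {
    raw <- if (mols$circular[mi[i]])
      circ_substr(mols$sequence[mi[i]], starts[i], lens[i])
    else substr(mols$sequence[mi[i]], starts[i], starts[i] + lens[i] - 1L)
    if (strands[i] == "-") raw <- revcomp(raw)
    seqs[i] <- if (s$error_rate > 0)
      mutate_seq(raw, sub_r, ind_r, ind_r) else raw
  }
  data.frame(id = sprintf("lr%05d", seq_len(n)),
             description = sprintf("mol=%s start=%d len=%d strand=%s",
                                   mols$id[mi], starts, lens, strands),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Simulate paired-end short reads from a simulated genome
#'
#' Paired 2 x `read_len` bp reads with Gaussian insert sizes, sampled
#' proportionally to molecule stoichiometry; substitution errors only.
#'
#' @param truth a `mito_truth` object.
#' @param spec overrides for `truth$config$short_read_spec`.
#' @return list with `read1` and `read2` data.frames (`id`, `sequence`).
#' @export
simulate_short_reads <- function(truth, spec = NULL) {
  stopifnot(inherits(truth, "mito_truth"))
  s <- utils::modifyList(truth$config$short_read_spec, spec %||% list())
  stopifnot(s$depth > 0)
  if (s$insert_size < 2 * s$read_len)
    stop("insert size must be at least twice the read length")
  set.seed(truth$config$seed + 3L)
  mols <- truth$molecules
  w <- mols$length * mols$copies
  total <- sum(w)
  if (total == 0) stop("zero-length truth: no molecule sequence to sample")
  if (all(mols$length < s$insert_size))
    stop("insert size exceeds every molecule length")
  rl <- s$read_len
  n <- max(1L, round(s$depth * total / (2 * rl)))
  mi <- sample(nrow(mols), n, replace = TRUE, prob = w)
  flen <- pmax(2L * rl, round(rnorm(n, s$insert_size, s$insert_sd)))
  flen <- pmin(flen, mols$length[mi])
  # sample fragment starts; circular molecules wrap through a doubled string
  starts <- integer(n)
  circ <- mols$circular[mi]
  starts[circ] <- vapply(which(circ), function(i)
    sample.int(mols$length[mi[i]], 1), integer(1))
  starts[!circ] <- vapply(which(!circ), function(i)
    sample.int(mols$length[mi[i]] - flen[i] + 1L, 1), integer(1))
  doubled <- paste0(mols$sequence, substr(mols$sequence, 1,
                                          pmin(nchar(mols$sequence), s$insert_size + 4 * s$insert_sd)))
  frag_src <- ifelse(circ, doubled[mi], mols$sequence[mi])
  frags <- substr(frag_src, starts, starts + flen - 1L)
  r1 <- substr(frags, 1, rl)
  r2 <- revcomp(substr(frags, flen - rl + 1L, flen))
  if (s$error_rate > 0) {
    r1 <- vapply(r1, mutate_seq, character(1), sub_rate = s$error_rate,
                 USE.NAMES = FALSE)
    r2 <- vapply(r2, mutate_seq, character(1), sub_rate = s$error_rate,
                 USE.NAMES = FALSE)
  }
  ids <- sprintf("sr%06d", seq_len(n))
  list(read1 = data.frame(id = paste0(ids, "/1"), sequence = r1,
                          stringsAsFactors = FALSE),
       read2 = data.frame(id = paste0(ids, "/2"), sequence = r2,
                          stringsAsFactors = FALSE))
}

#' Plant plastome-derived inserts (MTPTs) into a simulated genome
#'
#' Copies `n_inserts` windows of the plastome into unique segments of the
#' simulated genome at the stated identity (substitutions applied), and
#' records both coordinate systems in `mtpt_truth`.
#'
#' @param truth a `mito_truth` object.
#' @param plastome plastome sequence (data.frame or named character vector;
#'   first record used).
#' @param spec overrides for `truth$config$mtpt_spec`.
#' @return the updated `mito_truth` object.
#' @export
plant_mtpts <- function(truth, plastome, spec = NULL) {
  stopifnot(inherits(truth, "mito_truth"))
  s <- utils::modifyList(truth$config$mtpt_spec, spec %||% list())
  if (s$identity < 0 || s$identity > 1)
    stop("identity must be in [0, 1]")
  if (s$n_inserts == 0) return(truth)
  pl <- as_seq_vector(plastome)[[1]]
  if (max(s$insert_len_range) > nchar(pl))
    stop("insert length exceeds plastome length")
  set.seed(truth$config$seed + 4L)
  uni <- names(truth$element_type)[truth$element_type == "unique"]
  uni <- uni[nchar(truth$elements[uni]) >= 1000]
  if (!length(uni)) stop("no unique segment long enough to host an MTPT")
  mt <- truth$mtpt_truth
  for (i in seq_len(s$n_inserts)) {
    len <- sample(s$insert_len_range[1]:s$insert_len_range[2], 1)
    p_start <- sample.int(nchar(pl) - len + 1L, 1)
    strand <- sample(c("+", "-"), 1)
    ins <- substr(pl, p_start, p_start + len - 1L)
    if (strand == "-") ins <- revcomp(ins)
    if (s$identity < 1) ins <- mutate_seq(ins, sub_rate = 1 - s$identity)
    # inserts model distinct plastome-derived regions: keep each new site
    # clear of previously planted ones (no nesting, >= 200 bp apart)
    ok <- FALSE
    for (try in 1:100) {
      seg <- sample(uni, 1, prob = nchar(truth$elements[uni]))
      seg_seq <- truth$elements[[seg]]
      pos <- sample(200:(nchar(seg_seq) - 200), 1) # insert after this position
      prev <- mt[mt$segment == seg, , drop = FALSE]
      if (nrow(prev) == 0 ||
          all(pos < prev$seg_start - 200 - len | pos > prev$seg_end + 200)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place MTPT insert away from existing ones")
    truth$elements[[seg]] <- paste0(substr(seg_seq, 1, pos), ins,
                                    substr(seg_seq, pos + 1, nchar(seg_seq)))
    # shift earlier inserts in the same segment that lie after the new one
    if (nrow(mt)) {
      shift <- mt$segment == seg & mt$seg_start > pos
      mt$seg_start[shift] <- mt$seg_start[shift] + nchar(ins)
      mt$seg_end[shift] <- mt$seg_end[shift] + nchar(ins)
    }
    mt <- rbind(mt, data.frame(segment = seg, seg_start = pos + 1L,
                               seg_end = pos + nchar(ins),
                               p_start = p_start, p_end = p_start + len - 1L,
                               strand = strand, identity = s$identity,
                               stringsAsFactors = FALSE))
  }
  truth$mtpt_truth <- mt
  rebuild_molecules(truth)
}

#' Simulate a plastome-like reference sequence
#'
#' A random sequence standing in for a chloroplast genome in synthetic runs
#' (conifer plastomes are around 120 kb with GC near 0.39; the default is
#' scaled down to keep tests fast).
#'
#' @param len length in bp.
#' @param gc GC fraction.
#' @param seed integer seed.
#' @return data.frame with `id`, `sequence`.
#' @export
simulate_plastome <- function(len = 30000, gc = 0.39, seed = 99) {
  set.seed(seed)
  data.frame(id = "plastome_synthetic", description = "",
             sequence = random_dna(len, gc), stringsAsFactors = FALSE)
}
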