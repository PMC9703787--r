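# shared fixtures and independent oracles, built in code at test time

# small two-molecule genome (one circular, one linear) with one mid-size
# repeat family placed between two different unique-segment pairs
small_genome_cfg <- function(seed, error_rate = 0, lr_depth = 15,
                             n_unique = 6, n_rep = 1) {
  sim_config(seed = seed, n_unique_segments = n_unique,
             unique_len_range = c(9000, 16000),
             n_repeat_families = n_rep,
             repeat_len_mixture = list(p_bulk = 0, bulk_range = c(50, 200),
                                       tail_range = c(4000, 6000)),
             n_molecules = 2,
             long_read_spec = list(mean_len = 14000, sdlog = 0.35,
                                   min_len = 1000, error_rate = error_rate,
                                   depth = lr_depth,
                                   min_junction_depth = 3))
}

# selection with an explicit wide coverage range so that the scaffolding
# tests exercise the scaffolder, not the gene-hit sampling
select_all <- function(contigs, base_depth = 89) {
  sel <- select_mito_contigs(contigs,
                             select_params(cov_range = base_depth * c(0.3, 3)))
  assign_copy_class(sel)
}

# does a (possibly rotated / reverse-complemented) scaffold sequence equal a
# circular molecule sequence
circ_equal <- function(s, mol) {
  nchar(s) == nchar(mol) &&
    (grepl(s, paste0(mol, mol), fixed = TRUE) ||
       grepl(revcomp(s), paste0(mol, mol), fixed = TRUE))
}

# scaffold sequence matches some truth molecule of the same topology
matches_truth_molecule <- function(s, circular, truth) {
  for (j in seq_len(nrow(truth$molecules))) {
    mol <- truth$molecules$sequence[j]
    if (circular != truth$molecules$circular[j]) next
    if (circular) { if (circ_equal(s, mol)) return(TRUE) }
    else if (s == mol || revcomp(s) == mol) return(TRUE)
  }
  FALSE
}

# independent brute-force maximal-repeat oracle: k-mer seeded pair
# extension over both strands; returns the sorted canonical unit set
oracle_repeat_units <- function(seqs, min_len) {
  v <- if (is.data.frame(seqs)) setNames(seqs$sequence, seqs$id) else seqs
  regs <- list()
  for (i in seq_along(v)) regs[[length(regs) + 1]] <-
    list(seq = i, strand = "+", s = v[[i]])
  for (i in seq_along(v)) regs[[length(regs) + 1]] <-
    list(seq = i, strand = "-", s = revcomp(v[[i]]))
  km <- character(0); pm <- NULL
  pos <- list()
  kmers <- list()
  for (r in seq_along(regs)) {
    s <- regs[[r]]$s; n <- nchar(s)
    if (n < min_len) next
    kk <- substring(s, 1:(n - min_len + 1), min_len:n)
    for (t in seq_along(kk)) pos[[length(pos) + 1]] <- c(r, t)
    kmers[[length(kmers) + 1]] <- kk
  }
  km <- unlist(kmers); pm <- do.call(rbind, pos)
  units <- character(0)
  grp <- split(seq_along(km), km)
  grp <- grp[vapply(grp, length, 1L) >= 2]
  for (g in grp) {
    for (a in seq_along(g)) for (b in seq_along(g)) {
      if (a >= b) next
      r1 <- pm[g[a], 1]; o1 <- pm[g[a], 2]
      r2 <- pm[g[b], 1]; o2 <- pm[g[b], 2]
      if (r1 == r2 && o1 == o2) next
      s1 <- regs[[r1]]$s; s2 <- regs[[r2]]$s
      i1 <- o1; i2 <- o2
      while (i1 > 1 && i2 > 1 &&
             substr(s1, i1 - 1, i1 - 1) == substr(s2, i2 - 1, i2 - 1))
        { i1 <- i1 - 1; i2 <- i2 - 1 }
      j1 <- o1 + min_len - 1; j2 <- o2 + min_len - 1
      while (j1 < nchar(s1) && j2 < nchar(s2) &&
             substr(s1, j1 + 1, j1 + 1) == substr(s2, j2 + 1, j2 + 1))
        { j1 <- j1 + 1; j2 <- j2 + 1 }
      units <- c(units, substr(s1, i1, j1))
    }
  }
  units <- unique(units)
  canon <- vapply(units, function(u) {
    rcu <- revcomp(u); if (u <= rcu) u else rcu
  }, character(1), USE.NAMES = FALSE)
  sort(unique(canon))
}

# plant a unit at given positions of a random backbone with guard bases so
# that chance extension beyond the unit is impossible
plant_repeat <- function(backbone, unit, at, rc = FALSE) {
  guards <- list(c("A", "C"), c("G", "T"), c("C", "A"), c("T", "G"))
  s <- backbone
  at <- sort(at, decreasing = TRUE)
  for (k in seq_along(at)) {
    g <- guards[[((k - 1) %% length(guards)) + 1]]
    u <- if (rc && k == 1) revcomp(unit) else unit
    s <- paste0(substr(s, 1, at[k]), g[1], u, g[2],
                substr(s, at[k] + 1, nchar(s)))
  }
  s
}
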