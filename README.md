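# mitoscaff

Reconstruction of multipartite plant mitochondrial genomes from a
short-read assembly and PacBio long reads, as a tested, reusable R
pipeline.

Plant mitogenomes are not a single circle: they behave as a population of
linear and circular molecules assembled from shared unique segments and
interspersed repeats (REs), recombining at the repeats into alternative
arrangements. A short-read assembler collapses every repeat family into one
contig and breaks contigs at repeat boundaries, so reconstructing the
genome means answering, after assembly: which contigs are mitochondrial,
how many genomic copies each one represents, how the contigs connect, and
which scaffolds close into circles. `mitoscaff` is for researchers
assembling organelle genomes from combined short/long-read data — conifer
mitogenomes being the motivating case — and for anyone who needs the
companion statistics (repeat content, plastid-derived regions, cellular
copy number) on an existing assembly.

## What it computes

* **Contig selection** — a contig is mitochondrial if it carries a
  mitochondrial gene hit, or if it is ≥ 2,000 bp with mean short-read
  coverage inside the range spanned by the gene-hit contigs.
* **Copy classes** — from the coverage ratio r = cov / median(cov):
  `low` (r < 0.8), `single` (0.8 ≤ r < 1.25), `multiple(k)`
  (|r − k| ≤ 0.15, k ≥ 2), else `intermediate(k, k+1)`; contigs with
  r ≥ 1.25 are repeat-like and may be placed in several scaffolds.
* **Scaffolding** — seed-and-extend with long reads (≥ 10 kb, BlastN
  identity ≥ 90%) as framework: a junction needs ≥ 3 supporting reads,
  each anchoring a flanking contig over ≥ min(10 kb, 0.9 × contig);
  ambiguous ends stop extension and are reported as alternative
  connections; terminal ends linked by ≥ 3 reads flag the scaffold
  circular; junction sequence is filled from the longest spanning read.
* **Polishing** — CLC-style best-hit short-read mapping (length fraction
  0.9; similarity 0.90 then 0.95) with the chloroplast genome as decoy,
  followed by majority-consensus extraction with a low-coverage threshold
  of 5.
* **Repeats and MTPTs** — exact maximal-repeat enumeration (suffix array,
  both strands, tandem runs excluded); RE proportion = total RE length /
  sequence length; plastome-derived regions from BlastN hits > 50 bp at
  > 90% identity, merged within 10 bp.
* **Copy number** — copies per cell = mean mitogenome coverage /
  (input bases / haploid genome size).
* **Simulation** — ground-truthed multipartite genomes (unique segments,
  repeat families with alternative junctions, circular and linear
  molecules with stoichiometry, planted MTPTs) plus long- and short-read
  simulators, so every stage is testable without downloads.

## Worked example

Simulate a two-molecule genome (one circular, one linear; one 2-copy
repeat family), fragment it into assembler-style contigs, and run the
pipeline:

```r
library(mitoscaff)

cfg <- sim_config(seed = 42, n_unique_segments = 6,
                  unique_len_range = c(9000, 16000), n_repeat_families = 1,
                  repeat_len_mixture = list(p_bulk = 0,
                                            bulk_range = c(50, 200),
                                            tail_range = c(4000, 6000)),
                  n_molecules = 2,
                  long_read_spec = list(mean_len = 14000, sdlog = 0.35,
                                        min_len = 1000, error_rate = 0.05,
                                        depth = 15, min_junction_depth = 3))
truth <- simulate_mitogenome(cfg)
fr  <- fragment_to_contigs(truth, base_depth = 89)
sel <- assign_copy_class(
  select_mito_contigs(fr$contigs, select_params(cov_range = c(27, 267))))
sel[, c("id", "length", "mean_cov", "cov_ratio", "copy_class", "repeat_like")]
#>   id length mean_cov cov_ratio  copy_class repeat_like
#>  U01  10251     88.8 1.0113895      single       FALSE
#>  U02  10864     82.0 0.9339408      single       FALSE
#>  U03  12764     86.8 0.9886105      single       FALSE
#>  U04  15782     91.1 1.0375854      single       FALSE
#>  U05  15915     85.0 0.9681093      single       FALSE
#>  U06  14334     87.8 1.0000000      single       FALSE
#>  R01   5520    181.4 2.0660592 multiple(2)        TRUE
```

The collapsed repeat contig R01 sits at twice the median coverage —
`multiple(2)`, repeat-like. Scaffolding with the simulated 5%-error long
reads:

```r
ss <- build_scaffolds(sel[sel$selected, ], simulate_long_reads(truth))
ss$summary
#>                id length n_contigs circular
#>       scaffold_01  80699         7    FALSE
#>  scaffold_02_circ  10250     1     TRUE
ss$adjacency_report[ss$adjacency_report$contig == "R01", ]
#>  contig end partner p_ori support
#>     R01  3'     U06     +      15
#>     R01  3'     U03     +      11
#>     R01  5'     U05     -      19
#>     R01  5'     U02     -      11
```

R01 is placed twice inside scaffold 1 and its two ends connect to four
different unique contigs — the alternative-connection pattern that marks a
recombination-active repeat. The single-contig molecule closes into a
circle (`scaffold_02_circ`). Polishing the read-derived junctions with 30x
error-free short reads restores the exact molecule sequences:

```r
pol <- polish_scaffolds(ss, simulate_short_reads(truth, list(depth = 30)))
assembly_stats(pol$scaffolds)
#> scaffolds: 2  total 90950 bp  N50 80699  GC 46.04%  N bases 0
rs <- find_repeats(pol$scaffolds, min_len = 50)
repeat_proportion(rs)        # union of repeat copies over genome length
#> 0.121
estimate_copy_number(70.3, 7.43e9, 16.94e9)$copies_2sf
#> 160
```

The last call is the published worked example: 70.3x mitogenome coverage
from 7.43 Gbp of reads on a 16.94 Gbp haploid nuclear genome gives about
160 mitogenome copies per cell of haploid megagametophyte tissue.

A thin command-line front end over the same functions ships in
`inst/cli/mitoscaff` (`simulate`, `select`, `scaffold`, `polish`,
`repeats`, `mtpt`, `copy-number`, `compare`, `run-all` with a YAML
config).

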