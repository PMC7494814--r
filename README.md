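# guidecraft

Guide RNA design for CRISPR/Cas9 experiments that target one locus or
thousands at once — including the cases classic designers handle badly:
parallel targeting of large sets of near-identical sites (transcription
factor binding sites, motif families) and PE2/PE3 prime editing.

## The problem and the model

A Cas9 guide is programmed by a 20-nt **spacer**; the enzyme cuts where
the genome matches the spacer immediately 5′ of an **NGG PAM**, cleaving
after protospacer nucleotide 17 (3 nt from the PAM). Designing guides
means (1) turning each biological target into the right *search region*,
(2) enumerating N20-NGG sites on both strands, (3) counting genome-wide
(mis)matches to rule out off-target cutting, and (4) scoring on-target
efficiency.

guidecraft contributes three things around that skeleton:

- **A stranded genome-arithmetic vocabulary.** `extend_targets()`,
  `up_flank()`, `down_flank()`, `double_flank()` and `cut_to_spacer()`
  operate on tibbles of 1-based closed intervals, applying offsets in
  each interval's 5′→3′ direction. Named presets encode common
  applications: cut-within `[-16, +5]`, block `[-22, +22]`, CRISPRi TSS
  `[-50, +300]`, CRISPRa `[-300, 0]` up-flank, excise `[-16, +x]`
  down-flank, and vicinity double-flank.
- **Target-set-specific filtering (TSSF).** When many similar sites are
  targeted simultaneously, a spacer matching *another declared target*
  is not an off-target — it is free extra coverage. For each spacer and
  mismatch level *m* ∈ {0..k}, guidecraft counts genome matches G_m and
  target-overlapping matches T_m and reports
  **off_m = G_m − T_m**, with **off = Σ off_m**. Two counting engines
  are available: an exhaustive window scan (`engine = "exact"`, fully
  sensitive by construction) and a pigeonhole seed-and-verify matcher
  (`engine = "seeded"`, precision 1, complete at ≤ 1 mismatch, never
  above the exact engine, and much faster for large spacer sets).
- **Prime-editing construction.** For an edit (chrom, pos, ref, alt),
  admissible editing spacers are exactly those placing every edited base
  at protospacer positions 18..17+nrt (plus-strand starts in
  `[p − (nrt+16), p − 17]`); for each, the pegRNA 3′ extension is built
  as reverse-transcription template (carrying the edit) followed by the
  primer binding site, and PE3 nicking spacers are sought on the
  opposite strand 40–90 nt downstream, nick-to-nick.

Everything runs offline: `synth_genome()`/`make_genome()` build seeded
synthetic genomes with planted (mis)match copies, verified clean by a
brute-force oracle, so the whole test suite needs no downloads.

## Worked example

Plant the SRF-binding-site spacer `GTGAGAAGGTCGCCTTTATT` at two loci of
a 60 kb synthetic chromosome, declare both loci as targets, and design
blocking guides:

```r
library(guidecraft)

word <- "GTGAGAAGGTCGCCTTTATT"
plants <- tibble::tibble(seq = paste0(word, "AGG"), chrom = "chr13",
                         pos = c(12000L, 47000L), strand = c("-", "+"), mm = 0L)
g <- make_genome(c(chr13 = 60000), plants, seed = 1, max_mm = 2)
targets <- genomic_intervals("chr13", plants$pos, plants$pos + 19L,
                             plants$strand, c("siteA", "siteB"))

design <- run_parallel_targeting(g, targets, preset = "block",
                                 engine = "exact", scorer = "ruleset1")
design
#> <guide_design:parallel> 2 target(s), 8 spacer row(s), 8 retained

tab <- tidy(design, retained_only = TRUE)
tab[tab$spacer_seq == word, c("name", "target_name", "G0", "T0", "off0", "off", "score")]
#>                  name target_name G0 T0 off0 off score
#> 1 chr13:12003-12022:-       siteA  2  2    0   0 0.409
#> 2 chr13:47000-47019:+       siteB  2  2    0   0 0.409
```

Read the key row left to right: the spacer has two perfect genome
matches (`G0 = 2`) — its own locus and the second planted site — but
both fall inside declared targets (`T0 = 2`), so
`off0 = G0 − T0 = 0`; with no 1- or 2-mismatch matches anywhere,
`off = off0 + off1 + off2 = 0` and the spacer is off-target-free for
this target set, despite being multi-mapping in the conventional sense.
The `score` column is the internal Rule Set 1 style on-target score
(a synthetic-weight stand-in with the authentic feature structure; see
`?ruleset1_coefficients`).

`write_design(design, "out/run1")` serializes the table as TSV plus a
JSON run log (tool version, config hash, genome checksum, per-stage
counts); identical inputs give byte-identical output. A thin CLI over
the same functions lives at `inst/cli/guidecraft.R`
(`find-spacers`, `offtargets`, `block`, `cut-within`, `crispri`,
`crispra`, `excise`, `vicinity`, `prime-edit`, `score`, `make-genome`),
with exit codes 0/2/3 for success / input error / internal
inconsistency.

For prime editing:

```r
design <- run_prime_editing(g, edit_spec("chr13", 30000, ref, alt),
                            params = prime_params(nrt = 16, pbs_len = 13,
                                                  nick_window = c(40, 90)))
```

returns editing spacers (retained only when genome-unique, `G0 = 1`),
their 3′ extensions (`rt_template_seq`, `pbs_seq`,
`three_prime_extension`) and nicking spacers with `nick_distance` and
full off-target counts.

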