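---
title: "Guide design methods: genome arithmetic, TSSF off-target counting and prime-editing construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide design methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidecraft)
```

guidecraft designs CRISPR/Cas9 guide RNAs with an emphasis on two
workloads that stress conventional designers: thousands of simultaneous,
near-identical targets (parallel targeting), and PE2/PE3 prime editing.
This vignette is the package's own account of its methods: the models
and conventions, the parameters that matter, the numerical choices, and
what the test evidence does and does not establish.

## Coordinates and the interval model

All genomic ranges are tibbles with `chrom`, `start`, `end`, `strand`,
`name`, using 1-based fully-closed coordinates (`chr1:100-119` spans 20
bases). BED input/output is converted at the I/O boundary
(`read_bed()`/`write_bed()`), where the on-disk convention is 0-based
half-open. Strand is `"+"`, `"-"` or `"*"`; strand-aware operations
treat `"*"` as `"+"` and say so with a warning, because silently
guessing an orientation would silently change a search space.

Arithmetic is strand-aware in the 5'->3' sense: `extend_targets(x, a, b)`
grows the 5' end by `-a` and the 3' end by `+b` on the interval's own
strand, so on the minus strand the genomic window is mirrored.
`up_flank()`/`down_flank()` anchor at the 5'/3' end respectively;
`double_flank()` returns both flanks tagged per parent. Out-of-bounds
results are an error by default; an explicit `clip = TRUE` truncates to
the chromosome and warns. Overlapping outputs are never merged: each
transformed range keeps its parent target identity, which target-set
attribution requires later.

`cut_to_spacer()` inverts a cut-site annotation into a spacer range
(`[pos-17, pos+2]` for `+`, `[pos-16, pos+3]` for `-`), the convention
used by published guide libraries that record cut coordinates.

## Spacer discovery

`find_spacers()` reports every word of `spacer_len` unambiguous bases
followed on the same strand by an IUPAC PAM (default `N20-NGG`, the
wild-type S. pyogenes site), on both strands, fully contained in the
(transformed) target range. Containment of the *whole* spacer+PAM word
is what gives the preset offsets their meaning — e.g. `[-16, +5]`
guarantees the cut lands inside the original target (next section).
IUPAC codes are interpreted on the pattern side only; a genome `N`
matches nothing, and spacers overlapping any non-ACGT base are discarded
as experimentally unusable. Hits are reported once per
(location, strand, target): a spacer inside two overlapping targets is
two rows, deliberately, with `dedup_spacers()` providing the
location-unique library view. Output is sorted by
(chrom, start, strand) so identical inputs give identical files.
`cut_after` is the genomic position of protospacer base 17; Cas9 cuts
immediately 3' of it, three bases from the PAM.

## Application presets and the cut-within guarantee

`arithmetic_presets()` encodes one transform per application: block
`[-22, +22]` (any spacer/PAM word in the window overlaps the target by
at least one base), CRISPRi `[-50, +300]` strand-agnostic around the
TSS, CRISPRa `[-300, 0]` strand-agnostic up-flank, excise `[-16, +x]`
down-flank with `x` a required user parameter (the literature leaves it
application-specific, so the package refuses to guess), and vicinity
double-flank.

The cut-within preset deserves its own paragraph. A single strand-aware
`[-16, +5]` extension guarantees an in-target cut only for spacers on
the target's own strand: for the opposite strand the same window leaves
up to 10 bp of slack at one edge. Since the guarantee — "the cut falls
inside the original target" — is the entire point of the preset,
`transform_targets(..., "cut_within")` emits *mirrored per-strand
windows*: plus-strand spacers are sought in the `[-16, +5]` extension,
minus-strand spacers in its mirror `[-5, +16]` (both relative to the
target's strand), and `find_spacers()` honours the resulting
`search_strand` column. This is the unique reading under which the
guarantee holds on both strands, and the property test over random
targets checks exactly that. The same mirrored-window logic, with
`[-5, +nrt+16]`, reproduces the prime-editing search region below.

## Off-target counting and target-set-specific filtering

For each spacer, `count_genome_matches()` counts genome windows (both
strands) within Hamming distance `m` for `m = 0..max_mm`. The default
`max_mm = 2` reflects common reporting practice for guide libraries;
up to 3 is supported. Counting is PAM-agnostic by default (the
convention for mismatch benchmarking); `pam_mode = "required"` restricts
to PAM-flanked windows, which is the biologically active subset. A
window matching on both strands is two matches — two distinct Cas9
binding events. Matching is partitionable by chromosome and the result
is independent of partition order (tested).

Two engines implement the same contract:

- **exact** — an exhaustive compiled scan of every window with
  early-exit Hamming counting. Full sensitivity at every level is true
  by construction; the suite verifies it against an independent
  brute-force oracle written in plain vectorised R.
- **seeded** — a pigeonhole seed-and-verify matcher: each query is split
  into `max_mm + 1` contiguous seeds; any window within `max_mm`
  mismatches preserves at least one seed exactly, so hash lookups of
  genome substrings followed by Hamming verification find it. The
  engine's *contract* is the one fast read-mapping backends provide:
  precision 1, guaranteed completeness at `m <= 1`, counts never above
  the exact engine. The pigeonhole construction in fact meets the
  contract with full completeness at every supported `m`, which the
  suite asserts as `seeded == exact`; the contract, not any particular
  third-party aligner's behaviour, is what the package promises.

Target-set-specific filtering then distinguishes cross-target matches
from true off-targets. With `T_m` the number of level-`m` matches whose
window overlaps any declared (transformed) target range by at least one
base — on either strand, since Cas9 binding does not care which strand
the annotation used — the off-target counts are `off_m = G_m - T_m` and
`off = sum(off_m)`. A negative difference is impossible if the targets
were scanned, so it is raised as an internal-consistency error rather
than clamped. One base of overlap is the attribution rule because the
blocking preset's `[-22, +22]` rationale is exactly "at least one
blocked base".

Retention policies: `parallel` keeps spacers with `off = 0` up to
`max_mm` (cross-target hits welcome); `unique` keeps genome-unique
spacers (`G0 = 1`), optionally also `off = 0` — the rule for prime
editing and classic single-locus work.

## Prime editing

An edit is `(chrom, position, ref, alt)` on the plus strand, validated
against the genome, with `|alt| <= 48` (the prime editor's practical
rewrite limit). The defaults `nrt = 16` and `pbs_len = 13` follow the
recommendations of the original prime-editing literature; both are
plain parameters.

The admissibility rule is positional: every edited base must sit at
protospacer positions 18..`17 + nrt`, because reverse transcription
starts at the nick (between positions 17 and 18) and copies `nrt`
template bases. For a plus-strand spacer and a single-base edit at `p`
this is a start window of `[p - (nrt+16), p - 17]` — 16 admissible
starts at the default `nrt`. Insertions are measured against the
post-edit template length, which (since the RT template length adjusts
by `|alt| - |ref|`) reduces to the same pre-edit rule on the ref span;
this is the strictest consistent reading and is what the enumeration
oracle tests. Both strands are searched and reported symmetrically
(the mirror property is tested by reverse-complementing the whole
problem); any strand preference is left to the user, since admissible
minus-strand designs are real designs.

The 3' extension is RT template then PBS, written 5'->3' as cloned:
PBS = reverse complement of protospacer positions `17-pbs_len+1..17`
(`pbs_len > 17` would cross the protospacer 5' end and is refused);
RT template = reverse complement of the *edited* protospacer-strand
sequence from position 18 through `17 + nrt`, hence length
`nrt + |alt| - |ref|`.

PE3 nicking spacers are sought on the strand opposite the editing
spacer, with nick-to-nick distance inside `nick_window` (default
40–90 nt) measured from the prime-editing nick, downstream along the
edited strand. Nick positions are represented as inter-base boundaries,
which avoids off-by-one ambiguity between strands. The window origin is
the nick, not the edited base — the two differ by up to `nrt`, and the
nick is what the repair biology cares about; the parameters are
adjustable where users prefer other conventions.

`design_prime_editing()` composes the above: editing spacers must be
genome-unique on exact matches (`G0 = 1`, no cross-target tolerance —
each nicking spacer's only "target" is its own locus), nicking spacers
carry mismatch-aware counts at `max_mm = 2` by default, and scores are
attached to both but never used to filter editing spacers by default,
since sequence-based efficiency scores are not validated for pegRNA
spacers.

## On-target scoring

`build_context()` extracts the standard 30-mer scoring window (4 nt
upstream, protospacer, PAM at positions 25–27, 3 nt downstream) on the
spacer strand; windows truncated by a chromosome end or containing
ambiguous bases flag the spacer unscorable rather than dropping it.

`score_rule_set_1()` is a pure logistic model over tabulated features:
intercept, sparse position-specific single-nucleotide and dinucleotide
weights, and GC-count terms on the protospacer (separate slopes below
and above 10 GC bases). The shipped coefficient table is **synthetic**:
it reproduces the authentic feature structure of the published Rule
Set 1 model but its weights were generated once from a fixed seed
(`inst/extdata/ruleset1_synthetic_coefficients.tsv`, MD5 recorded in
`?ruleset1_coefficients`). Scores are therefore deterministic, stable
across platforms (regression-tested to 1e-9) and usable for consistent
ranking within a run, but they are not the published model's values and
carry no validated biological meaning. Externally trained scorers (such
as the gradient-boosted 2016 model) plug in through
`score_external()`: one 30-mer per stdin line, one numeric per stdout
line; a missing or failing adapter yields `NA` scores with a warning
and never aborts a run. Scoring never changes the spacer set.

## The synthetic-data generator

`synth_genome()` draws i.i.d. background sequence (default GC 0.5) from
an explicit seeded RNG stream that does not disturb the session RNG.
`make_genome()` plants words — typically spacer+PAM 23-mers — at
requested positions, strands and mismatch counts (mismatches never in
the protected PAM tail unless asked), then *verifies* with the
brute-force oracle that the background contains no additional copy of
any planted core within `max_mm`, regenerating the background up to a
bounded number of retries and failing loudly if the constraints are
unsatisfiable. Every engine-equivalence test in the suite runs against
genomes built this way, at sizes of 8–420 kb — large enough to exercise
chromosome partitioning and seed indexing, small enough that the whole
suite runs in well under a minute of compute for these parts.

What the generator emulates: planted exact and near-match structure,
multi-chromosome layouts, strand symmetry, ambiguous-base handling.
What it does not: repeat families, GC isochores, homopolymer tracts and
the empirical mismatch-neighbourhood density of real genomes. Passing
tests therefore establish the *correctness contracts* (counting
equivalence with an oracle, TSSF algebra, geometric guarantees), not
real-genome performance or biological off-target risk. The optional
integration check `check_reference_designs()` runs the prion-locus
prime-editing design against a user-supplied GRCh38 FASTA for exactly
that reason; it is gated on a local genome path
(`options(guidecraft.grch38_fasta = ...)`) because multi-gigabyte
references cannot ship with the package.

## Numerical and degenerate-input choices

- Coordinates are validated eagerly (`start >= 1`, `end >= start`,
  bounds against the genome when available); degenerate widths are
  errors, not empty results.
- Hamming counting treats any non-ACGT genome base as a mismatch
  against everything; queries must be pure ACGT.
- `max_mm` is capped at 3: counting levels beyond that is rarely
  reported and the exhaustive oracle regime the tests rely on stays
  cheap.
- Empty results (no spacers, no nicking candidates, empty target sets)
  are ordinary empty tibbles with stable column types, and exit code 0
  at the CLI; *inconsistent* states (`T_m > G_m`) are classed internal
  errors, exit code 3.
- All outputs are sorted deterministically; the run log records tool
  version, config hash and genome checksum, and identical inputs give
  byte-identical TSVs (tested).

## Known limitations

- The seeded engine indexes seeds per run rather than persisting a
  genome index; very large genomes pay the scan cost on every call.
- Off-target counting is substitution-only (no bulges/indels) and
  unweighted (no CFD/MIT-style aggregate risk score).
- Only 3'-PAM nucleases are modelled; 5'-PAM systems (e.g. Cas12a) and
  variable-length spacers beyond a single `spacer_len` are out of
  scope.
- The internal on-target scorer ranks; it does not predict validated
  efficiency (synthetic weights, see above).
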