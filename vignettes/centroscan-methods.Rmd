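---
title: "centroscan: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{centroscan: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centroscan)
```

`centroscan` re-implements, as one tested toolkit, the bespoke computations
that surround a telomere-to-telomere (T2T) fungal genome assembly: telomere
detection and read-based telomere rescue, k-mer consensus-accuracy (QV)
arithmetic, coverage-anomaly and MQ0 flagging, rDNA copy-number estimation,
Hi-C observed/expected (OE) centromere prediction fused with
sequence-feature tracks, Levan arm classification, and structural
annotation of centromeric *Copia* LTR retrotransposons. This vignette is
the package's account of those methods: the model behind each stage, the
parameters that matter, what the synthetic data generator emulates (and
what it deliberately does not), and the numerical choices a maintainer
would want written down.

Internally every coordinate is 0-based half-open; conversion to 1-based
closed coordinates happens only at the GFF3 boundary. All analysis stages
consume the shared containers (`genome`, `interval_track`, `depth_track`,
`contact_matrix`) produced by the readers — no stage re-parses files.

## Telomere detection and rescue

A telomere here is a terminal tandem array of a 6 bp unit: `CCCTAA` read
from the 5' terminus, its reverse complement `TTAGGG` at the 3' terminus. A
*tandem run* is a maximal chain of unit-length frames spaced exactly
`nchar(unit)` apart, each frame within a per-unit mismatch budget, with no
insertions or deletions between frames. This definition is deliberately
rigid: it is trivially checkable against a brute-force regular-expression
oracle, and real telomerase-synthesised arrays are overwhelmingly
substitution-divergent rather than indel-divergent.

Parameters (all configurable, defaults chosen to be insensitive over
synthetic sweeps):

* `window` = 1,000 bp — how far from the terminus a run may start. Assembled
  telomeres start at or very near position 0; the window tolerates a short
  unresolved overhang.
* `min_copies` = 5 (30 bp) — short enough to catch eroded ends, long enough
  that random sequence never qualifies (the chance of 5 tandem exact copies
  in a 1 kb window of random sequence is ~10^-14).
* `max_mismatch_frac` = 1/6 — one mismatch per 6 bp unit; `N` counts as a
  mismatch.

The 3' end is scanned by reverse-complementing the chromosome and reusing
the 5' rule, which makes strand-consistency (`revcomp` swaps the two end
reports exactly) true by construction rather than by testing luck.

Telomere rescue follows the manual procedure used in T2T finishing:
extract every read containing at least `min_copies_read` = 10 tandem
copies of the unit in either orientation (10 copies = 60 bp makes random
hits negligible), orient them so the motif reads `CCCTAA` from the 5' side,
then anchor the broken terminus against each read — an exact terminal seed
of 20 bp followed by gapless extension over the full 500 bp anchor at
identity ≥ 0.95 — and splice on the anchored extension that reaches
farthest and itself terminates in a telomere array. Ties break by anchor
identity, then lexicographic read id, so output is deterministic. With
error-free reads that span the truncation, the patched sequence equals the
pre-truncation sequence exactly; that equality is asserted in the tests.
The stage performs anchored extension only — it does not re-assemble the
extracted reads, so a rescue across a long unanchored repeat (e.g. through
a full terminal rDNA array much longer than the read length) is out of its
reach by design.

## k-mer accounting and consensus accuracy

`count_canonical_kmers()` counts *distinct canonical* k-mers (the
lexicographic minimum of each window and its reverse complement) with
multiplicities; windows containing `N` are skipped. Counting is done in
C++ with a 2-bit rolling encoding (`k` ≤ 31). The distinct-counting
reading matters: the consensus-accuracy model is about which assembly
k-mers exist in the read database, not how often.

With `K_total` distinct assembly k-mers and `K_only` of them absent from
the reads,

\[ E = 1 - \left(1 - \frac{K_{only}}{K_{total}}\right)^{1/k}, \qquad
QV = -10\log_{10} E, \qquad \mathrm{accuracy} = (1-E)\times 100\% . \]

The survivorship form inverts the fact that one consensus error poisons up
to `k` overlapping k-mers. Edge cases are explicit: `K_only = 0` reports
accuracy 100 and infinite QV; `K_only = K_total` reports `E = 1`, `QV = 0`
with a warning. `k` defaults to 17, the usual choice for genomes in the
tens of megabases (4^17 comfortably exceeds the genome size). A read k-mer
needs multiplicity ≥ 1 to support an assembly k-mer; no minimum-multiplicity
filter is applied, but the counts are returned so callers can apply one.

`kmer_histogram()` estimates genome size as total k-mer instances divided
by the homozygous peak depth. The peak is the modal multiplicity above 1,
located on a 5-point moving mean of the histogram, and then refined to the
histogram centroid within ±30% of that mode. The refinement is a numerical
choice worth recording: at desk scale the raw argmax of the multiplicity
histogram wobbles by ±2–3 bins under resampling (adjacent bins near a
Poisson mode differ by fractions of a percent while their counts carry
multinomial noise), which alone is a 3–5% size error; the windowed centroid
is stable to well under 1% and leaves the estimate invariant under a
doubling of read depth. Heterozygosity modelling (two-peak fitting) is out
of scope; only the single-peak estimate is provided, with an explicit
undefined-estimate path (warning, `NA`) when no multiplicity exceeds 1.

## Coverage QC

`bin_depth()` computes per-bin mean depth from a true-origin alignment
table; the final partial bin of each chromosome is normalised by its true
width, so `sum(depth × width)` equals total aligned bp exactly — the
conservation is asserted, not assumed. Bins are tiled (non-overlapping);
10 kb is the default width.

`flag_anomalies()` implements the low-coverage rule in two modes: an
absolute threshold (default 80, matching the convention of flagging 10 kb
bins below 80× against a ~248× genome-wide average) and a
fraction-of-genome-mean mode (default 0.32 ≈ 80/248) for runs at other
depths — the absolute constant is depth-specific and would be meaningless
on a 30× synthetic run. Adjacent flagged bins merge into one interval;
flagging is monotone in the threshold.

`flag_mq0_bins()` flags bins where at least `min_mq0_fraction` = 0.8 of
overlapping reads have mapping quality 0 (and at least one read overlaps).
Because every read overlapping the bin counts, reads whose origins
straddle the boundary of an ambiguous region dilute the fraction; the
flagged footprint is therefore the core of a collapsed-repeat region at
bin resolution, not its exact edges. Empty bins are never flagged.

`mapping_rates()` reports percentages half-up to two decimals; half-up
(rather than R's round-half-even) matches how such tables are
conventionally printed.

## rDNA copy number

The estimator is blast-coverage logic: find all read segments matching the
repeat unit, merge overlapping/abutting hits per read, sum to `L_total`,
and divide by coverage times unit length,

\[ \mathrm{copies} = \mathrm{round}\!\left(\frac{L_{total}}{C \cdot U}\right), \]

with nearest-integer (half-up) rounding — the rule that turns a ratio of
72.32 into 72 copies. `C` defaults to the genome mean from the coverage
stage, a single source of truth for depth.

Matching is the package's shared gapless seed-and-extend engine (see
below) with a 31 bp exact seed, identity ≥ 0.9 and a 100 bp minimum hit;
these are documented equivalents of a megablast-style search, not a
re-implementation of one. Two properties are worth noting. First, the
estimate is depth-invariant: doubling coverage doubles `L_total` and `C`
together. Second, a terminal tandem array has an intrinsic small negative
bias: read coverage decays to zero over the last read-length of a
chromosome, so roughly `read_length/2` of the array is under-covered
relative to the genome mean. At the synthetic scale (34 kb array, 2 kb
reads) this is a few percent; on a real dataset (hundreds of kb of array,
reads much shorter than the array) it is negligible.

`terminal_rdna_check()` reports, per chromosome end, the fraction of the
terminal window covered by merged unit hits, flagging ends above 50% —
the signature of an assembly whose terminal repeats displaced the
telomere.

## Hi-C OE transformation and centromere calling

Contact matrices are binned, symmetric, genome-global (per-chromosome bin
offsets make cis and trans blocks uniformly addressable). The OE
transformation divides each observed count by its expectation: for cis
pairs, the mean observed count at the same bin distance within that
chromosome; for trans pairs, the mean over all trans entries. A small
`epsilon` (10^-9) guards empty diagonals. Self-normalisation — the
per-diagonal mean of cis OE equal to 1 wherever defined — is exact by
construction and asserted to 10^-9 in the tests.

Two per-bin summaries feed the caller: the mean OE over all trans
partners, and the mean OE over cis partners at distance ≥ `d_min` bins
(default 50, i.e. 500 kb at 10 kb bins). On chromosomes shorter than
`d_min` bins — including the synthetic miniatures — the cis score is `NA`
and the caller degrades gracefully to the trans score alone.

The caller itself: per chromosome, the combined score is the mean of the
available OE-scale scores, median-centred; a 3-bin moving mean locates the
candidate peak (ties break toward the chromosome middle, then the lower
index, and the peak then snaps to the raw maximum within the smoothing
support, since the smoothed argmax can sit one bin off a single-bin peak);
the call is grown in both directions while the raw centred score stays at
or above `peak_fraction` = 0.5 of the peak height; a chromosome yields no
call when the peak height is below `min_peak_mads` = 4 robust deviations
(MAD) of the centred scores. Sequence evidence then compares the candidate
region's mean GC, gene density, repeat density and transcription against
the chromosome means (strict inequalities in the centromeric direction); a
call is retained with at least `min_evidence` = 2 of the 4 flags. Calls
whose midpoint lies in the outermost 5% of the chromosome are annotated
low-confidence — edge centromeres are the known failure mode of OE-based
prediction, since half their interaction neighbourhood is missing.

Two design choices here were genuinely open and deserve their rationale:

* **Fusion on the OE scale, not rank fusion.** Averaging the *ranks* of
  the trans and long-range cis scores looks attractive but fails exactly
  when one track carries no signal: ranks of pure noise are uniform, and
  averaging them into the informative track's ranks erases a contrast that
  is enormous on the OE scale (a centromeric bin's mean trans OE sits many
  standard errors above background, but its rank advantage is only "first
  of n"). Averaging the scores themselves preserves that contrast, and
  median-centring puts the result on a per-chromosome background of zero
  so that peak growth and the MAD test are well defined.
* **Noise scale from the unsmoothed scores.** A centromere spans one or
  two bins of a short chromosome; smoothing dilutes its peak by up to
  two-thirds and leaks it into the MAD if the MAD is computed on the
  smoothed series. Testing the raw peak height against the MAD of the raw
  centred scores keeps both quantities on the same scale and keeps the
  false-positive bound analytic (the maximum of ~n null bins is ≈ 2 MAD
  for the n used here, against a threshold of 4).

`classify_arms()` normalises arm lengths to 10 units
(`s = 10·min(m, L−m)/L`, `l = 10 − s`) and reports `d = l − s` and
`r = l/s` to two decimals (half-up). The type is assigned from the rounded
d alone — [0, 2.5] metacentric, (2.5, 5] submetacentric, (5, 7.5]
subtelocentric, (7.5, 10) acrocentric — because the d and r interval
systems disagree at the r = 3.0 boundary for arm ratios that d classifies
cleanly; d is the single consistent rule. A midpoint on a chromosome
boundary is a fatal error (`r` would be undefined); mirror invariance
(reflecting the chromosome changes nothing) is a tested property.

## Centromeric LTR annotation

`find_monomers()` locates copies of the monomer consensus (≈427 bp for the
centromeric *Copia* family this stage is built around) on both strands,
classifies them `complete` (consensus coverage ≥ 0.8 and identity ≥ 0.8)
or `shorter` (coverage 0.4–0.8), and reduces overlapping candidates to the
best identity × coverage. The class cutoffs are documented, configurable
stand-ins — the complete/shorter distinction is conventional, not
canonical.

`pair_elements()` performs greedy left-to-right pairing of same-strand
hits separated by 1–15 kb whose sequences align at ≥ 0.85 identity;
unpaired hits become solo LTRs (the recombination relics expected in
centromeres), and every hit is consumed by exactly one element — a
conservation property the tests assert. Paired elements are then checked
for the structural hallmarks of an intact element:

* **TSR** — an identical flanking duplication of 4–6 bp (longest match
  wins);
* **PBS** — an exact user-supplied motif within 20 bp downstream of the 5'
  LTR; with no motif supplied the flag is reported `NA`, never guessed;
* **PPT** — a purine run of ≥ 10 bp within the last 30 bp of the internal
  region;
* **domain order** — user-supplied GAG/INT/RT/RH marker sequences found in
  strictly increasing positions inside the internal region.

Minus-strand elements are evaluated on the reverse-complemented element
sequence, so all checks are strand-symmetric; domains are nucleotide
marker matches, not protein-profile searches (profile HMMs are a
non-goal). `centromere_colocation()` and `copy_table()` are deterministic
tabulations against called centromere regions.

## The shared alignment engine

Both the rDNA and LTR stages use one gapless seed-and-extend matcher:
exact seeds taken from the query every `stride` bp are located with
Biostrings' `matchPDict`; each seed hit fixes a diagonal; the query is
projected onto the subject along that diagonal and trimmed to its
best-scoring contiguous segment (maximum-sum subarray of
`match − min_identity`, prefix sums rounded to 9 decimals so that
mathematically tied prefixes break toward the longest segment — an
untreated 10^-16 float drift otherwise clips alignment ends). The engine
models substitutions only. That is a real limitation for diverged real
elements with indels; it is the right trade for this package, whose
generator plants substitution-divergent copies, and the trimming makes
truncated copies (the `shorter` class) come out with honest boundaries.

## The synthetic genome generator

The generator is first-class, tested code: it is how every stage's
recovery claims are made falsifiable. `sim_params(seed)` describes a
miniature genome whose defaults are the package's study conditions:

* 3 chromosomes of 500/400/300 kb at 56% background GC — miniature scale
  chosen so every stage runs in seconds while bins, arrays and reads keep
  realistic proportions;
* 30 tandem telomere units per end, planted verbatim (`CCCTAA` 5',
  `TTAGGG` 3');
* one 10 kb centromere per chromosome at midpoint fractions
  0.45/0.30/0.65, at 40% GC against the 56% background, zero genes,
  saturating repeat annotation, near-zero RNA depth (Poisson mean 0.2 vs
  20 outside);
* a planted LTR layout per centromere (427 bp monomer consensus; paired
  elements with 3 kb internal regions, 5 bp TSRs, PBS/PPT/domain markers;
  solo monomers, including one on the minus strand);
* a 5,701 bp rDNA unit repeated 10× as an exact tandem array inside the 3'
  telomere of chr3 (a per-unit substitution rate is available to emulate
  intergenic-spacer variation, default 0);
* reads at 30× with normal lengths (8 kb ± 1.5 kb), i.i.d. substitution
  errors at 0.1%, a collapsed-repeat coverage dip (region thinned to 0.25×
  its expected depth) and an MQ0 region whose reads are emitted with
  mapping quality 0;
* Hi-C at 10 kb bins with cis decay `count ∝ d^(−1)`, constant trans
  background, 5× enrichment of centromere–centromere bin pairs, and
  multiplicative log-normal noise (sdlog 0.1).

One root seed drives per-component sub-generators (genome, reads,
contacts), so regenerating one component never perturbs another, and the
whole dataset is byte-identical across runs with the same seed. Every
planted feature is recorded in a truth object and is an exact substring of
the emitted genome — the tests verify truth by string search, not by
trusting the generator's bookkeeping.

What the generator does **not** emulate — and hence what green tests do
and do not show about real data: background sequence is i.i.d. (no
isochores, no dispersed repeat families beyond the planted ones), read
errors are uniform substitutions (no homopolymer indels typical of long
reads), the genome is haploid with no heterozygosity, Hi-C matrices are
generated directly at the count level (no read-pair simulation, no
balancing artefacts), and rDNA arrays are exact duplicates by default.
Passing recovery tests therefore demonstrates that the algorithms are
correct implementations of their models under those models' assumptions;
they do not certify performance on indel-rich or structurally complex real
data.

Property-test problem sizes are the package's own choices, kept miniature
on purpose: 2–3 chromosomes of 100–150 kb for the read-heavy properties
(telomere patch equality at 20×, rDNA recovery at 25× with 2 kb reads),
ten seeds of a 3-chromosome world at 3× Hi-C enrichment for centromere
recovery, and the 500/400/300 kb default world for everything else.

## Degenerate inputs and numerical conventions

Fatal errors are reserved for contract violations: malformed FASTA
(duplicate or empty names, non-ACGTN characters, reported with record and
offset), intervals with `start ≥ end` or beyond chromosome bounds,
negative contact counts or out-of-range bin indices, zero total reads,
nonpositive coverage or unit length, an all-zero contact matrix ("no
signal"), patching an end that already carries a telomere. Warnings, not
errors, mark analysable-but-suspicious states: zero-depth bins at low
simulated coverage, `k` longer than every sequence, a homopolymer repeat
unit, an undefined histogram peak. A uniform matrix with flat features
produces a no-call result, not an exception.

Rounding is half-up wherever a reported value is defined "to n decimals"
(percentages, d/r values, the copy number); `N` bases are excluded from GC
denominators and treated as mismatches in every scan; all tie-breaks
(telomere runs, peak bins, anchoring reads, pairing order) are documented
and deterministic.

## Known limitations

* The alignment engine is substitution-only; diverged elements with indels
  will be under-detected relative to a true local aligner.
* Telomere rescue requires an anchorable unique terminus; it cannot patch
  across an unanchored repeat array longer than the reads.
* The MQ0 flag depends on the aligner's mapping-quality convention of the
  input table; the simulator's convention (0 for ambiguous origin, 60
  otherwise) is the simplest faithful model.
* OE-based centromere prediction near chromosome edges is intrinsically
  unreliable; such calls are annotated, not suppressed.
* The Hi-C input is assumed already filtered and normalised upstream
  (duplicate/low-quality alignment removal is an input requirement, not a
  feature of this package).
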