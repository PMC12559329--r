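---
title: "Methods: strand-specific nick mapping and Sanger trace decomposition on repeat-loop substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-specific nick mapping and Sanger trace decomposition on repeat-loop substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The system being modelled

Trinucleotide repeat tracts slip during DNA metabolism and form
extrahelical loops: a few unpaired nucleotides bulging out of one strand
of an otherwise perfect duplex. In reconstituted reactions on circular
plasmid substrates, mismatch-repair factors (MutSβ activating the MutLγ
endonuclease) nick the strand *opposite* such a loop, preferentially on
its 5′ side, which licenses displacement synthesis toward the loop and
copies the loop's complement into the opposite strand — repeat
*expansion*. The FAN1 nuclease, with RFC-loaded PCNA, instead incises
the *looped* strand one nucleotide 3′ of the loop, which leads to loop
excision — repeat *contraction*.

Two computational procedures quantify these outcomes and are the core of
this package:

1. **Nick mapping**: 3′-OH-capture sequencing reads are aligned against
   a circular plasmid reference and converted to strand-specific cut
   positions at single-nucleotide resolution.
2. **Trace decomposition**: Sanger chromatograms of reaction products
   are decomposed into a non-negative mixture of simulated indel
   references, quantifying the fraction of molecules carrying each
   insertion or deletion size.

A synthetic-data layer (substrate builder, read simulator, chromatogram
simulator) supplies ground truth for every stage, so each procedure is
tested as a round trip against planted truth.

## Substrates and coordinates

A substrate is a circular plasmid of length $N$ (default 3,200 nt, the
scale of the assay plasmid) plus a loop specification: carrier strand,
insertion point $i$, and loop sequence of length $L$ (the standard loop
is the 12-nt (CAG)₄; a (T)₄ variant is used for comparison). The looped
strand has length $N + L$; the opposite strand stays $N$.

One canonical frame avoids double bookkeeping: coordinates are 0-based
and interpreted modulo the strand length; the duplex frame is the FASTA
top strand 5′→3′; bottom-strand features are reported in top-strand
coordinates with a strand flag. `coord_map()` converts between the
duplex and looped-strand frames; loop-internal positions have no duplex
partner and are returned as an in-loop marker with the loop-local
offset.

The product predictions are pure sequence surgery: `expansion_product()`
inserts the loop's reverse complement into the opposite strand at the
site across from the loop (both strands then $N + L$, fully paired);
`contraction_product()` removes the loop (both strands $N$). These
sequences also serve as the mutant references for trace decomposition,
which keeps the two halves of the package consistent by construction.

## Read geometry

A nick at index $p$ of strand $s$ is a broken backbone between the
nucleotide at $p$ and its 3′ neighbour, leaving a free 3′-OH at $p$.
3′-OH-capture sequencing reads the *intact complementary strand*: the
simulated read is the sequence of the strand opposite the nicked one,
its 5′-most base sitting base-paired immediately across from the free
3′-OH, extending 5′→3′ along that strand with circular wrap-around.
The cut caller applies the identical convention in reverse. The exact
±1 phasing of the wet protocol's adapter chemistry is not recoverable
from published descriptions, so correctness is *defined* as
simulator/caller round-trip identity — the convention is shared, not
inferred.

Two consequences matter. First, reads produced by nicks on the strand
opposite the loop are physically the looped strand, so reads from nicks
within a read length 5′ of the insertion point traverse the loop and
cannot map to the loop-free duplex reference — these are the reads the
rescue pass exists for. Second, nicks strictly inside the loop have no
base-paired partner, so no read geometry exists for them; the simulator
rejects profiles with loop-internal intensity on the carrier strand
rather than inventing a convention. The preset scenarios never place
intensity there.

## Preset incision scenarios

`preset_profile()` encodes the two biochemical signatures as planted
intensity profiles:

* `mutl_opposite_5prime` — decaying peaks on the opposite strand 5′ of
  the loop: `n_peaks = 8` single-nucleotide peaks starting
  `first_offset = 20` nt from the loop, spaced `spacing = 30` nt, with
  heights $e^{-\mathrm{offset}/100}$ (`decay_length = 100` nt), plus a
  `background = 0.05` uniform fraction over both strands. The discrete
  peaks stand in for the observed sequence-preferential cutting; the
  spacing and decay keep ≥ 90% of opposite-strand mass within a few
  hundred nucleotides 5′ of the loop, matching the qualitative picture
  of incisions restricted to the loop-proximal 5′ flank.
* `fan1_loop3prime` — a single dominant peak on the looped strand at
  `loop3_boundary + 1` (one nucleotide 3′ of the loop) carrying
  $1 - \mathrm{background}$ of the mass, plus the same low uniform
  background standing in for the infrequent cuts seen elsewhere.
* `uniform` — equal intensity at every (pairable) position of one
  strand; used for null and calibration tests.

These values are simulation conditions chosen once, not fitted: no
quantitative per-position incision distribution is published, so the
presets encode the stated qualitative geometry with magnitudes a
practitioner would call realistic.

## Cut calling

The reference is the plasmid strand *duplicated and concatenated three
times*, so reads spanning the circular origin map contiguously. The
internal aligner is an exact k-mer seed (default `seed_k = 20`, taken at
offsets 0, k, 2k, … and the final window of the read) with ungapped
extension on both strands, scored by mismatch count
(`max_mismatches = 2`). With this offset set, any alignment within the
mismatch budget of a 75-nt read is proposed by at least one error-free
seed window. Desk-scale plasmids need no index structures beyond a
k-mer table. A SAM import path accepts external-aligner output against
the exported 3× reference and feeds the identical downstream code.

Copy selection: only alignments starting in the middle copy window
$[N, 2N)$ are kept, then shifted by $-N$. The middle copy avoids
concatenation-edge artifacts and counts each circular locus exactly
once; because the reference is exactly periodic, every circular
alignment has a middle-copy representative. An all-copies-mod-$N$ mode
is provided for comparison and agrees with the default on clean reads
(asserted in the tests). Best-score ties at distinct loci mod $N$ are
reported as *ambiguous* and counted, never silently dropped; duplicates
are not collapsed (the protocol has no UMIs).

Reads aligned to the top strand report cuts on the bottom strand and
vice versa, at the coordinate across from the read's 5′-most mapped
base. Reads that fail the primary pass are re-aligned against the
looped strand (also 3×). "Excluding the loop" in this second pass is
interpreted as a *reporting* convention: the pass aligns to the full
looped strand, and cut coordinates that fall inside the loop are
segregated into loop-local counts instead of being forced onto duplex
coordinates. The alternative reading — deleting the loop from the
second-pass reference — is implemented behind
`rescue_reference = "loopless"`; it cannot recover reads that contain
the loop sequence itself, which is why it is not the default.

Bookkeeping is exact and checked on every run:
$n_\mathrm{input} = n_\mathrm{unique} + n_\mathrm{rescued} +
n_\mathrm{ambiguous} + n_\mathrm{unmapped}$, and the per-position
counts sum to the number of placed reads. Raw counts are primary; CPM
(counts per million mapped) is provided for cross-run comparison, and
polar plots draw raw counts by default with the looped and opposite
strands as distinct series.

## Chromatogram model

The trace model is one scan per base: channel $b$ at scan $t$ carries
$A(t)\sum_k f_k\,[s_k(t) = b]$ with amplitude decay
$A(t) = e^{-\lambda t}$ (`decay_rate` $\lambda = 0.001$ per base, a
mild ~8% fall across a typical fitting window), plus Gaussian noise of
standard deviation `noise_sd` (default 0.01, as a fraction of the
initial amplitude), clipped at zero. There is no inter-scan peak
spreading or mobility shift: the noiseless case is exactly linear in
the mixture fractions, which is the property decomposition methods rely
on, and which makes exact-recovery tests meaningful to machine
precision.

What this generator does *not* emulate: peak broadening and overlap,
dye mobility shifts, base-caller miscalls, primer-proximal noise, and
the AB1 container format (chromatograms are exchanged as per-scan
4-channel TSV; proprietary trace files must be converted externally).
Passing tests therefore demonstrate correctness of the decomposition
arithmetic and statistics under the declared peak model, not robustness
to real-trace artefacts.

## Simulated references and decomposition

Instead of requiring a sequenced reference for every product, the
reference for each indel size $s$ is *simulated by modifying the
control sequence itself*: $s > 0$ inserts repeat-unit-phased bases at
the target site (so the shift equal to the loop length reproduces the
expansion product exactly), $s < 0$ deletes bases there. The per-shift
noiseless traces over the fitting window form the template matrix.

Defaults, declared rather than inferred (the original analysis does not
report them): shift range $-15 \ldots +15$ nt; fitting window starting
5 scans downstream of `target_site + max_insert` and spanning 80 scans,
so every template's indel lies fully upstream of the window and the
templates differ by pure sequence shifts; significance threshold
$\alpha = 0.001$.

The fit flattens the window's four channels into one observation vector
(320 observations) and solves non-negative least squares
(Lawson–Hanson). A non-negative constant *baseline* column is fitted
alongside the templates (default on): measured traces sit on a noise
floor, and the zero-clipped noise model likewise leaves a small
positive mean on empty channels; without the baseline term that floor
leaks into the shift components. The baseline coefficient is reported
separately and excluded from component fractions.

Standard errors come from the variance–covariance matrix
$\hat\sigma^2 (A_\mathcal{A}^\top A_\mathcal{A})^{-1}$ of the
unconstrained normal equations restricted to the active (non-zero) set
$\mathcal{A}$, with
$\hat\sigma^2 = \mathrm{RSS}/(n_\mathrm{obs} - |\mathcal{A}|)$; each
active component gets a two-tailed t test. Rank deficiency of the
template matrix (e.g. repeat-phased shifts inside a periodic tract,
where the shift split is unidentifiable) raises a degeneracy error
naming the collinear shifts instead of returning an arbitrary split.

Two normalisations are reported side by side, since it is ambiguous
whether quoted trace-signal percentages refer to the decomposed signal
only or include the unexplained residual: the *fraction* (coefficient
over the sum of all coefficients) and the raw *coefficient* (templates
are unit-total-fraction traces, so the coefficient estimates the molar
fraction directly and implicitly leaves room for residual). Recovery
tests use the coefficient; across planted fractions 0.1–0.7 at
`noise_sd` 0.01 its bias is ≈ −0.004 (competing components can only
add, so they absorb a sliver of shared signal), comfortably inside the
±0.01 band the tests assert.

## Multiple testing and calibration

No multiple-testing correction is applied by default, matching the
convention of the trace-decomposition tool family; a Bonferroni option
is exposed. The consequence is quantified rather than hidden: with ~30
shifts tested per trace at per-component $\alpha$, the probability that
*some* shift is spuriously significant in a null trace is ~$30\alpha$
by construction. The calibration suite therefore asserts two
properties over 1,000 null replicates: the *per-shift* spurious rate
stays within $\alpha$ plus binomial error (the t statistic is
calibrated), and the *per-run* spurious rate under the Bonferroni
option stays within $\alpha$ plus binomial error (family-wise control
is available when wanted).

## Problem sizes and degenerate inputs

The test and acceptance suites run at the study's scales: a 3,200-nt
substrate, 75-nt reads, 50,000 reads for distribution-level checks
(total-variation distance to the planted profile ≤ 0.02, per-read
round-trip identity ≥ 99%), 20,000 reads for the incision-scenario
checks, 20 seeded replicates for planted-fraction recovery, and 1,000
replicates for null calibration; property tests use 300–1,600-nt
substrates. Degenerate inputs are defined, not accidental: zero reads
give empty outputs, an all-zero profile with reads requested is an
error, zero mapped reads give an all-zero profile without division
errors, an empty loop makes the heteroduplex collapse to the duplex and
the rescue pass vacuous.

## Known limitations

* The aligner is ungapped; reads carrying indel sequencing errors are
  outside its model (substitutions only, within `max_mismatches`).
* Loop placement in repeat-rich context can make loop-spanning reads
  ambiguous; the substrate builder warns when the loop sequence occurs
  elsewhere in the duplex.
* The chromatogram model's linearity is an idealisation; quantification
  from real traces inherits whatever deviations real peak shapes
  introduce, and no mobility correction is attempted.
* Incision presets are qualitative geometry with chosen magnitudes, not
  fitted distributions; conclusions about *recovery* of a planted
  profile do not certify the profile itself.
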