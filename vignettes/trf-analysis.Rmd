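---
title: "Counting and comparing tRNA-derived fragments: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and comparing tRNA-derived fragments: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfquant)
```

## The problem

tRNA-derived fragments (tRFs) are 14–40 nt products of regulated tRNA
cleavage. The three major types are positional: tRF-5 fragments are 5'
prefixes of the mature tRNA, tRF-3 fragments are 3' suffixes (and therefore
end in the post-transcriptionally added CCA), and tRF-1 fragments are the
3' trailers of pre-tRNAs, which the mature molecule does not contain.
Because the catalogue of annotated fragments is small and their sequences
are known exactly, abundance can be measured by counting annotated
sequences directly in the reads of a small RNA library — no genome
alignment, no assembly. `trfquant` implements that workflow end to end:
reference construction, counting of tRFs, intact tRNAs and mature miRNAs,
length-based classification, per-group statistics, codon-level aggregation
of tRNA abundance, and the downstream target-repression readouts used when
a fragment is suspected of miRNA-like silencing.

## Reference model

The counting reference is an "artificial genome" of unique sequences:

1. tRNA gene bodies are read from a GtRNAdb-style FASTA. Inputs are taken
   as intronless gene bodies; no splicing is attempted.
2. The mature sequence is the gene body plus `CCA`, appended
   unconditionally (nuclear and mitochondrial alike). Genomically encoded
   CCA is deliberately not detected: a body that already ends CCA yields a
   mature ending `CCACCA`. The rule is deterministic and documented, which
   we prefer to a heuristic that silently deduplicates.
3. Identical mature sequences are collapsed into one entry whose id is the
   lexicographically first member gene; the full member and isoacceptor
   family sets are retained. Collapsing is idempotent and partitions the
   input gene set — both properties are asserted in the test suite.

A fragment's *parents* are isoacceptor families (amino acid + anticodon,
e.g. `Gly-GCC`), not loci: a tRF-5 is anchored to every family whose
mature sequence it prefixes, a tRF-3 to every family whose mature it
suffixes. tRF-1 fragments keep their declared parents, since the trailer is
absent from the mature reference — the same reason their sequences are
reported `UNCHECKED` rather than validated.

## Counting rules

All matching is on normalized uppercase DNA (U→T at the I/O boundary).

* **tRFs, exact mode (default).** A read is assigned to a fragment iff,
  after stripping at most `trim_trailing_a` 3' A's (fewest stripped wins),
  it equals the fragment sequence. The poly-A allowance exists because the
  library protocol polyadenylates small RNAs before reverse transcription;
  the default is 0.
* **tRFs, contained mode.** The fragment must occur as a substring of the
  read; a read containing several fragments goes to the longest one, ties
  to the lexicographically smallest id. Useful when adapters or tails were
  left on the reads.
* **tRNAs.** Reads shorter than `min_read_len` (default 40 nt) are
  discarded: only long reads are accepted as evidence of an intact tRNA
  rather than a fragment. A surviving read matches an entry iff it occurs
  as a substring with at most `max_mismatches` Hamming mismatches
  (default 0, no indels). Reads matching two or more collapsed entries are
  counted as ambiguous and dropped, not fractionally assigned — fractional
  counts would break the integer read ledger that every stage must
  conserve.
* **miRNAs.** Exact mode against mature miRNA sequences, same contract as
  tRFs.

Alignment-based small-RNA workflows typically map such reads with Bowtie
under undocumented parameters; we replace alignment with these documented
exact/Hamming rules
because they are deterministic and checkable against a brute-force
all-offsets scanner, which the tests do for mismatches 0–2.

Every sample keeps an exact ledger:
`assigned + ambiguous + filtered + unmatched == total`. This identity is
asserted on every simulated library in the acceptance tests.

**RPM.** Reads per million are computed within a feature class — the tRF,
tRNA and miRNA pools come from separately prepared (gel-excised)
libraries, so each class has its own denominator, the per-sample total of
assigned reads of that class. A whole-library denominator is available via
`rpm(, denominator = "library")`.

## Classification

Subtypes are assigned from length alone:

| major type | subtype | length (nt) |
|---|---|---|
| tRF-5 | 5a / 5b / 5c | 14–16 / 22–24 / 28–30 |
| tRF-3 | 3a / 3b | 17–19 / 21–23 |
| tRF-5 or tRF-3 | half | > 30 |
| tRF-1 | 1 | ≤ 40 |

The tRF-3 literature gives point lengths (18 and 22 nt); we adopt ±1 nt
windows so that real annotations do not fall through, and the windows are
arguments. Lengths in the gaps return `unclassified`, never the nearest
bin. tRNA halves — anticodon-loop cleavage products — are called by length
only (>30 nt); cleavage-site inference is out of scope. Internal fragment
vocabulary (i-tRF, tRF-2, A/V/D-tRF) is recognized but not classified,
because the annotated catalogues this pipeline counts carry only types
1/3/5. The 5'-oligo-G motif (putative translation-initiation inhibitors) is
a strict prefix rule: the first `min_run` (default 4) bases must all be G.

Codon-level aggregation maps each entry's anticodon to the codon it
decodes (reverse complement, reported in RNA alphabet) and sums group-mean
RPM over the 64-codon table. Up/down calls use an explicit 1.5-fold default
threshold — the figure this view reproduces does not state its thresholds,
so ours are declared tool defaults, configurable per call. Stop codons have
no cytoplasmic decoder and are always reported `absent`.

## Group statistics

Differential representation follows the classic small-RNA recipe: plain
arithmetic means of RPM per group, fold change as the ratio of means
(tumor/normal), and a two-sided unpaired t test on the RPM values.
"Unpaired t test" is taken in its conventional sense — Student's
pooled-variance test — with Welch behind a flag. No multiple-testing
correction is applied by default, keeping raw significance as the primary
readout; Benjamini–Hochberg is available via
`p_adjust = TRUE` and lands in an extra column. When either group mean is
zero the fold change uses a pseudo-value (default 0.5 RPM) on both means;
the policy and value are recorded in the output metadata. Degenerate
inputs are resolved deterministically: identical values in both groups
give t = 0, p = 1; fewer than two samples in a group gives a missing
p-value; zero pooled variance with unequal means gives p = 0.

The heatmap export is `log2((rpm + eps) / (mean normal rpm + eps))` per
sample with `eps = 0.5`, i.e. every sample, normal ones included, is shown
against the normal-group mean.

Target integration uses the two-sample Kolmogorov–Smirnov test for the
ECDF-shift readout (CDF-shift figures in this literature rarely name a
test; KS is the standard choice and is oracle-checkable), always
co-reporting medians and exporting ECDF coordinates. The asymptotic
p-value is the default since gene sets are large and ties are common.
Reciprocal tRNA–tRF analysis works at the isoacceptor-family level
(family-summed RPM) because fragment parentage resolves to families, not
loci; the default thresholds are the same 1.5-fold pair used elsewhere.

## The synthetic-data generator

The generator exists so that every stage is testable without downloads. It
emulates a lung-tissue tumor-versus-normal study design as defaults:

* 3 normal vs 5 tumor libraries;
* a catalogue of 122 fragments — 22 tRF-1, 48 tRF-3, 52 tRF-5 — over 24
  isoacceptor families, plus 60 miRNAs;
* group-level tRF type composition 7.51 / 52.55 / 39.94 % (tRF-1/-3/-5) in
  normal tissue and 1.01 / 24.77 / 74.22 % in tumor;
* log-normal baseline abundances (`meanlog = 3`, `sdlog = 1.5`, a heavy
  right tail typical of small RNA libraries; only proportions matter) with
  negative-binomial sampling (`Var = mu + mu^2/k`, default `k = 10`,
  `k = Inf` giving the Poisson limit);
* 100,000 reads per sample and class, substitution-only errors at a
  configurable per-base rate (default 0).

Counts are drawn by a gamma–Poisson scheme conditioned on the library
size: per-sample gamma intensities with shape `k` around the group mean,
then one multinomial draw of exactly `reads_per_sample` reads. This is the
negative-binomial model conditioned on the total, so library sizes are hit
exactly while between-sample overdispersion is preserved. Planted
log2 fold changes multiply the tumor means; because proportions
renormalize, the generator records both the planted effect and the
realized per-group expected proportions as ground truth, and recovery is
judged against the realized values. All randomness flows from one master
seed through a fixed per-stage offset scheme, so the reference, the
counts and the reads are each independently reproducible; generator
functions force their arguments before seeding so that lazily evaluated
calls cannot interleave the streams.

What the generator does *not* emulate: sequencer-specific error profiles
(e.g. semiconductor chemistries such as Ion Torrent, whose dominant
  errors are indels),
ligation and RT biases, modification-induced stops, adapter read-through,
and genomic background reads. Reads are error-free copies (or point
mutants) of annotated molecules. Passing the recovery tests therefore
shows that the counting, normalization and testing machinery is correct
under the stated statistical model — not that the pipeline is robust to
every artifact of real libraries. Real-data robustness rests on the
explicit matching rules and on the ledger, which make every lost read
attributable.

## Problem sizes and numerical choices

The test and acceptance workloads use desk-scale sizes chosen to keep the
suite fast while leaving the statistics meaningful: type-composition
recovery uses single 100,000-read libraries (binomial 99% CI of ±0.4
percentage points); null calibration uses 2,000 features at 3 vs 5
samples and two million reads per sample; fold-change recovery uses 50
planted ±1 effects over 20 replicate simulations of 200,000 reads per
sample, with recovery required within ±0.15 log2 units; the
Hamming-scanner cross-check covers >1,000 read/reference pairs at
mismatches 0–2. Reproducing any real study's dataset-level tallies — the
numbers of detected fragments, miRNAs and tRNAs in particular patient
libraries under particular database releases — is out of scope; the
generator reproduces such designs in structure, not in number.

Numerical conventions worth knowing: RPM columns of a non-empty class sum
to 1e6 within floating tolerance; fold changes of all-zero features use
the pseudo-value ratio (hence 1 when both means are zero); `cdf_shift`
demands both strata non-empty and names the offending stratum otherwise;
fragment positions in exported tables are 1-based inclusive on the mature
sequence.

## Worked example

```{r example, eval = FALSE}
library(trfquant)

cfg <- sim_config(seed = 1L)
simref <- make_reference(cfg)
sim <- simulate_counts(simref, cfg)
reads <- simulate_reads(sim, simref)

counts <- count_trfs(reads$tRF, simref$trfs)
calls <- classify_trfs(simref$trfs, simref$ref)
type_distribution(counts, calls, sim$design)

d <- diff_expression(rpm(counts), sim$design)
head(d[order(d$p_value), ])
```

The same analysis, driven by files, is one call:
`run_pipeline(list(outdir = "run1", simulate = TRUE, seed = 1))`, or from
a shell via the wrapper in `inst/scripts/trfquant.R`.

## Known limitations

* Exact/Hamming substring matching cannot absorb indels; on indel-prone
  chemistry, contained mode recovers some but not all affected reads.
* Ambiguous tRNA reads are discarded, so paralogous families with long
  shared stretches are undercounted relative to a fractional-assignment
  scheme.
* The t test is applied to RPM values, as in the classic workflow, not to
  a count model; for small libraries a negative-binomial GLM would
  have better power, and is deliberately out of scope.
* Fragment discovery is out of scope: only annotated catalogues are
  counted, so novel fragments are invisible.
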