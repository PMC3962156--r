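---
title: "Chromatogram provenance, base mis-calls, and their downstream cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatogram provenance, base mis-calls, and their downstream cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provseq)
```

## The problem

Sanger sequencing machines emit chromatograms (traces) and a base-call
string derived from them. Base callers make mistakes — misidentified
bases, spurious insertions, dropped bases, and duplicated calls from
widened peaks — and in practice these are corrected by a human looking
at the trace. Done cell by cell over a whole multiple sequence
alignment (MSA), that inspection is the slowest step of many
population-level sequencing studies.

`provseq` inverts the workflow. Instead of curating every read before
alignment, it assembles reads into consensus sequences while recording,
for every base, the *chromatogram position* it came from: the 1-based
index of the base call in the full, untrimmed raw read. Any cell of an
MSA built from the resulting preliminary FASTA can then be mapped back
to the exact call(s) that produced it with a few integer operations. We
call this the chromatogram-provenance property: an alignment that has it
can be audited cheaply, because only the suspicious cells — ambiguity
codes and low-frequency polymorphisms — need visual inspection, and the
tool prints exactly which trace positions to look at.

The second half of the package quantifies why this matters: it simulates
neutral coalescent data, injects sequencing errors at empirically
motivated per-base rates, and measures the damage to standard
population-genetic summaries and to tree reconstruction metrics.

## Assembly with provenance

**Trimming.** Raw reads carry undetermined, N-rich edges. Trimming is
deliberately manual: the user replaces the last *X* characters of the
left edge and the first *Y* characters of the right edge with gap runs
("trim indicators"). `parse_trim_indicators()` converts these to cut
lengths; automatic quality-based trimming is out of scope by design,
because any trimming the tool cannot see would silently break the
position arithmetic. With two gap runs the assignment is unambiguous. A
single run is assigned to the left edge when it starts in the first half
of the read and to the right edge otherwise; the midpoint rule is
arbitrary but deterministic, and it is documented here because no
natural convention exists for that corner case. Internal gaps beyond
the two indicator runs are rejected as user errors — base callers never
emit gaps.

**Consensus.** For a forward/reverse pair, the trimmed reverse read is
reverse-complemented (references keep their original raw-read positions
and raw calls) and locally aligned to the trimmed forward read with a
naive Smith–Waterman implementation (linear gap penalty; default scores
+1/−1/−2; a user matrix over the 15-letter IUPAC alphabet is accepted).
The non-overlapping overhangs are reattached, and the consensus is built
column by column:

* equal characters keep the character, carrying both references;
* a gap against a character keeps the character (*the insertion variant
  is always selected*) — a spurious inserted base therefore survives
  into the consensus, where it later produces a gap-dominated MSA column
  that the polymorphic-site scan flags;
* two distinct unambiguous characters become `N` (N strategy) or the
  IUPAC code of the pair (AMB strategy), and both raw calls are kept as
  the recorded mismatch pair;
* an unambiguous character beats an ambiguous one;
* two distinct ambiguity codes resolve to `N` under either strategy —
  the rule set does not otherwise cover this case, `N` is the
  conservative choice, and the ambiguous-character scan will flag the
  cell anyway.

Smith–Waterman tie-breaking (diagonal, then vertical, then horizontal;
smallest end row, then column) is fixed so that assemblies are
bit-reproducible. An alignment scoring below `min_overlap_score`
(default 8) raises an error instead of producing a nonsense consensus,
since the pipeline presumes partially overlapping reads.

**Preliminary file and sidecar.** `write_preliminary_fasta()` emits the
clean unaligned sequences plus a versioned JSON sidecar holding every
per-base reference and trim specification. The MSA step itself is
external — any aligner may be used — and `validate_msa_consistency()`
checks, name-keyed and order-independent, that the alignment rows
degap back to exactly the sidecar sequences before any mapping is
trusted.

**Detection.** `acd_scan()` reports every ambiguity-code cell with its
chromatogram position(s). `psd_scan(threshold = t)` reports a column
when at least two nucleotides are present and the non-majority fraction
(among A/C/G/T cells; ties broken alphabetically, ambiguity codes are
the ACD scan's domain, gaps excluded from the denominator) is at most
`t`, and additionally when a column that contains gaps has a non-gap
fraction of at most `t` — the signature of the always-selected insertion
variant. The default `t = 0.1` flags a 1-in-10 minority. Whether the
published threshold denominator includes gaps is not stated anywhere we
could verify; excluding them is consistent with the worked report
example (nine A, one G, "remaining characters, if any, are gaps") and is
flagged here for users with unusually gappy alignments.

## The sequencing-error model

`error_model()` holds four per-base, per-sequence rates; the two named
presets are

| preset | misidentification | insertion | deletion | extension |
|--------|------------------:|----------:|---------:|----------:|
| `errA` | 0.001             | 0.0001    | 0.0001   | 0.0001    |
| `errB` | 0.01              | 0.0005    | 0.0005   | 0.0005    |

Errors are injected into alignment rows post hoc, preserving site
homology: an insertion or extension creates a new column holding one
character and gaps elsewhere; a deletion gaps the cell but keeps the
column. Substitutions draw uniformly from {A, C, G, T, N} *excluding*
the current base, so a drawn event is always an actual error and the
rates are interpretable; `allow_self = TRUE` restores the unrestricted
reading (the published description is ambiguous on this point). At most
one frameshift event fires per base, realised by partitioning a single
uniform draw into deletion/insertion/extension bands, which preserves
the marginal rates exactly. The event log replays deterministically and
inverts bit-exactly (`replay_events()`, `revert_errors()`).

## The simulation suite

Coalescent genealogies are sampled in units of 4Ne generations
(E[TMRCA] = 1 − 1/n), under constant size or ms-style exponential
growth with an onset time that caps the rescaling; the cumulative
coalescent intensity is inverted in closed form, which keeps negative
growth rates safe. Sequences evolve under GTR+Γ via the
eigendecomposition of the reversible rate matrix, with four discrete
mean-rate categories (the field's convention). The packaged default
parameters (exchangeabilities 1.6/4.3/1.2/1.1/5.9/1, frequencies
0.27/0.22/0.26/0.25, α = 0.5) are typical empirical estimates for a
large multi-species nucleotide alignment; the published study fit its
own empirical values, which are not printed anywhere, so no result here
depends on matching them. Scaling coalescent branch lengths by 0.01
yields θ = 10 mutations per kilobase per 4Ne generations for 1 kb loci.

`simulate_infinite_sites()` drops Poisson mutations on branches, each
creating a new 0/1 column with known ancestral state. This is the
mutation model under which the classical estimators are exact
(E[S] = θ·a_n), and it is what the summary-statistic and ABC machinery
consume; the finite-site GTR simulator necessarily undershoots that
identity by a few percent through multiple hits, which is why the
Watterson calibration checks run on the infinite-site path while the
mis-call experiments, which compare errored to clean copies of the same
finite-site alignments, are unaffected.

Alignments are binarised column-wise (majority nucleotide → 0, others
→ 1, ties alphabetical). N and the other ambiguity codes are treated as
missing by default (`n_handling = "minor"` codes N as a minor allele
instead — how the published analysis counted N is unstated). Summaries:
segregating sites, folded SFS and singletons, θπ with a missing-aware
pairwise denominator, Watterson's θW, Tajima's D with the standard
constants, Kelly's ZnS (mean r² over segregating-site pairs), and Fay &
Wu's H. Because majority-based binarisation destroys ancestral
identity, the SFS is folded and H is only defined when the simulator's
true ancestral states are available — on real binarised data it returns
`NA` rather than a silently wrong value.

## Rejection ABC

`abc_reject()` draws parameter vectors from uniform priors (defaults:
θ ∈ (0.1, 200) per kb, growth rate ∈ (−10, 10), onset ∈ (0, 4) in 4Ne
units — the published priors are not stated, so downstream conclusions
use only prior-robust quantities), simulates a multi-locus dataset per
vector (20 loci × 1 kb × 100 sequences by default), standardises each of
the averaged summaries (θπ, θW, ZnS, H) by its across-simulation
standard deviation, and retains the closest vectors under Euclidean
distance. No regression adjustment is applied. Point estimates are the
marginal kernel-density mode (Silverman bandwidth) and the median; the
two conventions disagree in skewed posteriors, so both are always
reported. Accurate posteriors need on the order of 10^5–10^6
simulations; the test suite exercises the machinery at a few thousand
simulations and checks seeded determinism, exact-match retrieval, and
that the true θ lies inside the central 95% of the retained sample on
clean data — not posterior accuracy, which is a budget question, not a
correctness one.

## What the synthetic fixtures do and do not show

`generate_read_pair_fixture()` emulates bidirectional Sanger runs: a
random template, 5′- and 3′-anchored overlapping read windows, N-rich
undetermined edges, user-style trim indicators, and optional substitution
mis-calls, with ground-truth chromatogram coordinates for every template
position. The test suite drives the full pipeline over a thousand such
pairs and requires every single MSA cell to map back to its true trace
position. What the fixtures do not emulate: real peak-height ambiguity
(the synthetic `peak_index` is carried but meaningless), frameshift
read errors inside the pipeline (frameshifts are modelled at the
alignment stage, where homology bookkeeping is exact), chimeric reads,
and recombination. Passing tests therefore certify the provenance
arithmetic and the detection logic, not the base caller.

## Numerical and design choices

* Coordinates are 1-based and closed everywhere (MSA columns,
  chromatogram positions); `-` is the only gap character and `N` is a
  base call, never a gap.
* Fold-changes between errored and clean replicate distributions are
  computed as ratios of replicate means. Per-replicate ratios are
  undefined whenever a clean replicate has a zero count (for singleton
  counts this happens with non-negligible probability at θ = 10) and
  are upward-biased by small denominators; the ratio of means is the
  quantity one reads off a pair of replicate histograms.
* Replicate sizes used by the shipped analyses: 500 replicates for the
  mis-call fold-change study, 2 000 for the coalescent calibration
  checks, 200 for the bias-direction comparison, and 1 000 read pairs
  for the provenance round-trip — sizes at which the Monte-Carlo error
  of every reported mean is far below the effects being measured.
* The degenerate-input policy is explicit everywhere: Tajima's D, ZnS
  and H return `NA` below their preconditions; all-missing binarised
  columns are retained but flagged; degenerate (zero-variance) ABC
  summaries are dropped with a warning.

## Known limitations

Consensus generation supports exactly one forward/reverse pair per
sample. Recombination is not detected, and a recombining or highly
diverse alignment will simply produce larger reports. Error rates are
uniform along the read, although real traces degrade toward the ends.
ABIF support is a read-only subset (called bases and peak locations);
trace curve rendering and chromatogram editing are out of scope. The
polymorphic-site scan is a triage tool: it neither removes sites nor
corrects calls, because deleting low-frequency polymorphisms wholesale
would discard genuine singletons along with the errors.
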