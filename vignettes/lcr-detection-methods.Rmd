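---
title: "Detecting low complexity regions in proteins: methods and design notes"
author: "lcrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting low complexity regions in proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcrtools)
```

# The problem

Low complexity regions (LCRs) are stretches of protein sequence with
markedly reduced amino-acid diversity: homorepeats such as polyglutamine,
short tandem repeats (STRs), and compositionally biased tracts enriched in
one or a few residue types without a repeating pattern. They are
over-represented in disordered regions, often conserved, and implicated in
phase separation and repeat-expansion diseases. There is no single agreed
definition of "low complexity", so the established detectors formalize the
idea in genuinely different ways. `lcrtools` implements five complementary
detectors behind one interface, plus an annotation layer (entropy track,
composition comparison, per-region enrichment), strict/permissive consensus
operators, and a command-line tool over FASTA input.

All detectors consume a validated `seq_record` (uppercase, 20 canonical
letters plus `X` for unknowns; the ambiguity codes B/Z/U/O are mapped to
`X` on input, a trailing `*` stop is stripped) and return a common
`lcr_regions` table with 1-based inclusive coordinates, so outputs can be
written uniformly as TSV, GFF3, or per-region FASTA, and combined by the
consensus operators.

# The five detectors

## SEG: two-pass entropy segmentation

The Shannon complexity of a length-$L$ window is
$$K_2 = -\sum_{i:\,n_i>0} \frac{n_i}{L}\log_2\frac{n_i}{L},$$
in bits/position, where $n_i$ counts residue type $i$. A first pass flags
trigger windows of length $W$ with $K_2 \le K_1$; any window with
$K_2 \le K_2^{ext}$ that chains through overlapping low-complexity windows
to a trigger joins the same *contig*. Within each contig a brute-force
second pass finds the subsequence minimizing the composition probability
$$P_0 = \frac{F \cdot \Omega}{20^L},\qquad
  F = \frac{L!}{\prod_i n_i!},\qquad
  \Omega = \frac{20!}{\prod_k r_k!},$$
where $r_k$ is the number of residue types occurring exactly $k$ times
(including $k = 0$). The reported score is $\log_{10} P_0$. All factorials
are evaluated with `lgamma` in natural-log space; a subsequence beats the
incumbent only if its log-probability is smaller by more than $10^{-12}$,
with ties broken toward the longer subsequence and then the smaller start,
so results are exactly reproducible. Defaults are the canonical
$W = 12$, $K_1 = 2.2$, $K_2^{ext} = 2.5$; the `intermediate`
(15/1.9/2.5) and `strict` (15/1.5/2.8) presets narrow the search toward
longer eukaryotic repeats and strongly biased-yet-diverse tracts
respectively. Whether the original implementation triggers on strict or
non-strict inequality at the threshold is not documented; `lcrtools` uses
$\le$ (with a $10^{-9}$ float guard), which can differ at exact-boundary
windows.

`X` contributes to window length but to no $n_i$, so unknown-rich windows
score as low complexity; for $P_0$ the multinomial is ill-defined for
unassigned positions, so `X` positions are dropped from the composition
($L$ counts non-`X` residues there).

## CAST: similarity to homopolymers

Compositional bias is detected implicitly, as a high Smith–Waterman local
alignment score against an unbounded homopolymer of each of the 20
residues, under BLOSUM62 with an infinite gap penalty. With gaps forbidden,
the alignment reduces *exactly* to the maximum-sum contiguous segment of
the per-position substitution scores $s_j = \mathrm{BLOSUM62}[a_j, t]$ —
this reduction is part of the contract and is enforced in the tests against
a full dynamic-programming oracle. The best segment over all targets is
reported if it reaches the threshold (default 40, the method's classic
default), the target residue's occurrences inside it are masked with `X`
(which scores 0 against everything), and the search repeats. Masking only
the bias residue lets overlapping biases of different residues surface in
later rounds.

One degenerate case needs care: the winning segment can contain *no*
occurrence of its target — e.g. a $(VL)_n$ tract scores
$3 + 2$ per dipeptide against isoleucine, reaching 40 by length alone. The
target-only masking rule would then make no progress and the iteration
would never terminate. In that case `lcrtools` masks the entire winning
segment, which is the natural reading of "mask the region of highest
similarity" and guarantees strict progress; the case is rare and the
emitted region is unchanged.

## fLPS: lowest probability subsequences

A window of length $w$ containing $k$ copies of residue $a$ with
background frequency $p_a$ is scored by the binomial tail
$P(X \ge k),\ X \sim \mathrm{Bin}(w, p_a)$, evaluated in log space via
`pbinom(..., log.p = TRUE)`. The search has three stages:

* **QUICKSCAN** flags windows whose tail probability is at most $t$,
  stepping by $m$, and merges overlapping flagged windows into contigs.
  The pre-scan runs at two scales — coarse windows of length
  $\min(M, L)$ and fine windows of length $m$. A single near-global
  coarse window (the default $M = 500$ exceeds many protein lengths)
  dilutes short dense tracts below the gate: a 21-residue polyQ inside a
  500-residue protein shifts the whole-sequence glutamine count by barely
  two standard deviations. The fine scale ensures such tracts always seed
  a contig; since the next stage is exhaustive, the pre-scan influences
  only which neighborhoods are examined, never the score of anything
  reported.
* **MINIMIZATION** extends each contig by $M-1$ on both flanks (clipped to
  the sequence) and evaluates *every* window of length $M$ down to $m$ at
  every offset, keeping the minimum-tail window; it is emitted iff
  $P \le t$, one region per contig, ties toward longer-then-leftmost.
* **MERGE** combines overlapping or near-adjacent (gap $\le m$) regions of
  different residue sets when the union span, scored over the combined set
  $R$ with $p_R = \sum_{a \in R} p_a$, has a strictly smaller tail
  probability than both parents; candidate pairs are processed by
  ascending combined $P$ (ties leftmost) to a fixpoint, which makes the
  result order-independent. Finally each region is greedily trimmed or
  extended one residue at a time while its $P$ strictly decreases, so every
  reported region is locally optimal — a property the tests assert
  directly.

Defaults $m = 15$, $M = 500$, $t = 10^{-3}$ are the method's classic
defaults; the published `strict` preset ($m = 5$, $M = 25$, $t = 10^{-5}$)
targets short, strongly biased tracts. The null composition defaults to
uniform $1/20$; a bundled SwissProt-like composition table
(`swissprot_profile()`) or any user table can be substituted. Note that
$t$ is a per-window threshold: across the many windows of a long random
sequence, occasional sub-threshold windows are expected and are reported
as such.

## SIMPLE: motif repetitiveness against shuffled nulls

Each position $i$ receives a simplicity score
$$S_i = \sum_{\ell} \ell \cdot \#\{\text{other occurrences of the }
\ell\text{-mer starting at } i \text{ inside the window anchored at } i\},$$
with overlapping occurrences allowed and motifs containing `X` scoring 0.
Windows are full-width and centered, shifting inward at the sequence ends
so every position sees the same amount of context. Significance is decided
against `n_random` composition-preserving shuffles of the same sequence:
all positional scores of all shuffles are pooled into one empirical null,
and positions scoring strictly above the $1-\alpha$ null quantile are
significant; maximal significant runs become regions scored by their mean
$S_i$. The strict inequality means a degenerate all-equal null (e.g. a
pure homopolymer, whose shuffles are all identical to itself) never
declares everything significant.

The original protein adaptation of this method does not document its
scoring weights and window numerically, so these defaults — window 65,
motif lengths 1–3, 100 shuffles, $\alpha = 0.05$, seed 42 — are *toolkit
choices*, documented here precisely because they are not
reference-faithful constants: positions-for-position agreement with the
original binary should not be expected. Pooling one global null rather
than per-position nulls is a simplification that keeps the decision rule
monotone in $\alpha$ (tested). All randomization goes through an internal
seed-scoped RNG, so runs are reproducible and the caller's RNG state is
untouched.

## GBSC: repeats from 2-mer transition graphs

The sequence becomes a weighted directed graph: nodes are the observed
2-mers, and each position $i \le L-2$ adds one unit of weight (and records
$i$) on the edge from the 2-mer at $i$ to the 2-mer at $i+1$; 2-mers
containing `X` are skipped. On an `X`-free sequence the edge weights sum
to $L-2$ — an invariant the tests assert. A repeat unit of length $k$
corresponds to a simple cycle of $k$ edges (a self-loop for a homorepeat,
a 2-cycle for a dinucleotide-style STR, up to 4 edges, i.e. unit length
~4; longer units drift toward domain repeats and are out of scope).
Cycles whose minimum edge weight reaches `min_occ` qualify; their recorded
positions are projected onto the sequence and positions separated by at
most `window` residues are merged into candidate intervals. This gap
bridging is what tolerates substitutions and short insertions inside
imperfect repeats. An interval is reported when its traversal count —
in-interval transitions divided by the cycle length — reaches `min_occ`;
the unit is canonicalized to its lexicographically smallest rotation so
different phases of the same repeat compare equal.

The published description of this method is a short summary (its full
supplementary specification was not available), so the cycle-weight
criterion, the gap-bridging rule and the unit labeling here are a
faithful-in-spirit reconstruction; outputs should not be assumed identical
to the authors' implementation. Defaults `window = 15`, `min_occ = 3` are
toolkit choices: at least three unit copies is the conventional minimum
for calling a tandem repeat, and a 15-residue bridge tolerates
single-residue interruptions without fusing unrelated repeats.

# Annotation and consensus

`entropy_track()` reports the SEG window entropy of the window centered at
each position (default width 7, the scale at which short LCRs become
visible); the first and last $(w-1)/2$ positions are explicitly undefined
rather than computed from clipped windows, so values are comparable along
the sequence — a deliberate contrast with SIMPLE's shifted windows, where
a comparable context is exactly what the score needs.
`aa_frequencies()` / `compare_frequencies()` give per-residue composition
against a reference profile (difference and ratio, with the ratio
undefined where the reference is 0). `region_enrichment()` calls a residue
enriched when its in-region frequency is at least `ratio_min` (default 2)
times its background frequency with at least `count_min` (default 2)
occurrences; "enriched" has no standard definition, and a fold-change
with a minimum count is simple, monotone and configurable.

`consensus_regions()` operates on *positions*, not whole regions:
`intersection` keeps positions covered by every selected method (strict),
`union` by any (permissive). Positional semantics make the two operators
exact lattice duals and give the provable ordering
$\mathrm{coverage}(\cap) \le \mathrm{coverage(method)} \le
\mathrm{coverage}(\cup)$, asserted on random inputs.
`coverage_stats()` reports the fraction of residues covered by the union
of a region set — the proportion used to compare detector behavior across
sequence sets.

# Synthetic data

`generate_fixture()` builds test sequences from an explicit recipe:
background drawn i.i.d. from a stated composition, with planted
homorepeats, STRs (optionally corrupted at a per-position substitution
rate) and biased tracts (positions drawn from a small residue set) at
fixed coordinates, which are recorded in the record description for later
assertions. Generation is deterministic per seed. What these fixtures do
*not* emulate: realistic residue correlations, domain structure, and the
broad length/composition heterogeneity of real proteomes — so passing
planted-recovery tests demonstrates correctness of the detectors'
contracts, not field performance on natural sequences.

Two packaged scenarios deserve explanation:

* `synthetic_huntingtin_like()` mimics the polyQ architecture of the
  huntingtin N-terminus: a 21-residue glutamine homorepeat at residues
  18–38 followed by a proline-rich tract, in a generated background whose
  flanking features are glutamine-free so the longest Q run is exactly
  18–38 for every seed. It is a synthetic stand-in, not the natural
  sequence; it preserves the property under test (all five detectors
  should localize the reduced-complexity region around the tract).
* The repeat-rich set used by the acceptance script (50 sequences of
  length 300, each with a 12-residue homorepeat and a 16-residue STR,
  ~9% planted — a realistic LCR density) is compared against its
  composition-preserving shuffles. The background composition of each
  fixture is *balanced* against the planted residues so the overall
  composition stays near-uniform. This matters: a shuffle preserves
  composition by construction, so if the fixtures themselves were
  strongly biased, the shuffled "control" would remain attractive to the
  composition detectors — fLPS in particular assigns its minimum tail
  probability to very long windows when a bias is diluted rather than
  locally arranged, and would cover *more* of such shuffles. Balancing
  composition makes the comparison isolate what a shuffle is meant to
  isolate: residue arrangement. For the same reason fLPS enters this
  comparison with its published strict preset, whose 5–25-residue windows
  are local at these sequence lengths.

# Numerical choices and degenerate inputs

* All probability work (SEG $P_0$, fLPS tails) is done in natural-log
  space; scores are reported as $\log_{10}$.
* Tie thresholds are $10^{-12}$ on log-probabilities, with deterministic
  tie-breaks (longer span, then leftmost) stated per operation.
* Records shorter than a detector's window yield empty results with a
  logged notice, not errors, so multi-record FASTA runs never abort on a
  short peptide; genuinely invalid inputs (empty sequences, unknown
  letters, duplicate identifiers, out-of-bounds regions) are errors that
  name the offending record and position.
* Scores in text output are printed with up to six significant digits and
  always a decimal point; coordinates are 1-based inclusive everywhere
  (TSV, GFF3, FASTA headers).

# Problem sizes used in the shipped checks

The test-suite and the acceptance script run entirely on generated data at
sizes chosen to exercise every code path at interactive speed: oracle
equivalence on 200 random sequences of length ≤ 80 (SEG and CAST against
brute-force references) and 500 random interval sets (consensus against a
per-position oracle); planted-feature recovery on single sequences of
length 60–500; and the repeat-rich versus shuffled comparison on
50 + 50 sequences of length 300 with 30-shuffle SIMPLE nulls. These sizes
are the package's own choice of a thorough-but-quick regression scale;
nothing in the implementation depends on them.

# Known limitations

* SIMPLE's scoring is a documented reconstruction (see above); its
  absolute scores are comparable only within this toolkit.
* GBSC's reconstruction covers units of length ≤ 4 and builds one graph
  per sequence; proteome-pooled graphs are future work.
* fLPS's multi-stringency output classes and whole-sequence bias labels
  are out of scope; one threshold $t$ governs emission.
* The bundled SwissProt-like composition is a static snapshot for
  convenience; analyses that depend on an exact database composition
  should supply their own table.
* The CLI accepts FASTA only; accession fetching, domain/transmembrane
  annotation and any web machinery are out of scope.
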