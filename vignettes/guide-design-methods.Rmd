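---
title: "Guide RNA design with genome-wide off-target counting: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide RNA design methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnadesign)
```

## The design problem

The *S. pyogenes* CRISPR/Cas9 system cleaves double-stranded DNA wherever
the ~20-nt spacer of the guide RNA (gRNA) base-pairs with genomic DNA lying
immediately 5′ of a protospacer adjacent motif (PAM), canonically NGG (the
relaxed NRG form also supports cleavage at reduced efficiency). Choosing a
guide therefore has two parts: find every 20-mer adjacent to a PAM in the
region of interest, and rank them by how *specific* they are in the genome
being edited, because a double-strand break at an unintended locus is a
permanent off-target edit.

Specificity is dominated by the **seed** — the 8–12 bases of the
protospacer immediately adjacent to the PAM, where mismatches most strongly
impair cleavage. A guide whose full 20-mer is unique may still cut
elsewhere if its seed+PAM occurs at many loci, so the package scores every
candidate at three resolutions: the complete target ("20mer+PAM") and the
12-mer and 8-mer seed suffixes ("12mer+PAM", "8mer+PAM"), each counted
genome-wide on both strands.

## Candidate enumeration

`enumerate_candidates()` scans both strands of the query for windows
matching the PAM pattern (IUPAC codes; degenerate positions become
character classes, so a window containing N never matches — see "N
handling" below) and emits a candidate for every full-length protospacer
5′ of such a window. Coordinates are reported 1-based inclusive on the
query's plus strand, spanning protospacer+PAM; minus-strand candidates are
reported with their protospacer-strand sequence and reflected coordinates.
Ordering is ascending start with "+" before "−" at ties. The query is
capped at 10 kbp — designs are local by nature, and the cap keeps every
stage interactive.

Each candidate carries three annotations relevant to guide choice:

* **GC percent** of the 20-mer, one decimal. Guides with extreme GC
  content tend to be less effective.
* **Melting temperature** of the 20-mer duplex, °C (see below).
* **TTTT flag**: four consecutive T's act as an RNA polymerase III
  terminator, truncating gRNAs expressed from pol III promoters (U6/H1),
  so TTTT-containing spacers should be avoided in such vectors. The flag
  is computed on the protospacer-strand 20-mer only, not on the PAM or
  flanks.

### Melting temperature

No single Tm convention exists, so the choice is pinned explicitly:
nearest-neighbor thermodynamics with the SantaLucia (1998) unified
parameter set, terminal-initiation corrections, and the entropy salt
correction ΔS′ = ΔS + 0.368·(N−1)·ln[Na⁺]:

Tm(K) = 1000·ΔH° / (ΔS′ + R·ln(C_T/4)),

with R = 1.987 cal K⁻¹ mol⁻¹ and C_T/4 the two-distinct-strand
approximation. Defaults are 50 mM Na⁺ and 0.5 µM total strand
concentration; both are `design_params()` fields and echoed into report
metadata (`tm_method`) so values are auditable. The test suite pins five
sequences to values frozen from an independent implementation of the same
published parameter set, plus monotonicity properties (GC-rich > AT-rich;
Tm increases with salt).

## Exact off-target counting

`build_index()` makes a single pass over each strand of every genome
record: at every PAM-matching window it records the k bases immediately 5′
of the window, for k ∈ {20, 12, 8}. `lookup_hits()` then answers the three
counts for any target in O(1). Design choices that define the semantics:

* **Degenerate PAMs are not expanded.** Counting is per (k-mer, pattern):
  the scan tests PAM windows positionally, so NRG costs one pass, not one
  pass per concrete expansion.
* **Counts include the on-target site.** The query need not come from the
  indexed genome, so no attempt is made to subtract "self": a count of 1
  means "exactly the intended site", 0 means the sequence does not occur in
  the genome at all — a warning, since such queries may span exon–exon
  junctions and the resulting gRNA would still cut wherever the parts map.
* **Overlapping windows all count**: GGGG contains two GG PAM windows.
* **Highlight rule.** "Relatively few off-targets" is made testable as
  `hits_full == 1 && hits_seed12 == 1`. The 8-mer count is reported but not
  gated — 8-mer+PAM uniqueness is essentially unattainable in genomes
  beyond tens of megabases, so gating on it would highlight nothing. Both
  counts are exported so users can apply stricter policies.
* **Memory.** Only k-mers observed 5′ of a PAM are stored, so index size is
  bounded by PAM-site count × |k|, not 4^k.

The index serializes to a versioned flat text file (header with PAM
pattern, lengths, Tm conditions and an md5 genome checksum; then
`k<TAB>kmer<TAB>count` lines) and round-trips exactly, so repeated designs
against one genome skip rebuilding.

### N handling

Genome and query sequences admit N as the only ambiguity code. A window
containing N — PAM or k-mer — never matches and is never counted, and
candidates whose 20-mer contains N are skipped entirely rather than
reported with missing annotations. This is a deliberate, conservative
choice: exact-count columns should mean "literal occurrences", and an
N-containing window is not a literal occurrence of anything. In the
approximate search, by contrast, N in the genome simply mismatches every
base, so near-matches interrupted by an N are still reported with the N
counted as a mismatch.

## Approximate off-target search

`search_approximate()` finds every locus alignable to the 20-mer with at
most `max_mismatches` substitutions and `max_gaps` indels (unit costs),
because Cas9 tolerates not only mismatches but also bulges — insertions or
deletions between guide and target — and a mismatch-only search overlooks
those loci. Two stages:

1. A **Myers bit-parallel scan** computes, for every end position on each
   strand, the minimum edit distance of the query to a window ending
   there. A 20-nt query fits comfortably in one 32-bit word. End positions
   within the total budget (mismatches + gaps) proceed; this screen is
   complete because any alignment within the componentwise budget has edit
   cost ≤ the total.
2. A **gap-layered dynamic program** re-aligns the query against each
   candidate span (every length m−g … m+g ending at a screened position),
   minimizing (n_gap, n_mismatch) lexicographically — gaps are rarer
   biological events than mismatches, so an alignment with fewer gaps is
   preferred even at the cost of a mismatch. Its traceback yields the
   aligned strings and the marker line (`|` match, `X` mismatch, ` ` gap).

Overlapping alignments are collapsed: hits on the same record and strand
whose spans overlap by ≥50% of the shorter span reduce to the
best-scoring one (fewest gaps, then fewest mismatches, then leftmost).
The 3 bases 3′ of each matched span (protospacer strand) are reported as
`pam_at_site` with a boolean `pam_ok`; by default the PAM is *reported,
not required*, since the detail view's purpose is to show loci by sequence
similarity, and `require_pam = TRUE` restores Cas9-realistic filtering.
Default budgets (≤3 mismatches, ≤1 gap) are package choices, exposed on
the CLI.

The zero-budget, PAM-required special case must equal the exact
"20mer+PAM" count; `count_consistency_check()` asserts exactly that and is
exercised across fixtures in the test suite — a cheap end-to-end guard
that the two engines share one definition of a hit.

## The synthetic-genome generator

`make_synthetic_genome()` is how every claim above is validated without
shipping organism genomes. It draws a uniform {A,C,G,T} background, plants
each requested site at a seeded, non-overlapping position (minimum 30-bp
spacing) on the requested strand, and returns a BED6 manifest (0-based,
half-open) of the ground truth. Plantings come in three kinds: exact
protospacer+PAM copies, copies sharing only the 12-mer seed+PAM (their
5′ 8-mer is randomized with at least one forced mismatch, so they can
never be accidental full copies), and near-match copies with defined point
mutations.

Uniform background sequence will, with small but real probability, contain
accidental seed+PAM occurrences (for an 8-mer+NGG, about 0.02 expected per
10 kb both-strand scan), which would make exact-recovery assertions flaky.
The generator therefore **scrubs**: after planting it rescans both strands
for any planted k-mer+PAM word occurring outside a planted span and
mutates one background base in each such site, iterating to a fixed point.
Bases inside planted spans are never touched. As a consequence the
manifest-derived expectation (`manifest_expected_counts()`, which scans
the planted site sequences in both orientations) matches the genome-wide
count *exactly*, and the test suite asserts exact recovery across 100
seeded fixtures.

What the generator does **not** emulate: real genomes are not uniform —
they have repeat families, segmental duplications, GC-skewed isochores and
N-masked assembly gaps, all of which make real off-target landscapes
heavier-tailed than the fixtures'. Passing the fixture-based suite
demonstrates that the counting and search machinery is correct, not that
any particular guide in a real genome is safe; for real designs the user
supplies the actual target genome FASTA.

## Validation strategy and problem sizes

The package is validated against independent oracles rather than against
itself:

* **Counting**: a literal scan that expands the degenerate PAM into
  concrete words and counts them (with overlap) on both strands — on small
  genomes via fixed-string regex counting, at scale via a dictionary
  matcher. The acceptance suite runs twenty random genomes of 100–200 kb
  with a random 2-kb query each, alternating NGG/NRG (~22 000
  candidate × k checks), at well under two minutes on one CPU.
* **Approximate search**: an exhaustive enumeration oracle that tries every
  no-gap, one-deletion and one-insertion alignment with vectorized
  mismatch counting — valid for max_gaps ≤ 1, which covers the default
  budget — on composite genomes of 20–48 kb carrying planted substitution
  and indel variants.
* **Properties**: seed-count monotonicity (full ≤ seed12 ≤ seed8, >10⁴
  candidates), strand symmetry of whole designs under reverse complement
  of genome or query, exact planted-site recovery (100/100 fixtures), and
  byte-stable export round trips.

`scripts/acceptance.R --seed N --out results/acceptance.json` recomputes
all of these from scratch under one seed.

## Numerical and formatting choices

* GC and Tm are rounded to one decimal at computation time; exports print
  exactly one decimal, so parse(export(x)) is the identity.
* TSV: UTF-8, LF, tab separators, "." decimal point; no quoting is ever
  needed because no field can contain a tab. Missing annotations are empty
  strings in TSV, null in JSON.
* JSON key order is fixed and numbers are serialized at full precision,
  so identical reports are byte-identical and `export_json(import_json(x))
  == x`. The run timestamp is optional (`timestamp = FALSE`) to keep
  reruns diffable.
* All fixture randomness flows through an explicit integer seed and the
  generator restores the caller's RNG state.

## Known limitations

* No cutting-activity model: candidates are ranked by occurrence counts
  and edit structure only, not by cleavage-probability scores (MIT/CFD
  style). The exported counts are inputs any such scorer could consume.
* The k-mer index is in-memory and rebuilt per genome unless serialized;
  it targets desk-scale genomes (up to tens of Mb comfortably), not a
  hosted multi-organism service.
* Approximate search is validated against the enumeration oracle for
  budgets up to one gap; larger gap budgets run through the same DP but
  are not oracle-checked in the suite.
* The query is limited to 10 kbp and one record per design run; batch
  designs loop over records (the CLI makes this scriptable).
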