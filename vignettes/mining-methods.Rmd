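---
title: "Mining self-resistant biosynthetic gene clusters from gene coordinate tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining self-resistant biosynthetic gene clusters from gene coordinate tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgmine)
```

## The problem and the signature

Fungal secondary-metabolite biosynthetic gene clusters (BGCs) sometimes
protect their producer by carrying a resistant duplicate of the very gene
their product inhibits. Such a genome shows a characteristic signature:
an allele of an essential housekeeping gene with no biosynthetic role
sits inside a BGC, and a second allele lives elsewhere in the genome.
Finding this signature lets one nominate, purely *in silico*, BGCs whose
products hit a therapeutic target of choice.

rgmine detects the signature from nothing but gene coordinate tables, the
kind any annotated-genome portal exports as CSV: one table of candidate
resistance-gene homologs (the set **R**, typically from a TBLASTN search
with the housekeeping gene) and one table of core biosynthetic backbone
genes (the set **S** — NRPS, PKS, terpene synthase/cyclase or DMATS
genes, typically from an orthology-term search). No genome downloads, no
cluster-boundary prediction, no sequence analysis: deliberately so,
because boundary predictors often exclude exactly the resistance allele
(it has no biosynthetic annotation) and would turn true clusters into
false negatives.

## The decision rule

A pair (r, s) ∈ R × S is a **hit** when all five predicates hold:

1. r and s are annotated in the same genome;
2. r and s lie on the same scaffold;
3. their interval centers are at most *C* base pairs apart;
4. their intervals do not overlap (sharing even one base disqualifies,
   which also makes self-pairing impossible when a gene appears in both
   tables);
5. the resistance gene is at most *M* base pairs long;

and, unless the check is waived, the genome carries at least two
resistance-gene copies — self-resistance needs both a housekeeping and a
resistant allele. Every qualifying pair is reported, so a resistance
gene flanked by two in-range backbone genes yields two hits, as a
complete cluster with two backbone genes genuinely does.

### Parameters

* **cutoff `C`** (bp, required). Known fungal BGCs span roughly 10–70 kb,
  so 70 000 bp is the documented working value: generous enough not to
  lose genuine clusters, tight enough that chance proximities stay rare.
  The argument has no default — an appropriate cutoff is a scientific
  choice that depends on the gene class being mined, and silently
  defaulting it invites misreading.
* **maxGeneLength `M`** (bp, default unlimited). A guard against
  misannotated giant gene models masquerading as resistance homologs;
  left unlimited by default because no single value suits every target
  family.
* **singletonCheck** (default `TRUE`). `FALSE` is the "nocheck" waiver:
  it disables the two-copy rule, which abandons the self-resistance logic
  but lets the same join answer other proximity questions (e.g. all
  transcription factors near a backbone gene).

### Numerical choices

Coordinates are treated as 1-based, fully closed intervals (the
genome-browser convention), so a gene's length is `stop − start + 1`.
Centers of even-length genes fall on half-integers; to keep the core
predicate exact on every platform, all comparisons run on **doubled**
coordinates — `start + stop` against `2C` — so no floating point ever
enters the decision. Reported `center_distance` values are exact:
integers render without a decimal point, half-integers with a `.5`
suffix. Organism and scaffold identifiers are compared by exact string
equality after whitespace trimming (portal identifiers are
machine-generated; case-folding could merge distinct genomes). Strand is
ignored throughout — the decision rule never uses it. Output order is
fully specified (organism, resistance start, resistance id, SM start, SM
id, byte-wise collation), so identical inputs give byte-identical
outputs.

Hit tables additionally report `end_gap`, the count of bases strictly
between the two genes as annotated. The hit criterion itself is
center-to-center, but gene separations are conventionally quoted
end-to-end; carrying both removes any ambiguity downstream.

## Two engines, one contract

`bruteForceMine()` is the algorithm verbatim: for each r, for each s,
evaluate the five predicates. It is kept exported forever as the testing
oracle. `mineHits()` is the engine meant for real use: it groups genes
by (organism, scaffold), sorts SM genes by doubled center, and
binary-searches the window `[2c_r − 2C, 2c_r + 2C]`. At database scale
(≈2 300 × 28 000 genes) this turns minutes of pair scanning into well
under a second, and the test suite asserts element-wise identical output
from both engines across dozens of seeded fixtures. Singleton
elimination always counts copies on the full deduplicated table *before*
the length filter, because the length check belongs to the pair loop
while copy counting belongs to table construction; the alternative
ordering (count only copies passing M) is defensible but was not
adopted, and the choice is fixed here so results are reproducible.

Homolog mode collects, for every genome with a hit, *all* of that
genome's records from R — including the hit genes — deduplicated to a
set and sorted. Downstream curation needs the full complement of copies
to tell the housekeeping allele from the resistant one.

## The synthetic fixture generator

Real inputs come from database snapshots that drift over time, so the
package tests itself on synthetic genome annotations whose ground truth
is known *by construction*, never by running the miner on itself. A
`FixtureSpec` describes genomes, scaffolds, and:

* **planted pairs** at exact center distances (the SM gene's length is
  nudged by one base when parity demands an integral start coordinate),
  each with ≥1 extra resistance copy so the two-copy rule is satisfiable;
* **decoys**, each violating exactly one predicate: `singleton_near`
  (in-range pair, but the only copy in its genome), `far_pair` (two
  copies, distance > C), `overlapping_pair` (shares bases with its SM
  gene), `oversized_resistance` (in-range but longer than M);
* **background genes** placed by rejection sampling so they can never
  qualify: background SM genes sit > C from every resistance-gene
  center, background resistance homologs > C from every SM center. The
  background-resistance population is this generator's own extension of
  the planted/decoy scheme: a database-wide homolog table is dominated
  by copies nowhere near any BGC, and emulating that bulk is what makes
  the scale preset honest. Background resistance genes also avoid
  `singleton_near` genomes, where a stray second copy would silently
  turn the decoy into a genuine hit.

Placement is bounded rejection sampling with explicit failure; after
placement a construction-time audit enumerates qualifying pairs by
direct predicate arithmetic (grouped per scaffold — bookkeeping, not the
mining engine) and aborts generation if any incidental pair slipped in,
under both the default and the waived singleton rule. Truth is therefore
exact, and precision/recall assertions against it are meaningful at 1.0.

Defaults: scaffolds of 1 Mb (3 Mb in the scale preset), gene lengths
uniform on 500–15 000 bp — bracketing typical fungal genes up to the
large multi-domain backbone genes — truth stated at C = 70 000 bp and
M = 20 000 bp (a finite M is needed for the oversized decoy class to be
testable; 20 kb comfortably exceeds real resistance-gene homologs while
staying below the oversized decoys at 1.5 M). The generator works in
coordinates only: no sequences, no phylogeny, no transfer events. What
passing tests show is that the *decision rule and its implementation*
are exact; they cannot show that a particular biological target family
or E-value threshold yields a complete homolog table — that remains the
user's search-design problem.

`mycocosmScaleSpec()` emulates the shape of a whole-portal run — 1 800
genomes, ≈28 000 SM backbone genes, ≈2 300 resistance homologs — for
performance testing. The suite's problem sizes (fixtures of a few
hundred genes for properties, up to ~10⁴ for oracle equivalence, ~3×10⁴
for the scale run) were chosen to exercise every code path at sizes a
laptop handles in seconds.

## Reports

`distanceHistogram()` bins hit center distances into half-open,
lower-inclusive bins `[0, w), [w, 2w), …` — a distance exactly on a
boundary falls upward, a convention chosen because it is the one that
can be tested unambiguously. `cutoffSweep()` evaluates a strictly
increasing cutoff ladder; since every predicate except the distance is
cutoff-independent, one run at the largest cutoff filtered downward
equals per-cutoff runs (the suite asserts this equality), and hit sets
are nested — extending a cutoff can only add candidates. Together these
views answer the practical question of where to set C: genuine pairs
pile up at short distances while false positives accrue roughly
linearly with distance. `genomeSummary()` produces the "N hits in M
genomes" aggregation runs are quoted by.

Run configuration is echoed to a timestamped log line on standard error
rather than into the CSVs, so outputs stay byte-reproducible; the CSVs
themselves are written with fixed headers, minimal quoting and `\n` line
endings on every platform.

## Known limitations

* The tool ranks nothing: every pair satisfying the predicates is
  reported, and hit curation (is the neighborhood actually a BGC?) is
  manual by design.
* It cannot discover *new* target genes — the user chooses the target
  and supplies its homolog table; the quality of the input search
  bounds the quality of the output.
* A cluster split across a scaffold edge loses its hit (predicate 2),
  and a resistance gene whose second copy was missed by the input
  search is eliminated as a singleton; both failure modes come from the
  inputs, not the join.
* The two-copy rule counts copies within the supplied table only; deeply
  diverged second alleles missed by the homolog search will cause false
  negatives.
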