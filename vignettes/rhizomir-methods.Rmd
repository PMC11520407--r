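---
title: "rhizomir: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rhizomir: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizomir)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the design choices that were
genuinely open, and what the synthetic validation does and does not show.

## The duplex expectation score

Plant miRNAs guide cleavage or repression of their targets through
near-perfect sequence complementarity, so target prediction in this tradition
(psRNAtarget and its relatives) is a complementarity scan rather than a
thermodynamic folding calculation. `score_duplex()` evaluates an ungapped,
antiparallel duplex between a miRNA of length $L$ and a target-sense site of
the same length: miRNA position $i$ (1-based from the 5' end) faces site
position $L-i+1$. Each position contributes a penalty $p_i$ — 0 for a
Watson–Crick pair (A:U, U:A, G:C, C:G), 0.5 for a G:U wobble, 1 for anything
else — weighted by $w_i$, which is 2 inside the seed region (positions 2–13)
and 1 elsewhere:

$$E = \sum_{i=1}^{L} w_i\,p_i.$$

$E = 0$ means a perfect duplex; with the defaults an all-mismatch duplex of a
21-mer scores $2 \times 12 + 9 = 33$. The published description of the tool
family this score belongs to does not pin down the exact penalty table, so
all five numbers are runtime parameters of `scoring_params()`:

| parameter | default | meaning |
|---|---|---|
| `mismatch` | 1 | penalty per mismatched position |
| `wobble` | 0.5 | penalty per G:U pair (tolerated in RNA helices at reduced stability) |
| `seed_start`, `seed_end` | 2, 13 | seed region, where pairing defects are most consequential for plant miRNAs |
| `seed_multiplier` | 2 | weight applied inside the seed |
| `max_expectation` | 3 | reporting cutoff for the genome scan |

The defaults follow the established psRNAtarget convention (mismatch 1,
wobble 0.5, doubled seed penalties, cutoff 3). Classification of a position
as pair/wobble/mismatch is structural — changing the `wobble` penalty changes
the score, not which positions are annotated `o` in the pairing string.

Two deliberate restrictions: duplexes are **ungapped** (no bulge scoring), so
every window admits an exact brute-force recomputation and the scanner can be
verified against exhaustive enumeration; and ambiguity codes (`N` and the
rest of the IUPAC set) **never pair**, a conservative treatment of assembly
gaps. Gapped alignment and ΔG-based scoring are out of scope.

## The genome scan

`scan_genome()` scores *every* window of miRNA length on *both* strands of
every contig — no k-mer seeding heuristics — and reports windows with
$E \le$ `max_expectation`. A hit's strand is the strand whose 5'→3' sequence
is the target-sense (mRNA-like) site; this makes sense-matching against CDS
orientation well defined downstream. Internally the scan is a vectorized
position-weighted lookup over the encoded genome, but the emitted set is
identical to per-window scoring by construction, and the test suite verifies
that equality against an independent scalar oracle on hundreds of random
genome/miRNA instances.

Overlapping hits of the same miRNA on the same strand within one window
length are collapsed to the single best (lowest-$E$; ties to the smaller
start) hit. The collapse radius of one miRNA length is a package choice —
counting "targeted sequences" implies deduplicated sites, but no radius is
canonical — and `collapse = FALSE` disables it.

Degenerate inputs: contigs shorter than the miRNA are skipped with a warning;
an empty miRNA set is a contract error; identical inputs always produce
byte-identical output files.

## CDS context

Bacterial genomes lack the annotated 3' UTR transcripts that plant target
scanners consume, so predicted sites are contextualized by distance to the
nearest annotated CDS instead. Distance is boundary-to-boundary on the contig
(0 when the hit overlaps the CDS), with no operon inference — the simplest
defensible reading of "near a gene" in a compact genome. Orientation is
relative to the CDS strand: upstream means 5' of the gene start, where a
site could sit in the 5' UTR of the transcript.

`filter_by_cds_distance()` removes sites farther than `max_distance` from any
CDS. The default of 200 nt reflects typical bacterial 5' UTR lengths
(usually well under 200 nt); it is a tunable, recorded in output provenance,
because no universal threshold exists. `require_sense` (off by default)
additionally demands that the site lie on the coding strand — off because a
genome-level screen should surface antisense proximity too. Ties in nearest
distance go to the leftmost CDS, a deterministic and otherwise arbitrary
rule.

## Compartment-specific miRNA calling

Small RNA-seq of soil compartments is noisy and shallow; the calling rule is
deliberately a hard presence/absence filter rather than a differential
abundance model. A miRNA is compartment-specific under rule
$(t, b)$ iff its count is $\ge t$ in **every** target-compartment sample and
the **sum** of its counts across bulk-soil samples is $\le b$. The presets
are $(10, 1)$ for rhizosphere and root libraries and $(5, 0)$ for the
bacterial fraction, whose libraries recover far fewer plant-miRNA reads. The
bulk allowance of one read total encodes the view that an isolated singleton
in bulk soil is a sequencing artifact, not evidence of presence.

Quantification upstream of the rule is exact full-length matching of reads to
mature sequences (U ≡ T), after the 18–27 nt length filter. Exact matching
replaces genome mapping plus miRNA assignment: it is deterministic,
oracle-checkable, and adequate for mature-miRNA quantification of trimmed
reads, at the cost of dropping isomiRs (length/end variants). A
Hamming-distance-1 mode exists behind `max_mismatch = 1` but is off by
default; isomiR-aware counting is a declared limitation, not a hidden
behaviour. Catalog entries with identical mature sequences are merged under
the lexicographically first name with synonyms recorded, since reads cannot
distinguish them.

## Origin screening and scrambled controls

A miRNA detected in the bacterial fraction could in principle be a bacterial
small RNA. `screen_origin()` therefore searches for the literal sequence
(and its reverse complement) in genome collections with **zero** mismatches:
the question is whether the bacteria could encode the molecule at all, so
the screen is binary presence/absence of the exact k-mer, counting
overlapping occurrences. Inexact (BLAST-like) screening is a non-goal.

`scramble()` produces the standard negative control: identical nucleotide
composition, random order, re-drawn until it differs from the input (a
homopolymer, which admits no distinct permutation, is a contract error).
Scrambled controls are not checked for accidental complementarity to any
genome — the control's logic is compositional, and such a check would change
what the control means.

## Overlap against a random-sets null

Whether predicted targets are enriched among differentially expressed genes
is formalized as drawing a set of size $n$ uniformly from a universe of $N$
genes and intersecting it with a fixed set of size $m$: the overlap is
hypergeometric, $P(X \ge k)$ is the enrichment p-value, and $mn/N$ the
expected overlap. The universe defaults to the annotated genes of the
supplied GFF — the only defensible default when no background list is given —
and is overridable. `permutation_overlap()` estimates the same tail by
seeded Monte-Carlo with the $(1+\#\{k_{rep} \ge k\})/(reps+1)$ estimator,
and the suite checks the two routes against each other and against exact
integer enumeration for small universes.

## The synthetic generators

The generators produce data with exactly the structure the pipeline assumes,
plus ground truth:

* `make_genome()` draws i.i.d. bases at a requested GC content. Real
  bacterial genomes have codon structure, repeats and skew; an i.i.d.
  background is intentionally neutral — it makes chance complementarity
  quantifiable and planted signals unambiguous.
* `plant_sites()` writes target-sense sites into the genome with chosen
  mutations; each mutated position receives a base that neither pairs nor
  wobbles, so the constructed expectation is exactly the weighted sum over
  mutated positions and always agrees with `score_duplex()` on the planted
  window (a tested invariant).
* `make_count_table()` models compartment-specific miRNAs as negative
  binomial counts in target samples (mean 30, dispersion 0.5 by default —
  overdispersion typical of sequencing counts) with Bernoulli singletons
  (rate 0.3) in bulk, and background miRNAs as low Poisson counts
  everywhere. Two regimes matter: the *separation* regime (no bulk noise,
  mean far above threshold, tight dispersion) in which the caller must
  recover the truth set exactly, and the *noisy* default regime in which
  specificity above 0.99 is required over 50 seeded replicates.

What the generators do **not** emulate: adapter/quality artifacts in reads,
isomiR distributions, compositional bias of real soil small-RNA libraries,
genome repeats, and operon structure. Passing tests therefore demonstrate
algorithmic correctness on data with the assumed structure, not robustness
to every real-data pathology.

## Validation scale and numerical conventions

The test suite validates the scanner against exhaustive brute-force
enumeration on 50 seeded random genomes (400 nt, within the ≤ 2 kb class
where enumeration is comfortable) × 3 random 21-nt miRNAs × 3 cutoffs, and
planted-site recovery on 200 sites with 0–3 mutations across 10 × 3 kb
genomes; the acceptance script scans a 150 kb genome with 48 planted sites
for six miRNAs and screens 20 × 50 kb genomes. These sizes were chosen to
exercise every code path at desk scale; the scanner itself is linear in
genome length × miRNA count and handles multi-megabase bacterial genomes.

Coordinates are 0-based half-open everywhere inside the package; conversion
happens only at the GFF3 (1-based inclusive) and BED boundaries, so
`length = end − start` holds on every feature. miRNAs are stored as RNA,
genomes as DNA, and every comparison treats U and T as equivalent.
Expectations are sums of exactly representable doubles (multiples of 0.25
under the defaults), so cutoff comparisons are exact; the TSV writer fixes
four decimals, which round-trips those values losslessly. All stochastic
functions take explicit seeds and restore the caller's RNG state.

## Command-line front end

The CLI (`inst/cli/rhizomir.R`) is a thin dispatcher over the exported
functions, one subcommand per analysis, with `#`-prefixed provenance headers
(version, command, input checksums), exit codes 0/1/2 for
success/contract-error/usage-error, and an optional YAML config file
mirroring the flags (flags override the file). YAML was chosen as the config
format because it is the configuration dialect already ubiquitous in R
pipelines.

## Known limitations

* Exact-match quantification undercounts miRNAs observed mainly as isomiRs.
* The expectation score ignores site accessibility, secondary structure and
  free energy; it ranks complementarity only.
* CDS distance is measured on the chromosome, not along transcripts; in
  operons a site "downstream" of one gene may be inside another's transcript.
* The overlap test conditions on set sizes and assumes exchangeable genes;
  it ignores gene length or expression-level detection bias.
* The i.i.d. genome background understates chance complementarity in
  low-complexity or repeat-rich regions of real genomes.
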