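---
title: "Distinguishing contamination from horizontal transposon transfer with reads"
author: "httguard package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing contamination from horizontal transposon transfer with reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A retrotransposon family found in both a parasite genome assembly and its
host's genome admits two explanations: horizontal transposon transfer
(HTT) between the lineages, or contamination of one sequencing library
with DNA of the other organism. Assemblies cannot arbitrate, because
contaminating reads are readily co-assembled into the "wrong" genome —
repeat-dense regions especially. Individual reads can: a read pair or a
long read derives from one contiguous DNA molecule, so when part of a read
codes for the element, the *rest* of that molecule tells you which
organism it came from. If the non-repetitive remainder matches the focal
species' own taxon, the element is endogenous (consistent with HTT); if it
matches the putative donor taxon, the element arrived as contamination.

## The classification model

Reads are selected in one of three modes, depending on the data at hand:

* **long**: long reads are kept when a six-frame translated search against
  the element's ORF protein yields a hit with E-value below `1e-10`.
* **ref**: read pairs are aligned to the reference assembly; the element is
  annotated on the assembly (alignments with divergence under 20% and
  length of at least 200 bp), and pairs are kept when *exactly one* mate
  overlaps an annotated interval. Pairs with both mates inside element
  regions are discarded — they carry no independent information. The
  element-overlapping mate must additionally have its best repeat-library
  hit on the element itself (reciprocal check), guarding against
  cross-family misassignment.
* **noref**: without a reference, pairs are kept when one quality-masked
  mate's best repeat-library hit is the element (E < 1e-10) while the
  other mate shows no element hit at all.

The informative mate (or the whole long read) is then hard-masked against
the full repeat library — so only non-repetitive sequence decides — and
searched against two databases: **self** (genomes of the focal taxon,
excluding the focal species itself) and **non-self** (genomes of the
donor/contaminant taxon). Both searches use the same effective database
size (the larger of the two), so E-values and bitscores are directly
comparable. Hits against the focal species' own genome are discarded:
assemblies are built from the very reads under test and would match
trivially. The surviving hits are pooled and ranked by bitscore
(ties broken by E-value, then subject id, so runs are reproducible); the
verdict is the database label of the top hit. Equal top bitscores across
the two databases give `ambiguous`; no surviving hits give `unassigned`;
reads with fewer than 30 unmasked bases are `low-quality` and never
classified (below the seed size of the search engine, a hit would be
meaningless).

Dataset-level fractions are computed over assigned (self + non-self) reads
only. The call is `contamination` when the non-self fraction reaches the
call threshold (default 0.80), `endogenous/HTT-consistent` when the self
fraction does, and `inconclusive` otherwise. Any majority rule reproduces
the calls on clearly separated datasets; 0.80 leaves a deliberate
inconclusive band for mixed signals.

```{r example}
library(httguard)
scn <- build_scenario(scenario_config(seed = 1, scenario = "HTT"))
res <- run_contest("noref", pairs = scn$pairs,
                   rte_consensus = scn$rte_consensus,
                   self_db = scn$self_db, nonself_db = scn$nonself_db,
                   own_species = scn$own_species,
                   repeat_library = scn$repeat_library)
res$summary
```

## The search engine

External search engines operate at genome-database scale; at the scale of
this package's analyses a built-in engine keeps the toolchain
self-contained, and the BLAST 12-column tabular interface
(`read_tabular_hits()` / `write_tabular_hits()`) lets users substitute
blastn or DIAMOND output wherever hits are consumed.

The engine is seed-and-extend: exact k-mer seeds (k = 11 for nucleotide,
k = 5 for amino acid queries) located through a keyed index, clustered by
diagonal (tolerating 200 bp of indel drift) and subject position, screened
by a cheap ungapped X-drop extension (three representative seeds per
cluster; clusters whose ungapped E-value exceeds 1 — far above any
reportable hit — are dropped, which is what keeps chance seeds on long
queries from costing gapped extensions), then extended by affine-gap
Smith–Waterman over the seeded window (implemented in C++; large
extensions switch to a banded kernel along the seeded diagonals with
linear memory in the query length, and a hard window cap bounds any
single DP matrix). Statistics follow
the Karlin–Altschul forms: `bits = (lambda * S - ln K) / ln 2` and
`E = m_eff * n_eff * 2^(-bits)`. Defaults are the blastn-like +2/−3 match
scheme with gap open 5 / extend 2 and the widely published constants
lambda = 0.625, K = 0.41 for those scores; protein search uses BLOSUM62
with gap 11/1 and lambda = 0.267, K = 0.041. All are overridable through
`dna_scheme()` / `protein_scheme()`.

Two consequences of seeding are worth knowing. A local alignment is
guaranteed to be found only if it contains at least one exact k-mer match;
at the divergences this package targets (≤ ~30%) seeds are abundant, and
the recall property is verified against exhaustive Smith–Waterman in the
test suite. And because each seed cluster is extended separately, a copy
interrupted by a long insertion is reported as two hits — which is exactly
what the defragmentation step expects.

## Repeat annotation, masking and defragmentation

`annotate_repeats()` reports merged, filtered matches of a repeat library
on a sequence. Divergence is `100 − identity` computed over aligned
columns *including* gap columns. Threshold boundaries follow the
conventions used throughout: keep length `>=` threshold, keep divergence
strictly `<` threshold. Masking (`mask_repeats()`) replaces annotated
bases with `N` (hard) or lowercases them (soft); length is conserved and
the informative length is the unmasked base count.

`defragment()` reassembles copies from fragments: same family, same
strand, genomic gap at most `max_gap` (default 5000 bp) and collinear
consensus coordinates (the next fragment must continue where the previous
one left off, with 20 bp of tolerated overlap). In strict mode an
intervening annotation of a different family blocks the merge. Tandem
full-length copies never merge because their consensus coordinates
restart. The defaults are configurable; they were chosen once as values a
repeat annotator would consider ordinary and are exercised against
planted split-copy fixtures.

## Consensus reconstruction

Per-species consensus sequences are built by reference-anchored star
alignment with a majority rule: every fragment is aligned (ends-free
global alignment, both orientations) to a family seed sequence; per seed
column, the plurality base among covering fragments wins where coverage
reaches `min_coverage` (default 3), and the seed base is retained
elsewhere. Insertions relative to the seed are discarded, so the
consensus lives in the seed's coordinate system. This is a deliberate
design choice over progressive multiple alignment followed by
profile-HMM consensus emission: it needs no external alignment or HMM
tooling, is deterministic, and the property that actually matters —
recovery of the ancestral sequence — is verified directly (30 copies at
10% divergence recover the ancestor at ≥ 99% identity in the acceptance
suite). What the star alignment gives up is insertion states: lineage-
specific insertions absent from the seed cannot enter the consensus.

Consensus-to-consensus identity (`pairwise_identity()`) uses ends-free
global alignment and counts matches over aligned columns, excluding the
cost-free terminal overhangs.

## Kimura distances and repeat landscapes

Copy age is proxied by the Kimura 2-parameter distance of each copy to its
consensus, `K = -1/2 ln((1-2p-q) sqrt(1-2q))`, with transition proportion
`p` and transversion proportion `q` counted only over columns where both
sequences carry an unambiguous base. CpG dinucleotide positions of the
consensus are excluded (both positions), because methylated CpGs
hypermutate and inflate apparent age; adjacency is determined on the
ungapped consensus and mapped through the alignment. An alternative
RepeatMasker-style treatment — downweighting CpG transitions instead of
excluding the sites — is not implemented; exclusion is the reading this
package commits to, and with `exclude_cpg = FALSE` the raw counts are
available. For symmetric distance matrices between consensuses,
CpG positions of either sequence are excluded (`cpg_on = "both"`).

The repeat landscape (`repeat_landscape()`) bins copies by distance (in
percent, 1%-wide bins by default), each copy contributing its length, and
reports the minimum, length-weighted mean and maximum distance — the
summary triple printed on landscape plots. Replication bursts appear as
peaks; gradual accumulation as a broad slope.

Saturated copies (where a logarithm argument becomes non-positive) carry
`NA` distances, are flagged, and are excluded from landscapes.

## Trees

The HTT topology question — does the recipient's element nest inside the
donor clade? — is answered with neighbor joining on CpG-excluded K2P
consensus distances, midpoint-rooted when a root is needed. This is a
deliberate stand-in for Bayesian/ML phylogenetics, which is out of scope
here; NJ on nearly additive distance matrices recovers the topology, and
the acceptance suite verifies that a recipient seeded from a donor
lineage attaches sister to that lineage in ≥ 90% of simulated replicates.
Negative NJ branch lengths are clamped to zero and counted. The
`star_score()` of a copy tree (internal branch length over total branch
length, 0 for a perfect star) summarizes whether copies proliferated in
one burst and then diverged neutrally, the pattern expected after a
horizontal transfer.

## The simulator and what passing tests mean

`build_scenario()` generates the full test bed: an ORF-bearing ~3 kb
element, donor and recipient genomes, sister-genome databases, read sets
and per-read truth labels, under three scenarios — `HTT` (element in both
genomes, recipient family seeded from the donor lineage, reads only from
the recipient), `contamination` (element only in the donor, donor reads
mixed in at 5%, and the donor sequence riding along in the "assembly" as a
co-assembled contaminant contig) and `negative` (no shared element; a
decoy repeat family is planted everywhere to keep masking and reciprocal
checks honest).

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `te_length` | 3000 bp | typical non-LTR retroelement scale |
| `n_copies_donor` / `n_copies_recipient` | 30 | enough for consensus building and landscapes |
| `copy_divergence` | 0.10 | an active-but-aging family |
| `kappa` | 2.0 | canonical transition/transversion ratio |
| `genome_length` | 100 kb | background per genome; copies add to it |
| `background_divergence` | 0.20 | deep host–parasite split |
| `within_taxon_divergence` | 0.05 | sister species close enough to classify against, far enough to be non-trivial |
| reads | 2×150 bp, insert 500±50, 20× | short-read archive norm |
| long reads | exp(8 kb), 5× | long-read archive norm |
| `error_rate` | 0.005 | post-filter Illumina scale |
| `contamination_fraction` | 0.05 | realistic low-level contamination |

Copy evolution uses closed-form K80 transition probabilities, so multiple
hits are modelled and K2P estimates of evolved copies are calibrated
against the simulated branch length (the Kimura recovery check would fail
under naive proportion-`d` mutation at `d = 0.3`). Sequencing errors get
Phred 11 qualities against a Phred 40 baseline, so quality masking is
exercisable end to end. All randomness flows from R's RNG under the
config seed; outputs are byte-identical across runs.

What the simulator does **not** emulate: platform-specific error profiles
(homopolymer indels), diploidy, nested or fragmented ancient repeats,
taxonomically structured databases with hundreds of genomes, and genuinely
unknown donor taxa. Passing the scenario-discrimination checks shows the
method's logic is sound under clean separations; on real data the
informative-read yield and the sharpness of the self/non-self margin
depend on database composition and repeat-library completeness, and old,
fragmented element copies that escape masking can leak reads toward the
wrong database — the same caveat that applies to the original protocol.

## Numerical and policy choices

* Internal coordinates are 0-based half-open everywhere; BLAST/SAM
  1-based dialects are shifted only at I/O boundaries.
* Quality masking replaces bases with `N` rather than dropping reads;
  reads left with more than 50% `N` are flagged low-quality and excluded
  from classification (a conservative policy choice).
* Minus-strand hits are stored with normalized `start < end` plus a
  strand flag, so interval arithmetic never branches.
* The shared effective database size for the two classification searches
  is `max(total self, total non-self)` — our reading of "adjusted to the
  largest" sizing, making E-values comparable across databases.
* Consensus-column ties break alphabetically; hit ranking ties break by
  E-value then subject id; both make reruns identical.
* Selection thresholds: E < 1e-10 throughout; translated read screening
  additionally requires amino-acid identity > 75%; genome screening keeps
  alignments of ≥ 100 bp and species with ≥ 10 reciprocal loci.
* The reference-free mode masks informative mates against the full repeat
  library before classification, like the other two modes — a consistency
  choice.
* Tied self/non-self top bitscores are reported `ambiguous` and excluded
  from the fractions rather than resolved arbitrarily.

## Problem sizes in the test suite

The acceptance checks run the full scenario matrix at the default study
conditions (100 kb backgrounds, 30+30 copies, 20× paired coverage — about
13 000 pairs per scenario), consensus recovery on 30 copies of a 3 kb
element, Kimura recovery on 50 copies × 1 kb at three distances, and 50
seeded topology replicates with 5 species × 8 copies of a 1.5 kb element
(the acceptance script uses 25 replicates). These sizes were chosen so a
single desktop core covers the whole suite comfortably while every check
retains clear statistical margin.
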