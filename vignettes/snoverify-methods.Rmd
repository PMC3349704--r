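---
title: "Methods: detecting and verifying box C/D snoRNA genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and verifying box C/D snoRNA genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snoverify)
```

## The biological problem

Box C/D small nucleolar RNAs (snoRNAs, SNORD genes) guide site-specific
2'-O-methylation of ribosomal and small nuclear RNAs. A functional C/D
snoRNA has a stereotyped architecture: a C box (consensus RUGAUGA) near the
5' end and a D box (CUGA) near the 3' end, brought together by a short
terminal stem formed by inverted repeats at the termini; internal, often
imperfect C' and D' copies; and, immediately upstream of the D and/or D'
box, an antisense element of roughly 9–20 nt that base-pairs with the
target RNA. The target nucleotide that receives the methyl group is the one
paired to the guide position located four nucleotides from the D/D' box in
the guide:target duplex — the "four-nucleotide rule" that anchors all
target predictions in this package.

In vertebrates nearly all snoRNA genes sit inside introns of host genes and
are processed from the host pre-mRNA; only a handful (SNORD3, SNORD13,
SNORD118, SCARNA2, SCARNA17) carry their own promoters. This makes genomic
context diagnostic: a snoRNA-like sequence stranded in intergenic space, or
carrying substitutions in its conserved boxes, is most likely a
retrotransposed pseudogene rather than a gene. Automated ncRNA annotations
do not make this distinction, which inflates apparent snoRNA gene counts;
`snoverify` implements the sequence- and context-level checks needed to
make it, plus the machinery to audit claimed guide/target assignments.

## Box detection and layout assembly

Boxes are found by degenerate-consensus scanning: a hit is any window whose
Hamming distance to the IUPAC pattern (N matching any base) is within a
per-box tolerance. Tolerances quantify "intact": the D box is the shortest
and most constrained element, so its default tolerance is 0 mismatches; C
tolerates 1 (absorbing the RUGAUGA variation); the internal copies C'/D'
are known to be imperfect and default to 2 and 1. All are configuration
keys (`boxes.*_max_mismatch`).

`scan_cd_layouts()` pairs every C-box hit starting within `layout.c_window`
(12 nt) of the 5' end with every D-box hit ending within `layout.d_window`
(12 nt) of the 3' end, on candidate-scale sequences of 50–120 nt
(`layout.min_len`/`max_len`, typical vertebrate C/D sizes). For each pair
the best internal D' (and then C', downstream of it) is attached, and the
terminal stem is sought: the longest ungapped pairing — Watson–Crick plus
at most `stem.max_gu` (1) G-U wobbles — between `stem.search_window` (8) nt
ending at the C box and the same window after the D box, reported from
`stem.min_pairs` (4) pairs up. Length ties resolve toward the outermost,
most terminal pairing, matching the intuition that the stem closes the
ends. None of these geometric values is prescribed by the underlying
biology with precision; they are defaults meant to be permissive and are
all exposed in the configuration.

H/ACA candidates are handled only at the box level (an interior-third
ANANNA hit plus an ACA box `haca.aca_offset` = 3 nt from the 3' end);
hairpin verification and pseudouridylation-pocket prediction are out of
scope.

## Guide duplexes and the four-nucleotide rule

The antisense element is *not* the whole fragment between boxes — treating
it that way is one of the annotation errors this package is built to catch.
`extract_guide_region()` takes the window of at most `element.max_len` (20)
nt immediately 5' of the D (or D') box, clipped at the preceding box.
`find_duplexes()` then enumerates every maximal ungapped antiparallel
pairing against the supplied target RNAs in which each position is
Watson–Crick or G-U, keeping those of 9–20 nt (`element.min_len`/`max_len`)
with at most `element.max_gu` (3) wobbles. G-U pairs count toward element
length, as they do in real guide elements.

The offset convention is stated once and used everywhere: with `b` the
0-based start of the D/D' box, the guide partner of the methylated
nucleotide is index `b - 5`, i.e. exactly four candidate nucleotides lie
strictly between the partner and the box. `predict_methylation_site()`
returns a site only when that index is inside the duplex; whether a G-U
pair may occupy the site position is a flag
(`element.allow_gu_at_site`, default on).

`validate_claimed_target()` turns the known failure modes of published
target tables into reason codes: `ELEMENT_IS_INTERBOX_SPAN` (the claim is
just the C–D' or C'–D fragment), `TARGET_DISALLOWED` (by default any 5S
rRNA identifier — eukaryotic 5S rRNA carries no 2'-O-methyl marks, so any
claimed 5S target is wrong on its face), `DUPLEX_TOO_SHORT`,
`SITE_UNPAIRED`, and `OFFSET_GT4` (the claimed site's guide partner is more
than four nucleotides from the nearest downstream D/D' box, which makes the
proposed modification mechanistically impossible).

## Homolog search

The search mirrors a curation workflow for intron-hosted genes:
`host_guided_search()` first searches the introns of the named host gene,
falls back to the whole genome only when that fails, and always finishes
with a second pass over the host introns so extra copies in other introns
are not missed.

The underlying `seeded_search()` is deliberately relaxed for distant
homologs: exact seeds of `search.word_size` = 3, match +1 / mismatch −1,
and cheap affine gaps in which the first gap character costs
`search.gap_open` = 1 and each further one `search.gap_extend` = 1 (a gap
of length *k* costs `gap_open + (k-1)·gap_extend`). Seed positions are
clustered; a window around each cluster — padded by the query length plus
`search.xdrop`, so `xdrop = Inf` widens the window to the whole sequence —
is aligned with a full affine-gap Smith–Waterman (compiled), and alignments
are harvested iteratively with masking until none reaches
`search.min_score` (16), so every non-overlapping local alignment above
threshold is reported, not just the best. With `word_size = 1` and
unbounded windows the procedure degenerates to an exact Smith–Waterman,
which is how it is validated. No E-value statistics are computed: hits
above the raw score threshold are meant for inspection, and at these
settings chance hits are *expected* (see the membership filter below).

`global_identity()` reports percent identity from an end-gap-free global
alignment (match +1, mismatch −1, gap −2, terminal gaps free), with
terminal-gap columns excluded from the denominator and internal gaps
counted as non-matches. Since several alignments can tie for the optimal
score with different identities, the pair is aligned in a canonical order,
making the measure symmetric.

## Classification: gene, pseudogene, or uncertain

`classify_candidate()` runs independent checks and emits one reason code
per failure; `gene` means the reason list is empty.

* **Boxes** — within the same tolerances used for scanning. When the strict
  scan finds no layout, boxes are relocated with
  `classify.diag_extra_mismatch` (+2) slack so the report can name the
  broken box (`BOX_MUT_C`, `BOX_MUT_D`, `BOX_MUT_DPRIME`); a truncated copy
  that has lost a box therefore typically carries both a `BOX_MUT_*` and a
  `TRUNC_*` code.
* **Stem** — `NO_STEM` when no qualifying terminal stem exists.
* **Antisense element** — for families with a known target, the family's
  site must be recoverable from the candidate's own guide region
  (`ASE_DISRUPTED` otherwise). Families with unknown targets skip this
  check.
* **Full length** — candidates shorter than `classify.full_length_frac`
  (0.9) of the family reference are truncated; the missing end is read off
  the end-gap-free alignment (`TRUNC_5`/`TRUNC_3`).
* **Location** — `EXONIC_OVERLAP`, `ANTISENSE_STRAND` (intronic but on the
  wrong strand: processing from the host pre-mRNA requires sense
  orientation), or the intergenic path. Families flagged
  `independent_promoter` in the catalog skip all location checks.

A candidate that passes every sequence check but lies in intergenic space
is the genuinely ambiguous case: it could be a functional gene with its own
promoter or a perfect recent retrocopy. Without transcript evidence it is
labeled `uncertain` with `[INTERGENIC, NO_TRANSCRIPT_EVIDENCE]`; full
containment in an mRNA/EST evidence feature upgrades it to `gene` with a
provenance note. This three-way outcome is what separates a careful census
from a raw annotation count.

`locate_candidate()` calls a candidate intronic only when it is fully
contained in a single intron *and* overlaps no exon of any gene (the
overlapping-gene edge case is resolved in favor of the exon); among
overlapping hosts the tightest containing intron wins, with lexicographic
gene-id tie-breaks, so the call does not depend on annotation order.

## The discovery pipeline and its membership filter

`classify_genome()` searches every contig with every catalog reference,
merges overlapping hits across families and strands into candidate loci
(best score wins), and classifies each locus. Because the search settings
are relaxed by design, raw hits include many chance local alignments; a
manual workflow would discard these on inspection. The pipeline instead
requires family membership before classifying. Membership is judged on a
*local* alignment of the candidate to each reference under
homology-detection scoring (match +1, mismatch −2, gap 2 + 2k): a
discovered candidate can carry flanking genomic sequence, which an
ends-free (dovetail) alignment cannot clip on both sides at once, and the
harsher mismatch/gap penalties stop chance extensions through unrelated
sequence from paying their way. The best such alignment must reach
`classify.min_identity_pct` (75%) over at least `classify.min_aln_len`
(30) columns. Both values come from alignment statistics, not from
fitting: below ~70–75% nucleotide identity ("twilight zone") an
assignment to a specific family is unreliable, and identity is only
meaningful over a substantial alignment — 30 nt is about the shortest
credible C/D fragment (C box, 9-nt element, D box, stem arms). Family
assignment itself ranks references by alignment score — ranking by raw
identity would let a one-nucleotide perfect overlap outrank a full-length
95% match. The truncation check reads its 5'/3' missing lengths off the
reference side of this same alignment, so padding a truncated copy with
background cannot disguise it as full length.

These thresholds suit a within-genome copy census, where family copies are
recent and high-identity. Cross-species searches at 55–90% homolog identity
should use `seeded_search()`/`host_guided_search()` directly and inspect
hits, which is the workflow the search defaults were chosen for.

## The synthetic-fixture generator

`build_toy_genome()` emulates the structures the classifier must
distinguish, on a scale where exhaustive verification is possible:
plus-strand host genes of 120-nt exons and 400-nt introns separated by
600-nt intergenic gaps on a uniform-ACGT background; per family, one intact
gene copy implanted in an intron plus one pseudogene copy per configured
mode — `box_mut`, `truncate5`/`truncate3` (removing 40% of the sequence),
and `shuffle_element` implanted intronically, and `intergenic_retro` (an
intact copy whose only lesion is its location) placed intergenically.
Implants sit at least 50 nt from any boundary so containment calls are
never ambiguous. `make_snorna_gene()` assembles stem–C–spacer–D'–C'–
element–D–stem with the element chosen so the four-nucleotide rule points
exactly at the profile's target position, rejection-sampling the random
spacers until the sequence scans to exactly one valid layout. All
randomness flows from a single seed; two runs are byte-identical.

The default study conditions — 3 families, a 300-nt target RNA, 12-nt
elements, 3 hosts with 4 introns each — keep a full
simulate → search → locate → classify round trip under ~15 s, and the
truth table is recovered exactly (100% sensitivity and specificity) at
these noise-free settings. What passing these tests shows is that the
rules are implemented correctly and the pipeline is self-consistent; what
it does not show is performance on real genomes, where copies diverge,
elements drift, backgrounds are not uniform random, and annotations are
incomplete. The generator makes no attempt to model evolutionary
divergence or indels.

## Nomenclature

Homologs of human snoRNAs are named by prefixing the human gene name with a
four-letter lowercase species code: first letter of the genus plus the
first three of the epithet (*Mus musculus* → `mmus`, so the mouse homolog
of SNORD87 is `mmusSNORD87`; *Microcebus murinus* → `mmur`). The published
convention shows only that colliding species must differ, so the collision
rule here is a package decision: extend with further epithet letters
(5-letter, 6-letter, ...) until unique, then with genus letters once the
epithet is exhausted. Epithets shorter than three letters pad from the
genus, with a warning.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; GFF3 (1-based
  inclusive) and reported target positions (1-based) are converted only at
  file and report boundaries. Multi-transcript genes collapse to the
  longest transcript (ties: lexicographically smallest transcript id).
* Sequences are stored as DNA; U is folded to T on input, and RNA
  lettering is available on output (`as_rna()`).
* An N in a sequence pairs with nothing and matches only a pattern N; it
  never scores as an alignment match.
* Duplex maximality is defined purely by pairability: a run longer than
  `element.max_len`, or with too many G-U pairs, is not reported (its
  sub-runs are not maximal).
* Empty inputs (no genes, no hits, empty catalogs) produce empty tables,
  not errors; malformed files produce input errors that the command-line
  interface maps to exit code 1 (internal errors map to 2).

## Worked example

```{r example, eval = FALSE}
set.seed(7)
fam <- sim_family_catalog(3)                       # catalog + toy target RNA
sim <- build_toy_genome(fam$catalog, fam$targets,  # seeded toy genome
                        sim_config(seed = 7))
res <- classify_genome(sim$genome, sim$genes, sim$catalog, sim$targets,
                       species_label = "toy")
summarize_census(res, "toy")
#>     family species n_genes n_pseudogenes n_uncertain
#> 1 SNORD901     toy       1             3           1
#> 2 SNORD902     toy       1             3           1
#> 3 SNORD903     toy       1             3           1
```

Each family contributes one intact intronic gene, three reason-coded
pseudogenes (mutated D box; 5'-truncation; shuffled antisense element) and
one intact intergenic retrocopy reported as `uncertain` — the same copy
that a context-blind annotation would have counted as a gene.

## Known limitations

* The membership and classification thresholds are tuned for recent,
  high-identity copies; deeply diverged pseudogenes fall below the
  membership filter and are reported as background rather than family
  pseudogenes.
* No covariance-model or profile detection, no thermodynamic folding: the
  terminal-stem finder is a deterministic complementarity search, and
  H/ACA support stops at box layouts.
* The seeded search has no E-value model; score thresholds are raw and
  scale-dependent, which is acceptable for curated, candidate-scale inputs
  but not for blind genome-wide screens of large genomes.
* Promoter prediction is out of scope; the independent-promoter exception
  list is taken from the family catalog, not inferred.
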