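---
title: "Methods: profile-HMM annotation of immunoglobulin variable domains"
author: "igprofile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-HMM annotation of immunoglobulin variable domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

High-throughput antibody repertoire sequencing needs every read's framework
(FR1--FR4) and complementarity-determining regions (CDR1--CDR3) located
precisely before any downstream analysis is meaningful.  Most numbering
tools are built around human and mouse reference data and bake in
assumptions -- fixed species lists, maximum CDR3 lengths -- that fail for
species with incomplete database coverage or unusual antibodies, the
canonical example being the ultralong CDR-H3 loops of cattle, which a
length-capped annotator silently truncates or rejects.

`igprofile` addresses this by letting the user build a profile hidden
Markov model from nothing more than two FASTA files of V-region and
J-region germline amino-acid sequences of whatever species is under study,
and by merging *multiple* partial HMM alignments of a query into one
consensus numbering, so a domain interrupted by a long CDR3 is stitched
back together rather than forced through a single global alignment.

## Model building

**V x J permutation alignment.**  The builder concatenates every ordered
(V, J) germline pair into one row -- `|V| x |J|` rows -- and assigns every
residue an IMGT position.  Assignment is anchor-based: the two conserved
cysteines of the V segment receive IMGT 23 and 104, the conserved
tryptophan IMGT 41, and the conserved Trp/Phe of the J segment IMGT 118.
Residues between anchors are spread over the fixed IMGT spans (FR2 and FR3
positions are filled completely; CDR1 and CDR2 loops shorter than their
spans are gapped in the middle, the left half taking the extra residue, as
IMGT prescribes).  A segment whose anchor spacing cannot fit these spans is
refused by name rather than mis-numbered.  Note that a V x J model has *no*
CDR3 match columns -- V ends at position 104 and J begins at 117/118 -- which
is deliberate: CDR3 diversity is handled at annotation time, not in the
model.

**Validation.**  Before training, the alignment is checked for structural
failures (non-rectangular rows, duplicate ids, a required region with no
occupied columns -- CDR3 excepted, for the reason above) and for anchor
conservation (a warning, not a failure, below 90%: a species may genuinely
deviate at an anchor).  A hand-corrected alignment can be re-imported
(Stockholm dialect with an explicit `#=GF IMGT` label line, or aligned
FASTA whose labels are re-derived by the same anchor routine).

**Profile HMM.**  Match states are alignment columns with at least 50%
occupancy.  Emissions are column counts with a Laplace pseudocount of 1;
transitions follow the Plan7 topology (match/insert/delete, no I--D edges)
with a pseudocount of 1 per allowed move, so all probabilities are strictly
positive and every distribution sums to one.  Background (and insert)
emission probabilities are proportional to the number of amino acids a
symbol represents, which makes the background exactly uniform per residue
under any alphabet reduction.  One modelling choice deserves emphasis: at
the single junction whose flanking labels bracket the CDR3 pivot (base
<= 111 on the left, >= 112 on the right), the insert-opening and
insert-extension probabilities are set to 1/2.  The model knows positions
105--117 are absent there, so CDR3 residues should ride insert states at
that junction; without this prior the Viterbi path is score-tied between
opening the insertion at the junction and absorbing CDR3 residues into
framework columns they happen to match by chance.

Models are stored in a registry directory (one subdirectory per model:
profile as self-describing text with 17-significant-digit numbers for a
bit-exact round trip, metadata JSON, source alignment), resolved from an
explicit argument, `options(igprofile.registry=)`, the
`IGPROFILE_REGISTRY` environment variable, or the per-user data directory,
in that order.  Builds are deterministic to the byte.

## Alignment and scoring

Queries are aligned by Viterbi local alignment (Smith--Waterman-style free
entry into and exit from any match state) in log space; the bit score is
the log-odds of the path against the background divided by log 2.  After
the best hit is found its query interval is masked and alignment repeats,
up to 4 times, while hits clear the reporting threshold -- this produces
the multiple non-overlapping hits per domain that consensus merging needs.
Defaults, all exposed in `annotationConfig()`: reporting threshold 8 bits
(a short J-side fragment of ~11 conserved residues scores well above this;
random 10-mers almost never do), minimum hit span 5 residues, at most 4
hits per query per model.  Ties inside the dynamic programme break
deterministically (match preferred over insert over delete), so identical
inputs give identical hit lists.  The engine is ~100 lines of C++ via Rcpp;
its correctness is pinned by a brute-force path-enumeration oracle written
independently in R, which the test suite compares against on random tiny
profiles (<= 6 match states, <= 8 query residues) to 1e-6 bits.

## Consensus merging

The package's central mechanism.  All per-residue assignments
`(query index, IMGT position)` made by all hits of the chosen model are
pooled, and the consensus is the heaviest subsequence that is strictly
increasing in both query index and IMGT order.  Each assignment weighs one
residue; two small tie-breakers are added -- the emission log-odds of the
assignment (scaled by 1e-3) so a strongly aligned region outvotes a
coincidental single-column match, and the hit's bit score (scaled by 1e-9)
as a final deterministic tie-break.  Stretches of unassigned residues
between chosen entries cost 0.01 per residue *except* when the flanking
labels bracket the CDR3 pivot: CDR3-length gaps are free, which is exactly
the "no CDR3 length cap" requirement, while a spurious edge match that
would open a long gap elsewhere (say, inside FR4) is penalised away.  This
residue-level vote subsumes hit-level conflict resolution: a stray
conserved-column match at the edge of one hit loses to the hit that aligns
the whole region, and a second non-mergeable domain (an scFv-style query)
shows up as a high-scoring hit that retains under half of its assignments,
which rejects the query as `multiple_domains` (score floor 40 bits,
configurable).  A conflicting hit within 1 bit of the winner records an
`ambiguous_merge` finding.

Residues between consecutive consensus entries are then labelled.  When the
flanking labels bracket the CDR3 pivot the IMGT CDR3 rule applies: free
integer positions 105..117 middle-gapped for short loops, and loops longer
than 13 receive insertion codes 111.1, 111.2, ... ascending then ...,
112.2, 112.1 descending before 112 (the 112 side takes the odd one), under
the comparator 111 < 111.1 < ... < 112.2 < 112.1 < 112.  Elsewhere free
integers are used and overflow gets ascending insertion codes on the
preceding position.

## Validation heuristics and regions

The consensus is validated against knowledge derived from the model: at
least 80% of the model's FR1--FR3 match columns present (per region), FR4
present at all, labels strictly increasing (hard failure), Cys expected at
23/104 only when the model itself is >= 90% Cys there (a warning -- never a
rejection -- since anchors do vary), and a total matched span of at least
20 residues (shorter fragments are artefacts of the local aligner, not
domains).  There is deliberately no upper bound on CDR3 length.  Regions
are then cut at the fixed IMGT boundaries (FR1 1--26, CDR1 27--38, FR2
39--55, CDR2 56--65, FR3 66--104, CDR3 105--117 plus insertions, FR4
118--128); an empty region is emitted as a zero-length interval at the
boundary of its neighbours so the seven intervals always partition the
annotated span.  All coordinates are 0-based half-open throughout,
including the BED output.

## Reduced alphabets

Sequence-simplified models generalise beyond their training coverage.  The
package implements the hierarchical residue groupings of Li, Fan, Wang &
Wang (2003, *Protein Engineering* 16:323--330), sizes 3 to 20 (20 = no
reduction).  The hierarchy is stored as an explicit merge order whose
partitions at small sizes match the commonly reproduced Li et al. tables
(e.g. size 5: `CMFWY | LIV | G | ATS | NQDEHKRP`); where the source offers
several schemes at one size, the merge order documented in the source code
is this package's fixed choice.  A group's representative is its first
member in the listing, so the mapping is idempotent and surjective by
construction.  The alphabet size is stored inside the model and queries are
reduced automatically, so an unreduced query against a size-8 model gives
the same results as a pre-reduced one.

## Nucleotide input

Nucleotide records are translated in all six frames (standard genetic code,
partial codons dropped, ambiguous codons to `X`), frames containing a stop
codon are removed, the survivors are annotated, and by default only the
best-scoring annotated frame is kept per original read (`bestFrame`),
since stop-free wrong frames of real antibodies are the main source of
false annotations in practice.  Reverse-frame results are reported on the
`-` strand in BED with the original read id.

## The synthetic-data generator

All tests and the acceptance script run on generated data with known
truth; nothing is downloaded.  `makeGermlineSet()` derives `nV` V (96
residues, anchors fixed at the offsets the IMGT layout implies, CDR1 length
8, CDR2 length 6) and `nJ` J segments (11 residues from Trp 118) from a
seeded random ancestor at ~12% per-position divergence, giving pairwise
identities in the 70--90% band typical of germline families.  Non-anchor V
residues avoid Cys/Trp and J residues avoid Trp/Phe so the anchor finder is
unambiguous by construction -- a simplification relative to real germlines,
where anchor detection must fall back on windowed heuristics.
`makeRepertoire()` emits reads `V + insert + J` (insert length uniform in a
range, residues uniform over all 20 amino acids) with truth coordinates
recorded before seeded point mutations are applied outside the anchors; a
`breakAnchors` flag mutates the anchors instead, to exercise the
anchor-warning path separately.  What passing these tests does *not* show:
robustness to somatic-hypermutation hotspots, indels within frameworks,
allelic variation beyond the simulated divergence, or germline sets whose
segments differ in length -- real repertoires are messier than this
generator.

## Problem sizes and defaults used by the test suite

The suite builds models from a 4 V x 3 J set (seed 1) and annotates 200
zero-mutation reads (CDR3 0--10), 100 ultralong reads (CDR3 40--61), 500
reads at 5% mutations, 50 nucleotide-encoded reads, plus 100 random tiny
oracle cases; the whole suite runs in well under a minute per block on one
CPU.  The acceptance script repeats these measurements from scratch at a
caller-supplied seed and reports annotation rates, boundary exactness,
ultralong CDR3 recovery, oracle agreement, six-frame uniqueness and
worker-count invariance; it states nothing the code does not compute at
run time.

## Known limitations

The V-segment labeller requires canonical anchor spacing (full FR2/FR3);
germlines with framework indels are refused at build time rather than
approximated.  Only one annotated domain per query is supported
(multi-domain constructs are rejected, not split).  E-values are not
computed -- the bit-score threshold is absolute.  TCR models are untested
but nothing in the pipeline is antibody-specific beyond the anchor
conventions.
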