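---
title: "Measuring reductive genome evolution in a two-subspecies strain panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring reductive genome evolution in a two-subspecies strain panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Dairy lactobacilli such as *Lactobacillus delbrueckii* ssp. *bulgaricus*
(yogurt) and ssp. *lactis* (hard cheeses) live in milk, a stable,
nutrient-rich medium.  Genes for metabolising plant carbohydrates or
synthesising amino acids are superfluous there, and such genomes show
*reductive evolution*: genes decay into pseudogene fragments, disappear
outright, and insertion-sequence (IS) elements proliferate.  Comparing
strain panels of the two subspecies makes the process visible — one clade
has simply travelled further from the common ancestor than the other.

`reducto` implements the comparative-genomics measurements this kind of
study rests on, as a reusable, fully testable pipeline:

1. **Composition statistics** per genome: overall GC, CDS GC, GC at third
   codon positions (GC3, a signature of directional mutation pressure),
   coding density (union of CDS intervals), gap-aware genome-size
   estimates, and the IS-element landscape including the largest
   element-free region.
2. **Pseudogene-fragment detection**: each annotated CDS is searched,
   conceptually translated in six frames, against a reference protein set;
   when it aligns with proteins longer or shorter than its own product by
   strictly more than ±10%, those proteins are back-aligned (tblastn-style)
   to the CDS ± 3 kb of genomic context.  A CDS is marked
   `pseudogene_fragment` only if the chained back-alignment is longer than
   the CDS *and* shows a frameshift (frame change between collinear chained
   segments) or an in-frame stop codon.
3. **Ortholog clustering and core-proteome partition**: all-vs-all
   Smith-Waterman comparison of non-pseudogene proteins; an undirected edge
   requires e-value < 10^-3^, identity > 78% over aligned columns, and
   coverage > 76% of the longest sequence (all strict); groups are the
   connected components (single linkage).  The partition reports the
   overall core and the four categories of the subspecies comparison
   (A: present in all strains of one subspecies, absent from every strain
   of the other; B: absent from only some; C, D mirrored), plus **fragment
   rescue** — subspecies-specific groups whose trace survives as a
   pseudogene fragment in the opposite subspecies, evidence for
   differential loss rather than acquisition.
4. **Marker-gene phylogenetics**: progressive alignment, p/K2P distances
   with pairwise deletion, neighbor joining, bootstrap supports, an MLST
   run over seven housekeeping loci (fusA, gyrB, hsp60, ileS, pyrG, recA,
   recG), diagnostic-site detection in 16S-style alignments, and a
   Robinson-Foulds screen for horizontal transfer.
5. **Pathway-completeness phenotype prediction**: substrate pathways are
   AND-of-OR gene groups; a pathway is complete iff every group has an
   intact member (fragments never count); predictions are compared with an
   observed fermentation matrix and scanned for substrates that uniformly
   separate the subspecies.

## The synthetic study and what it does (not) emulate

Everything is exercised on simulated genomes with machine-readable ground
truth, generated by `simulate_study()`.  The default study conditions are
fixed once and used throughout the tests and the acceptance analysis:

* 10 strains in two clades of 5; 120 ancestral genes of 300-900 bp at GC
  0.50 (the organism's genomes print ~49.7%); 200-bp intergenic spacers;
  one 1.5-kb rRNA-like locus.
* clade divergence 1.5% (lactis-like) vs 3.0% (bulgaricus-like) from the
  common ancestor — the bulgaricus-like clade has evolved further — with
  0.5% per-strain divergence and an extra 0.8% shared by the first two
  lactis-like strains (a resolved subclade, so that within-clade edges
  exist against which transfer conflicts are measurable).
* per-gene loss/pseudogenisation probabilities 0.05/0.05 (lactis-like) vs
  0.12/0.10 (bulgaricus-like); lesions are single events per gene: one ±1
  frameshift, one in-frame stop substitution, or one 3′-truncation
  removing 30-70% of the gene.
* planted clade-specific sets of 12 (lactis-like) and 6 (bulgaricus-like)
  genes, of which 5 and 2 survive as detectable fragments in one
  opposite-clade strain each (the rescue quantity, echoing the 65/25 and
  24/5 proportions of the motivating study at desk scale).
* three horizontally acquired genes at foreign GC 0.42: one per clade and
  one (`hgtX`) present everywhere but replaced in the whole
  bulgaricus-like clade by a copy from the LAC01 tip lineage — a
  xenologous replacement.  A transfer into a clade *ancestor* leaves the
  unrooted gene-tree topology congruent with the strain tree (only branch
  lengths shift), so the planted event is a tip-lineage transfer, which
  creates a genuinely conflicting, well-supported split.
* IS libraries of three families; 20 insertions per lactis-like strain vs
  6 per bulgaricus-like strain, at most one per intergenic spacer and only
  in spacer intervals free of any annotated CDS.

Design constraints that keep the ground truth unambiguous (the point of a
planted-truth benchmark is that every downstream disagreement is a bug,
not an ambiguity):

* substitutions are ORF-preserving — they never create an internal stop
  nor touch the start or stop codon — so a planted lesion is the *only*
  source of gene disruption;
* frameshift and premature-stop offsets lie ≥ 30 codons from both termini
  and are chosen so that the re-annotated ORF (the gene caller reads from
  the ancestral start to the first in-frame stop) triggers the ±10%
  length anomaly with margin;
* truncations remove 30-70% so that the surviving prefix can never reach
  the 76% coverage threshold of the clustering.

What the generator deliberately does **not** model: correlated (ancestral)
loss events beyond the planted clade-specific sets — losses are drawn
independently per strain, so the synthetic core proteome is
proportionally smaller than in the real panel, where shared history
concentrates losses; recombination; codon-usage selection; realistic IS
transposition dynamics (sequences are random at genomic GC, insertion
sites uniform over free spacers); assembly artefacts (single contig per
strain, no gaps).  Passing the recovery tests therefore demonstrates the
*measurement machinery* is correct, not that real annotations are as
clean as simulated ones — on real data, gene-caller idiosyncrasies and
database incompleteness will dominate the error budget.

## Numerical and algorithmic choices

* **Coordinates** are 1-based closed throughout (the IRanges convention of
  the host ecosystem); GFF3 emission is then an identity mapping.
* **Alignment engine**: `Biostrings::pairwiseAlignment` (exact
  Smith-Waterman/Gotoh, BLOSUM62, gap open 11, extension 1; a length-k gap
  costs 11 + k).  E-values use the Karlin-Altschul approximation with the
  gapped BLOSUM62 parameters (λ = 0.267, K = 0.041) and the actual residue
  count of the run as the search space.  The 10^-3^ cutoff is loose by
  design; the identity and coverage thresholds dominate, so exact blastp
  statistical parity is not required.
* **Identity** is identical matches over aligned columns *including* gap
  columns (the blastp convention); **coverage** is the aligned span on the
  longer sequence over its length, evaluated on the single best local
  alignment.  All three thresholds are strict inequalities, as printed.
* **Candidate prefiltering**: all-vs-all comparison and translated search
  use shared 5-mer peptide counts to select candidate pairs (a seed
  heuristic in the blastp/blastx spirit).  At the default thresholds a
  qualifying pair shares far more words than the cutoff, so the edge set
  equals brute-force evaluation — asserted against an all-pairs oracle in
  the tests.
* **HSP splitting**: one optimal local alignment will bridge a long
  genomic insertion through cheap gap extensions, where a seeded aligner
  reports separate HSPs.  Back-alignments are therefore split into blocks
  at gap runs longer than `chain_max_gap`/3 residues (block scores
  recomputed under the same scoring) before chaining.  Without this,
  spacer homology downstream of a gene — carried into the reference set by
  overrun fragment annotations — masquerades as alignment extent.
* **Chaining and frameshift localisation**: same-strand segments chain
  when the later one adds at least 10 unique residues and some protein
  position splices the pair with a genomic gap of at most `chain_max_gap`
  (60 bp); the splice test works from per-column coordinates, so indel
  gaps inside an alignment cannot distort the geometry.  Local alignments
  overrun a lesion into the other segment's protein range — occasionally
  by 60+ residues of chance-scoring off-frame sequence — so the reported
  frameshift position is the optimal *splice point*: the protein position
  maximising the summed per-column scores of the first segment's prefix
  and the second's suffix, mapped to genomic coordinates.  On the default
  study this localises planted lesions to within a few bp.
* **Anomaly trigger over the hit list**: any significant hit with an
  anomalous length can trigger back-alignment (up to `max_backaligns`
  proteins are tried), not only the top hit.  With a reference set that
  itself contains fragments, the best hit may be a near-equal-length
  fragment of the same gene while the full-length homolog scores just
  below it; triggering on the list keeps the caller's recall at 100%
  without needing any intactness pre-filter on the database.
* **Terminal stops**: the stop ending an annotated CDS never counts as
  internal; a stop counts only with aligned residues on both sides within
  the chained alignment.  Genetic code: the standard bacterial table.
* **Neighbor joining** breaks Q-criterion ties on the smallest pair of
  subtree labels; negative branch lengths are clamped to zero with the
  deficit moved to the sister edge, which leaves additive inputs exact
  (verified over random additive trees).  Distances use pairwise deletion;
  p-distance is the default, K2P available, and saturated K2P pairs are
  reported `NA`, never imputed.
* **Progressive alignment** canonicalises on sorted labels (input order
  cannot change the result), builds its guide tree from fractional shared
  k-mer distances with average linkage, and merges profiles by
  global affine profile-profile alignment (sum-of-pairs column scores,
  existing gaps score zero) in compiled code.
* **Incongruence flag**: Robinson-Foulds distance is the plain symmetric
  difference of non-trivial splits, but the *transfer screen* is stricter:
  it requires a well-supported split of one tree to be incompatible (the
  classical four-intersection test) with a well-supported split of the
  other.  A split merely unresolved in the other tree — the normal state
  of weak within-clade edges in single-gene trees — is not evidence of
  transfer.  With a plain supported-symmetric-difference flag, vertically
  inherited control genes get flagged routinely.
* **Rounding** for report output is half-up to one decimal (composition
  tables print one decimal); raw fractions are kept alongside.
* The ±10% length-anomaly boundary is read strictly (exactly 10% does not
  trigger), with the CDS-encoded protein length as the denominator; both
  choices are configurable.  A lone frameshift splitting a gene into two
  normal-looking CDS leaves no length anomaly and is *not* caught — the
  procedure is implemented as specified, anomaly first.

## Problem sizes used by the tests and the acceptance analysis

Unit and property tests run on toy constructions and a reduced study
(6 strains, 45 genes).  The acceptance analysis and `analysis/` scripts
use the full default study (10 strains, 120 genes, ~1.1 Mb of genome in
total), 1000 bootstrap replicates for the MLST tree, 200 random additive
trees for the neighbor-joining check, and 200 replicates for the gene-tree
supports in the transfer screen.  These sizes were chosen so the whole
analysis reruns comfortably on a laptop core while every planted quantity
remains exactly recoverable.

## Known limitations

* The pseudogene caller's reference set is the other strains' annotated
  proteomes; a gene lost or broken in *every* strain leaves no full-length
  reference and cannot be called (in the real study an external protein
  database plays this role).
* Truncation lesions without frameshift/stop evidence are invisible to
  the caller by construction of the published procedure; they are,
  however, kept out of ortholog groups by the coverage threshold, so
  partition counts remain exact.
* The e-value model is an approximation (one λ/K pair for all matrices);
  it is not intended for marginal-significance decisions.
* `diagnostic_sites` reports alignment-column coordinates; projection to a
  reference numbering system is out of scope.
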