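---
title: "Deletion-bin mapping and functional-marker analysis with delbin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deletion-bin mapping and functional-marker analysis with delbin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delbin)
```

## The mapping problem

Hexaploid bread wheat carries three homoeologous copies of each
chromosome (genomes A, B and D), and classical cytogenetic stocks make
it possible to place a PCR marker on a physical map without any
sequence assembly:

* a **nullisomic–tetrasomic (NT)** line lacks one chromosome pair,
  compensated by four copies of a homoeologue — a marker that fails to
  amplify only in the lines nullisomic for chromosome *C* lies on *C*;
* a **ditelosomic (Dt)** line retains a single chromosome arm — failure
  to amplify in the line retaining arm *X* places the marker on the
  complementary arm;
* a **terminal-deletion (Del)** line retains the proximal fraction
  `[0, f]` of one arm, where the breakpoint *f* is expressed as a
  *fraction of arm length* (FL, 0 at the centromere, 1 at the
  telomere).

`delbin` implements this workflow for a family of wheat peroxidase
(POD) genes — enzymes whose grain activity bleaches carotenoid pigments
and so matters for flour colour — but every operation is generic over
markers and arms.

### The bin model

Given error-free presence/absence calls on one arm, the marker position
*p* satisfies `p > f` for every Del line lacking the marker and
`p <= f` for every line retaining it. The inferred **deletion bin** is
therefore the half-open interval

```
( max{f : line absent},  min{f : line present} ]
```

with two boundary conventions:

* **lower bound 0** when no Del line on the arm lacks the marker;
* **upper bound 1.0** when no Del line on the arm retains it. This
  "whole-arm" upper bound is only sound when the arm's Dt line does
  amplify the marker, and `infer_bin()` enforces that; for a telomeric
  bin the *distal fraction* `1 - lower` is also reported.

The upper bound is inclusive because a retaining line with breakpoint
*f* is compatible with a marker exactly at *f*; the lower bound is
exclusive for the symmetric reason. `brute_force_bin()` re-derives the
same interval by exhaustive enumeration over an FL grid (default step
0.001) and exists purely as an independent oracle; the two routes are
required to agree in the test suite on randomized panels.

When the interval degenerates (`lower >= upper`) the calls are
mutually contradictory. The default policy is strict: a
`delbin_contradiction_error` lists the conflicting line pairs. An
optional *tolerant* mode greedily drops the call implicated in the most
conflicts (ties broken by line name, so the result is deterministic)
and reports what it dropped. Real deletion panels are small enough that
silent auto-repair would be more dangerous than useful, which is why
tolerance is opt-in.

Missing calls (`NA`, printed as `/` in amplification tables) never
contribute evidence anywhere. Two primer sets that assay the same gene
can be merged line-by-line with `merge_marker_calls()`; a disagreement
between them demotes that line to missing with a warning rather than
letting one primer set win.

## Gene models and the ATG-anchored coordinate system

Cloning tables in this literature anchor coordinates at the initiation
codon: the A of the ATG is +1, 5′-UTR positions are negative, and there
is **no position 0**. `region_length()` implements the resulting
arithmetic (a region from −20 to 468 spans 488 bp). All variant
positions reported by the package use the same convention.

`merge_amplicons()` joins overlapping PCR fragments on an exact
suffix/prefix match, longest first, with a 15-bp minimum by default —
comfortably below the junctions such primer walking produces, but large
enough that random 25%-identity sequence essentially never matches.
Sequencing-error tolerance is deliberately out of scope: the inputs are
Sanger-validated amplicon consensus sequences, not reads. When an
overlap length is implied by declared coordinates the caller can pass
`expected_overlap` and a mismatch is reported with its first discordant
offset. Where a stated overlap and the declared coordinates of two
fragments disagree, the coordinates govern: they are the only
representation consistent with the fragment sizes and the merged
length.

`build_gene_model()` partitions a genomic sequence into 5′ UTR, ORF and
3′ UTR. In automatic mode the initiation codon is the 5′-most ATG that
(a) satisfies a lenient, single-criterion Kozak rule — purine at −3
*or* G at +4; both context bases are reported — and (b) is followed by
an in-frame stop. The rule is deliberately lenient because translation
initiation context is invoked qualitatively in gene-cloning work, not
with a calibrated score; a stricter rule would reject genuine
initiation codons in GC-rich cereal genes. Translation uses the
standard genetic code; the terminal stop is never included, so an ORF
of `3n` bp yields `n − 1` residues. Molecular weight is the sum of
average residue masses plus one water, in kDa; an empty protein returns
the mass of water with a warning, a defined answer being more useful
than an error for degenerate inputs. GC content is reported to 0.1%.

## Variant calling between alleles

`global_align()` computes a Needleman–Wunsch global alignment with
affine gaps (via Biostrings). The default scoring — match +2, mismatch
−3, gap open −7, gap extend −2 — is conservative about gaps relative to
mismatches so that a single multi-base InDel stays intact instead of
fragmenting into scattered single-base gaps; all four parameters are
configurable. Tie-breaking among co-optimal alignments follows the
aligner's deterministic traceback. An independent plain-R affine-gap
scorer cross-checks alignment scores on short sequences in the test
suite.

`call_variants()` turns each mismatching column into one SNP (adjacent
substituted columns count separately, matching how such comparisons are
tallied in the literature) and each maximal gap run into a single
InDel. InDels are normalised by left-aligning within their repeat
context, the same convention VCF uses, so a planted event has exactly
one canonical representation; positions report the reference base
immediately 5′ of the event. Identity is `100 × matches / columns`,
gap columns included in the denominator — the denominator must be
stated because published identity percentages rarely say which
convention they use, and the package's figure is therefore
property-tested rather than compared to any printed value. The
molecular weight of the modelled proteins is treated the same way.

Applying a called variant set back onto the reference allele must
reconstruct the other allele exactly; this patch round-trip is enforced
for every generated pair in the tests.

Protein consequences are computed by translating both gene models and
aligning the proteins: substitution columns are missense counts, gap
content is inserted/deleted residues. Codon arithmetic resolves the
classic off-by-one of "an insertion between bases 42 and 43": base 42
ends codon 14, so a 6-bp insertion there contributes the residues at
positions 15–16 of the longer protein. Any InDel whose length is not a
multiple of 3 flags the comparison as a frameshift and the downstream
consequence fields are reported as undefined rather than guessed.

## Allele-specific PCR and genotype calls

The binding model for `find_binding_sites()` has two parameters: the 3′
terminal `three_prime_exact` bases (default 3) must match the template
exactly, and at most `max_mismatch` (default 2) mismatches are allowed
elsewhere. This reflects how allele-specific primers discriminate — Taq
cannot extend a mismatched 3′ terminus — without pretending to model
annealing thermodynamics; annealing temperatures are carried as
metadata only. Both strands are scanned, and `insilico_pcr()` pairs
convergent sites into products (size measured between the primers' 5′
ends, capped at 5 kb by default), so results are invariant under
reverse-complementing the template.

A *complementary dominant* marker pair — two assays, each amplifying
exactly one allele — behaves like a codominant genotype call:
`call_genotype()` maps "product in assay b only" / "assay a only" /
"both" / "neither" to the b allele, the a allele, `ambiguous`, and
`null` respectively. Product sizes are matched to each assay's expected
size within ±10 bp, a gel-resolution analogue; off-size products are
ignored with a warning.

## Marker–trait association

Enzyme-activity phenotyping follows a duplicate-measurement protocol
with a CV rule: if the duplicate coefficient of variation exceeds 10%,
a third measurement is made. `qc_mean()` implements the rule and
resolves the retest as the **mean of the two closest values**, which
discards the aberrant measurement that triggered the rule; the protocol
itself only promises "average values", so this resolution is a package
decision, logged per record in the returned status. Records that
exceed the threshold with no retest available fail QC and are excluded
(and counted) by `associate()`.

The association test is a fixed-effects one-way ANOVA on per-variety
accepted means (delegated to `stats::lm`/`anova`), followed by Fisher's
LSD at α = 0.05 and 0.01:

```
LSD_ij = t(1 − α/2, df_within) * sqrt(MSW * (1/n_i + 1/n_j))
```

with letters assigned by the standard descending-mean line method.
Multi-environment structure is flattened to a per-variety mean before
testing; population structure, kinship and multiple-marker corrections
are out of scope for this single-locus design. On two groups the ANOVA
F statistic equals the squared pooled-variance t statistic, which the
tests verify numerically.

## What the synthetic generators emulate

Every pipeline input has a generator that records its ground truth, so
each stage — and the pipeline end-to-end — is testable without any
sequence accession or raw phenotype file:

* `gen_stock_panel()` / `gen_amplification_matrix()` reproduce the
  deletion geometry exactly (a Del line retains `[0, f]`), with
  independent per-cell false-absent/false-present error rates for
  robustness tests;
* `gen_allele_pair()` defaults to the allele configuration central to
  the package's motivating use case: a 1074-bp ORF (357 residues) with
  a 20-bp 5′ UTR and 27-bp 3′ UTR, 21 non-adjacent exon SNPs, and one
  in-frame 6-bp insertion (GCTGTG) after ORF base 42, which adds an
  Ala–Val dipeptide and yields a 359-residue allele. SNP placement
  avoids the start/stop codons, a ±6-bp guard window around the
  insertion, and never creates a stop codon; the insertion context is
  forced non-repetitive so the planted event is its own left-aligned
  normal form and recovery can be required to be exact;
* `gen_pcr_template()` plants primer sites at a configured spacing and,
  for the non-target allele, mutates the allele-specific primer's 3′
  terminal base — the complementarity invariant (exactly one assay
  amplifies per template, never both, never neither) is then a testable
  property rather than an assumption;
* `gen_variety_panel()` draws variety means per allele group from a
  normal law and replicates around them with a configured CV,
  re-measuring any duplicate whose CV exceeds the threshold, exactly as
  the QC rule expects. The defaults — two regions with group sizes
  83/64 and 32/45 (224 varieties, 115 + 109 per allele), means 676 and
  708 U min⁻¹ g⁻¹, between-variety SD 80, replicate CV 5% — put the
  synthetic panel on the scale of published wheat POD activity panels.
  A scaled-t option provides heavier tails for robustness checks.

What the generators do **not** emulate is real wheat sequence
composition (GC content is a knob, not a model), linkage between the
marker and unmodelled loci, genotyping error, or genotype × environment
interaction. Passing tests therefore demonstrate that the inference
machinery is correct under its stated model, not that the model captures
every property of field data.

Group sizes in the published activity table disagree with the running
text about which allele has 115 carriers; the package treats group
counts as data and never hard-codes an allele-to-count assignment.

## Numerical and reproducibility choices

* FL values are handled as plain doubles; the brute-force oracle uses a
  `1e-12` slack when comparing grid points to breakpoints so that a
  breakpoint lying exactly on the grid is classified consistently.
* Every generator accepts one explicit integer seed and restores the
  caller's RNG state afterwards; identical seed and configuration give
  byte-identical output, and the pipeline reports embed the package
  version and seed in a header line.
* Monte-Carlo checks in the test suite use fixed seeds with
  3-standard-error binomial bands: the type-I error of the association
  test is checked against α over 200 simulated null panels, and the
  rejection rate under a planted 32 U min⁻¹ g⁻¹ effect at the default
  group sizes is checked against the closed-form power of the
  corresponding two-sample t test. Panel sizes in these simulations
  (60–224 varieties, 200 replicates) keep the whole suite under a
  couple of minutes without starving the binomial comparisons.
* Alignment-oracle cross-checks run on sequences up to 12 bp, where
  exhaustive affine-gap scoring is tractable; bin-oracle equivalence
  runs on 100 randomized panels with breakpoints on a 0.01 grid so the
  0.001-step grid hull is exact.

## Known limitations

* The bin model assumes a single locus per marker per genome; a marker
  absent in nullisomics of two chromosomes is flagged `multi_locus` and
  left unassigned rather than resolved.
* `merge_amplicons()` is exact-match only and so unsuitable for raw
  read data.
* The in-silico PCR model ignores primer thermodynamics, secondary
  structure and competition; it answers "would this primer pair with
  these 3′ termini produce this fragment", not "how efficient is the
  reaction".
* `associate()` fits a single-locus fixed-effects model; it will
  happily report a significant association that a structured population
  would explain away.
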