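---
title: "svherd: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svherd: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`svherd` implements the post-calling half of a cattle structural-variant
(SV) survey: everything that happens *after* two SV callers and a
small-variant caller have produced joint-genotyped VCFs for a cohort.
Raw-read processing (alignment, depth computation, the callers themselves)
is out of scope; depth summaries and VCFs are inputs. The package provides

* site-level filtering with the caller developers' recommended rules,
* sample sex inference from X/Y-to-autosome depth ratios,
* identification of SVs detected by both callers,
* genotype-quality evaluation via KING kinship against a SNP baseline,
* chip-marker overlap and tag-SNP discovery by dosage r²,
* gene exon/CDS overlap and processed-pseudogene artifact flagging,
* per-SV report cards (allele frequency, genotype counts, exact HWE), and
* a synthetic pedigree-cohort generator that exercises all of the above
  with known truth.

# Coordinate conventions

All coordinates are 1-based inclusive, as in VCF and GTF. For symbolic SV
records (`<DEL>`, `<DUP>`, `<INS>`) the VCF POS is the base *before* the
event, so the affected reference interval of a deletion or duplication is
`POS+1 .. END` and its length is `END − POS`. Insertions are zero-length
breakpoints at POS; for affected-base accounting they contribute
`|SVLEN|` bases. SNPs count one base and indels the absolute REF/ALT
length difference. Affected-base totals are additive — overlapping records
within one call set are deliberately double-counted, matching the way the
published per-caller genome-coverage table was constructed.

# Filtering rules

Smoove-style site filters (`filter_smoove_site`): a site is kept only if
its mean heterozygous-sample quality (MSHQ, range 1–4) is strictly greater
than 3, and — for deletions — the site-level DHFFC (depth fold change
inside the SV relative to its flanks) is strictly below 0.7, or strictly
above 1.25 for duplications. DHFFC is reported per sample; the published
thresholds are per site. We aggregate as the **median over carrier
samples** (dosage ≥ 1), the robust choice and the common duphold practice;
sites with no heterozygous sample (no MSHQ) or no carrier DHFFC pass the
corresponding rule and are counted as pass-throughs rather than silently
dropped.

Universal rules (`filter_universal`): spans strictly larger than 0.5 Mb
are removed (span = `END − POS`, the choice documented over `SVLEN` since
the two can disagree for imprecise calls), as are records on contigs
outside the whitelist and 1-bp deletions (a known caller artifact class).
GATK hard filters (`gatk_hard_filter`) implement the published SNP rules
(QD < 2, FS > 60, MQ < 40, MQRankSum < −12.5, ReadPosRankSum < −8) and
indel rules (QD < 2, FS > 200, ReadPosRankSum < −20); any one failing rule
drops the site, absent annotations never fire, and all inequalities are
strict so metrics exactly at a threshold pass. Every filter attributes a
removed record to the *first* failing rule in the fixed order (size,
contig, 1-bp, MSHQ, DHFFC), making report counts conserve totals exactly.

# Sex inference

`depth_ratios` computes X:autosome and Y:autosome ratios using the
unweighted mean of per-autosome mean depths as the baseline (the
alternative, weighting by chromosome length, differs negligibly when
per-chromosome depths are near-uniform). `classify_sex` applies rectangular
regions: XX when x ≥ 0.8 and y ≤ 0.1; XY when x ∈ [0.35, 0.65] and
y ∈ [0.25, 0.75]; XYY-like when x ∈ [0.35, 0.65] and y ≥ 0.85; anything
else is reported as *ambiguous* rather than forced into a class. The
numeric bounds are this package's operationalisation of what the original
study did visually from a scatter plot; they separate the observed
clusters with wide margins and are all configurable.

# Shared-SV identification

A pair of records, one per caller, is *shared* when the SV type and
chromosome match, the overlapping portion is at least 90 % of the length
of **each** record, at least 90 % of comparable genotypes agree, and no
sample is homozygous-reference in one set while homozygous-alternate in
the other. Genotypes missing in either record are excluded from the
concordance denominator (the alternative — counting missing as mismatch —
would penalise a caller for its missing rate twice). Insertions have no
span, so "overlap" for INS pairs is breakpoint distance ≤ 100 bp, a
package invention needed only for totality. When a record has several
qualifying partners, the pair maximising `min(frac_a, frac_b)` wins, ties
broken by genotype match fraction, then leftmost partner start; matching
is greedy one-to-one in descending score. Merged records carry the first
set's genotypes (the Manta-role precedence).

# KING kinship and the correlation experiment

For samples *i*, *j* with dosages over pairwise-complete loci,

φ = (N_het,both − 2·N_opposing-hom) / (N_het(i) + N_het(j))

— the within-pair KING-robust estimator, as produced by
`vcftools --relatedness2`. φ is 0.5 for identical genomes and ≈ 0.25 for
parent–offspring pairs, independent of allele frequencies, and is
invariant to allele-label swaps. `king_matrix` evaluates all pairs by
cross-products of het/hom indicator matrices, identical to the per-pair
definition (unit-tested against a loop oracle).

The evaluation protocol (`kinship_correlation`) mirrors the published one:
a single SNP baseline of 20,000 biallelic loci with per-site missing rate
≤ 0.1 is drawn once without replacement; then 100 replicates of 2,000 SV
loci are drawn *with* replacement, φ is recomputed per replicate, and the
Pearson correlation between SV-based and SNP-based φ is taken over all
sample pairs where both are defined. Only autosomal loci should be
supplied: X loci in XY samples are hemizygous (diploid-coded 0/2), never
heterozygous, and measurably deflate parent–offspring φ.

# Tag SNPs and chip overlap

A chip marker *overlaps* an SV when its position lies inside
`POS+1 .. END` (the anchor base at POS is excluded; insertions never have
overlapping markers). A *tag SNP* lies outside the SV, within 10 kb of
the nearer SV edge, and has dosage r² ≥ 0.8 with the SV, where r² is the
squared Pearson correlation of 0/1/2 dosages over pairwise-complete
samples (the `vcftools --geno-r2` quantity). Candidates from both flanks
are visited nearest-first (ties: left flank first) and scanning stops
after five tags. The scan order affects only *which* five tags are kept
when more than five qualify, never whether an SV has a tag. Distances are
measured from the SV edges, not its midpoint; the 10 kb window applied to
the edge is a documented convention (the source is silent on edge vs POS).

# Gene overlap and pseudogene artifacts

`gene_overlaps` reports, per gene, the exon (and separately CDS)
intersection with each SV's affected interval, unioned over transcripts,
and records it only when it reaches 10 bp. The floor exists precisely
because of processed pseudogenes: an intron-less retro-copy of a gene
inserted elsewhere sends its reads back to the parent gene, where
split-reads spanning exon–exon junctions mimic intron deletions whose
boundaries poke a few bases into flanking exons.

`flag_pseudogene_artifacts` operationalises the qualitative signs of such
artifacts: a deletion *intron-matches* when both boundaries are within
20 bp of the same annotated intron's boundaries; a gene is flagged when
one sample carries intron-matching deletions over at least 2 distinct
introns; *het-only* evidence is added when ≥ 80 % of carrier genotypes
are heterozygous, and *exon-coverage-elevated* when a carrier's exon
coverage reaches 1.3× the cohort median (only if a coverage track is
supplied — its absence downgrades, never blocks, a flag). All four
thresholds are heuristics invented here, exposed as parameters, and must
not be read as values from the original study.

# Exact Hardy–Weinberg test

`hwe_exact` is the two-sided exact conditional test: given the allele
counts, every heterozygote count *h* of matching parity has probability
∝ 2^h · n! / (n_AA(h)! · h! · n_aa(h)!), and the p-value sums the
probabilities of all configurations no more likely than the observed one
(plain minimum-likelihood tail; no mid-p correction). Probabilities are
evaluated with log-factorials and normalised; the test suite cross-checks
against an independent recurrence-based enumeration to 1e−12 and against
the reference value p = 0.61 for genotype counts (273, 37, 0) — the
closest-AF-to-0.06 configuration for a 310-sample cohort with no
homozygous-alternate genotypes. Comparisons use a 1 + 1e−12 relative
guard so ties in probability are included despite floating-point noise.

# The synthetic cohort generator

`simulate_cohort` produces the full stated world downstream stages need:

* **Cohort**: 310 samples, 290 XY / 20 XX by default, on five 10-Mb
  autosomes plus an 8-Mb X and 2-Mb Y (real bovine coordinates are a
  non-goal).
* **Pedigree**: a small-effective-size breeding population — 30 founders,
  with each later sample fathered by one of the first 8 samples
  ("popular sires") and the second parent drawn from all earlier samples.
  This is the deliberate model of an intensively selected dairy
  population: pervasive, graded relatedness is what makes kinship-based
  genotype evaluation informative. With an outbred design (hundreds of
  unrelated founders) the between-pair kinship variance is so small that
  even perfect SV genotypes cannot correlate strongly with the SNP
  baseline, so the published protocol would be uninformative on the
  synthetic data. The pedigree is deterministic and independent of the
  master seed: it is part of the stated world.
* **Allele frequencies**: founder frequencies are Beta(0.5, 0.5), giving
  the U-shaped spectrum typical of sequence-discovered variants, clamped
  to [0.02, 0.98] so loci stay polymorphic at cohort size.
* **LD structure**: SNPs within 10 kb of an SV copy the SV's founder
  haplotype allele with probability √r²* (r²* = 0.9 by default), else an
  independent draw at the same frequency; this makes the haplotype
  correlation θ = √r²* and hence the dosage r² ≈ r²*, exercising the tag
  scanner in both directions.
* **Transmission**: children receive recombinant gametes (Poisson
  crossovers at 1e−8 per bp per meiosis, no interference). X
  transmission follows the parents' sex labels; XY samples are
  hemizygous on X, diploid-coded 0/2 as short-read callers do.
* **Depth**: 20× mean autosome coverage with 5 % CV per chromosome;
  X at 1× (XX) or 0.5× (XY) the autosome level, Y at ~0 or 0.5×. At
  these noise levels the sex classes are separated by many standard
  deviations, which is why the sex-inference acceptance check expects
  100 % accuracy — it validates the classifier regions, not robustness
  to pathological noise.
* **Pseudo-callers** (`emulate_caller`): each truth locus is reported
  with a detection probability, POS/END are jittered uniformly, and
  genotypes are corrupted per SV type. Errors are *adjacent-dosage*
  miscalls (0→1, 2→1, 1→0 or 2): a single error never converts one
  homozygote into the opposing one, matching how joint genotypers
  actually fail. (Uniform replacement would put an opposing-homozygote
  pair at nearly every site in a 310-sample cohort and empty the shared
  set.) Site MSHQ is drawn near 3.6 ± 0.4 truncated to [1, 4] so a
  minority of sites fail the > 3 rule; DHFFC is drawn from the *true*
  copy-number state (DEL carriers 0.5 het / 0.05 hom, DUP 1.5 / 2.0,
  non-carriers 1.0, σ = 0.05) so both filter directions are exercised.
  Default error rates keep deletions cleaner than duplications (alpha
  0.01/0.03, beta 0.03/0.07) with beta missing 0.003 and no insertions —
  free parameters chosen once; the qualitative DEL < DUP ordering is the
  only anchored property.
* **Pseudogene artifacts** (`inject_pseudogene_artifact`): for a chosen
  gene with ≥ 2 introns, each carrier receives a heterozygous deletion
  exactly spanning every intron, and the carrier's exon coverage for that
  gene is raised 1.6× — the closed loop for the artifact flagger.

**Determinism.** Every draw runs under a seed derived by hashing the
master seed with a stage and locus key, so a fixed seed yields
byte-identical output files and adding loci or stages never perturbs
draws for existing ones. Streams are keyed per (stage, locus) and
vectorised across samples — the per-(sample, locus) granularity would
multiply seeding cost by the cohort size without adding any stability
property that is actually relied on.

**What a green test does not establish.** The generator has no
read-level errors, no reference bias, no repeat-driven false calls, no
population structure beyond the single pedigree, and caller error is
independent across samples and loci. Green acceptance therefore
validates the *pipeline logic* — conventions, thresholds, estimators,
bookkeeping — on data with the assumed statistical structure, not caller
accuracy on real genomes.

# Known limitations

* Two-caller merging only; no multi-caller (> 2) support.
* BND and inversion records are skipped on read (with a logged count),
  matching the downstream scope of DEL/DUP/INS.
* The exact HWE test is the plain conditional test; no mid-p variant.
* `find_shared` is quadratic per (chromosome, type) stratum after an
  interval prefilter — fine for ~10⁵ records, not engineered for more.
* Hemizygous X genotypes are evaluated as diploid-coded, with
  sex-stratified card blocks as the interpretive aid; no ploidy-aware
  statistics.
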