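---
title: "Mapping a recessive retinal-disease locus to an intronic SINE insertion: methods"
author: "sinemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive retinal-disease locus to an intronic SINE insertion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinemap)
```

# The problem

Progressive retinal atrophy (PRA) is an inherited photoreceptor
degeneration of dogs, the counterpart of human retinitis pigmentosa, and in
most breeds it segregates as an autosomal recessive trait. `sinemap`
re-implements, as a tested pipeline over synthetic data, the chain of
analyses by which such a locus is discovered and characterised:

1. case–control association with stratification correction
   (`assoc_scan()`),
2. homozygosity mapping of a critical region shared by cases
   (`scan_regions()`),
3. segregation- and exon-proximity-filtered variant screening
   (`segregation_filter()`, `proximity_filter()`),
4. split-read detection of a mobile-element insertion with target-site
   duplication (TSD) inference and read-support genotyping
   (`call_insertions()`),
5. structural decomposition of the inserted SINE
   (`decompose_insert()`),
6. branch-point displacement and splice-acceptor impact
   (`find_bps()`, `assess_insertion()`),
7. exon-skip transcript consequences (`compare_isoforms()`,
   `insilico_rtpcr()`), and
8. panel concordance / penetrance statistics (`concordance()`,
   `penetrance_proxy()`).

The numbered scripts under `analysis/` run these stages in order on the
package's own simulated inputs; every computation lives in the package and
is unit-tested.

# Association scan

The scan uses the allelic (allele-count) 1-df chi-square per marker, not a
genotypic test — the convention of standard GWAS toolkits for biallelic
markers. Population stratification is handled by complete-linkage
clustering of samples on identity-by-state (IBS) distance (1 minus the
shared-allele fraction over co-genotyped markers) cut at a fixed `K`
(default 2), followed by a Cochran–Mantel–Haenszel (CMH) test across
clusters. `K` is a user parameter because the clustering criterion used in
the original analysis is not recoverable; complete linkage with a fixed cut
is deterministic and reproducible.

**A note on the CMH variance term.** The package requires exactly that
`cmh_test()` with one stratum equal `allelic_test()` — a reduction property
the tests assert to machine precision. The classical Mantel–Haenszel
variance $r_1 r_2 c_1 c_2 / (n^2(n-1))$ makes the one-stratum statistic
$(n-1)/n$ times the Pearson chi-square, so `sinemap` uses $n^3$ in the
denominator instead. The two forms differ by under 1% at the sample sizes
involved and are asymptotically identical; the test suite cross-checks
against `stats::mantelhaen.test()` at exactly that $(n-1)/n$ ratio.

Multiple testing uses max(T) permutation: phenotype labels are permuted
*within clusters*, and each marker's p-value is
$p_{genome} = (1 + \#\{\max_m T^{perm} \ge T^{obs}_m\}) / (1 + n_{perm})$.
Ties count as exceedances and the +1 smoothing keeps p-values positive, so
$p_{genome} \ge 1/(n_{perm}+1)$. The genomic inflation factor is
$\lambda = \mathrm{median}(T)/q_{\chi^2_1}(0.5)$; the suite verifies
$\lambda \approx 1$ on null statistics and that the family-wise error rate
of the scan is approximately the nominal 5% over 200 replicate null
cohorts (20 samples, 50 markers, 200 permutations each).

# Homozygosity mapping

For each marker the *shared allele* is the allele homozygous in the
plurality of cases, with ties broken lexicographically — a deterministic
stand-in for visual haplotype inspection. A case *supports* an interval
when it fails to be homozygous for the shared allele at no more than
`case_mismatch_tolerance` markers (default 1); missing genotypes count
against the tolerance, not against the run, which is the permissive reading
of "almost completely homozygous". An interval is reported when the
supporting fraction reaches `min_case_fraction` (default 0.65, the
majority-of-cases regime of 12 supporting cases out of 18), no control is
homozygous for the shared haplotype across it, and every obligate carrier
is non-homozygous. Only maximal such intervals are kept, ranked by bp span.
Region bounds are the outermost markers of the run (1-based inclusive;
spans are quoted as $(end-start)/10^6$ Mb, and BED export converts to
0-based half-open). Multiallelic microsatellites participate exactly like
SNPs: homozygosity is allele-pair equality.

The implementation is an $O(m)$-starts sweep using per-case prefix sums and
per-control homozygosity run lengths; the tests prove it equal to an
exhaustive $O(m^2)$ interval oracle on 100 random matrices and verify that
the top-ranked region contains a planted locus in at least 90% of 50
default-configuration cohorts.

# Variant screen

The recessive segregation rule retains a call only if it is homozygous
alternate in every case, heterozygous in every obligate carrier and
homozygous reference in every control. A missing genotype in any pivotal
sample excludes the variant by default (the candidate that motivated the
rule was fully typed); `permissive = TRUE` treats missing as compatible.
The exon-proximity rule keeps variants inside an exon or within `window_bp`
(default 50) of an exon boundary — the original "in or near an exon"
criterion has no printed distance, so 50 bp is a declared default chosen to
cover canonical splice motifs and the −15/−16 near-acceptor site. Indels
longer than ~10 bp are typically absent from small-variant callers; the
split-read stage below is the discovery path for those.

# Insertion detection from short reads

A mobile-element insertion with a TSD leaves three signatures in 51-bp
alignments: reads terminating abruptly with soft-clipped tails at two
nearby positions (the two ends of the duplicated motif), a step to roughly
double read depth across the motif, and — in carriers — both clipped and
cleanly spanning reads at the same site. `collect_clip_clusters()` groups
clip positions (minimum clip 8 nt, cluster window 5 bp); a right-clip
cluster at $R$ pairs with a left-clip cluster at $L$ when
$4 \le R-L+1 \le 30$, and the reference interval $[L..R]$ is the TSD.
These thresholds are declared defaults tuned for 51-bp reads — the original
inspection was visual and published no numbers.

Insert ends are reconstructed as per-column majority consensus of the
clipped tails (truncated below 60% agreement), so with reads shorter than
the insert at most read-length − min-clip = 43 nt per end is recoverable
and the insert is only partly determined, exactly the partial-reconstruction
regime the read simulator reproduces.

**Allele fraction.** A clipped read attests the insertion at one junction;
a read spanning the whole motif unclipped attests the reference allele at
*both* junctions. The insertion allele fraction is therefore
$\mathrm{vaf} = s/(s + 2p)$ with $s$ supporting and $p$ spanning reads.
Counting spanning reads once would bias a heterozygote to $2/3$ (supporting
reads accrue at two junctions, spanning reads at one locus); with the
two-observation convention the heterozygote expectation is exactly 0.5 for
the default geometry (51-bp reads, 14-bp TSD, 8-nt clip/anchor minimum), in
line with "about half the reads" carrying an insertion in a carrier.
Genotype thresholds (hom ≥ 0.85, het 0.25–0.75, hom-ref ≤ 0.10, else
no-call) are justified by binomial concentration at ≥ 30X: the suite
verifies ≥ 95% correct trio genotyping with the exact 14-bp TSD at 30X over
100 replicates.

# SINE decomposition

A fully resolved insert is parsed 3′-anchored-first: the poly(A) tract is
the longest suffix with ≥ 90% adenine and no two adjacent non-A bases
(single interrupting T's are characteristic), trimmed to start on an A;
the dinucleotide linker is the maximal tandem 2-mer run nearest the
poly(A); the SINE body is the 5′ remainder, defined positionally — matching
against a repeat consensus library is out of scope. Components tile the
insert, which the tests assert as a conservation property, and decomposing
a generated insert returns the generator's parameters exactly over 100
random architectures (body 80–200 bp, 3–12 linker copies, poly(A)
20–60 bp). The observed allele's architecture — 132-bp body, (CT)₈,
interrupted poly(A), 14-bp TSD, 238 bp in total — is the generator default
in the read-simulation regime. Poly(A)-length variation between alleles is
reported but never alters genotype calls.

# Splice impact

The acceptor consensus is 6 pyrimidines, any base, then CAG ending the
intron; the terminal AG is invariant, and hexamer non-pyrimidines plus a
non-C at the C position consume a mismatch budget (default 1). The
branch-point sequence (BPS) consensus is Py-N-Py-T-Pu-A-Py with the branch
A at position 6. The *offset* of a BPS is measured from the branch A to the
last intron base, 1-based — the measurement endpoint is not defined in the
source material, and this convention is the one under which the packaged
fixture reproduces a 76-nt wildtype offset. The canonical window is
20–50 nt; `find_bps()` searches nearest-first (a single putative site, not
a scored ranking) and continues to `extended_limit` with a non-canonical
flag.

An insertion between the BPS and the acceptor displaces the branch point by
exactly the insertion length; an insertion upstream leaves it unchanged.
The site is *disrupted* when the insertion displaces the BPS **and** leaves
it beyond the canonical maximum: a wildtype BPS already functioning outside
the window (like the 76-nt site) is not itself called disrupted. For the
characterised allele — wildtype offset 76, 238-bp insertion between −15 and
−16 — the mutant offset is 76 + 238 = 314 nt, beyond the >300 bp bound, and
the acceptor AG is untouched (any insertion ≥ 3 nt upstream leaves it so).

# Transcript consequences

The toy two-isoform gene model is built *only* from printed constants and
their arithmetic consequences: the full-length isoform translates to
716 aa and the exon-4-skipped short isoform to 660 aa, so exon 4 is
3 × (716 − 660) = 168 nt; the exon-5 acceptor sits at c.1758 full-length
and c.1590 short; the four RT-PCR amplicons 421/321/253/153 bp imply exon 5
= 421 − 321 = 100 nt and 153 nt of primer-bearing exon sequence. The
remaining codons are synthetic, chosen deterministically (first seed whose
translation satisfies every constraint, asserted at build time). Because
exon 5 is 100 nt, skipping it shifts the frame (100 mod 3 = 1) into a
premature stop inside the final exon — hence never a nonsense-mediated
decay candidate under the 50-nt last-junction rule, consistent with mutant
transcripts surviving in blood. The counts of aberrant and lost residues
are *computed from the synthetic sequence*, not copied from any published
figure: without the real coding sequence those published residue counts
cannot be reconstructed arithmetically, so the package treats them as
outputs of its method, not constants.

Variant naming reproduces the printed descending order
(`c.1758-15_1758-16ins238`); strict 5′→3′ HGVS ordering is available via
`strict_hgvs = TRUE`. In-silico RT-PCR measures the inclusive distance
between primer 5′ ends on the spliced transcript and returns no amplicon
when a primer exon is skipped.

# Screening statistics

Concordance under the recessive model: cases are concordant when
insertion-homozygous, obligate carriers when heterozygous, clear dogs when
heterozygous or homozygous wildtype; dogs of unknown status are excluded
from per-status concordance but *included* in the penetrance denominator
(cases among all insertion homozygotes), mirroring the 22-of-24 arithmetic.
The "clinically free" group is clear dogs plus obligate carriers.
Percentages round half-up to one decimal (56.25 → 56.3; `base::round()`
would banker's-round to 56.2). Allele frequency is
$(2\,\mathrm{hom} + \mathrm{het})/(2N)$. The published cohort-wide allele
frequencies (0.052 and 0.0052) rest on unpublished service-testing counts
and are not recomputable; the operation exists and is tested on panels with
known counts. The pedigree checker flags four violation classes of
recessive, fully-penetrant inheritance and skips ungenotyped members.

# The synthetic-data generators

The generators are first-class, tested code, and their defaults *are* the
study conditions:

* `gen_cohort()` — 18 cases / 10 controls / 1 obligate carrier, 500 SNPs at
  10-kb spacing, an 11-marker haplotype block around the causal locus,
  locus homogeneity 0.65. The homogeneous-case count is the *rounded count*
  `round(0.65 × 18) = 12`, assigned at random — emulating the printed
  12-of-18 configuration exactly rather than binomially, so the
  majority-of-cases regime holds in every replicate. Discordant cases are
  phenocopies; controls and phenocopies carry at most one mutant haplotype
  (15% rate). The background frequency of the disease-linked allele on
  population haplotypes is drawn from U(0.1, 0.4) — a disease haplotype is
  uncommon in the population (the published breed-wide allele frequency is
  ~0.05), and a common background allele would make the planted locus
  unidentifiable by any method. Optional subpopulations shift allele
  frequencies by ±`divergence` to emulate stratification.
* `gen_reads()` — 51-bp reads at Poisson depth (default 100X; the targeted
  data ranged ~102–174X, and 100X keeps simulations inside test budgets
  while preserving every signature), insert longer than the read, TSD
  duplicated on the insertion haplotype, clipping geometry computed
  analytically. Emitting alignments directly, instead of running an
  aligner, is a deliberate design choice: it reproduces exactly the
  split-read/spanning-read/depth-step signatures the caller consumes while
  keeping the package self-contained. No sequencing-error model by default;
  a uniform substitution rate is available for robustness checks.
* `gen_insert()`, `gen_pedigree()`, `gen_gene_model()`,
  `gen_acceptor_intron()` — as described above; the intron fixture's
  background alphabet excludes T outside the planted motif and acceptor, so
  the planted BPS is provably the only match.

All generators are deterministic under their mandatory seed.

**What passing tests do and do not show.** The simulations carry no linkage
disequilibrium decay, no realistic canine LD map, no genotyping error, no
base-quality structure, and phenocopies are unlinked to any second locus.
Passing therefore demonstrates correctness of the algorithms under the
stated statistical structure — shared haplotype blocks, binomial read
sampling, Mendelian transmission — not performance on real BeadChip or
capture data. Thresholds that the source analysis applied visually (clip
clustering, genotyping bands, the exon-proximity window) are declared
defaults here, and results on real data would depend on them.

# Numerical choices and degenerate inputs

* Degenerate 2×2 tables (a zero margin) score chi-square 0, p 1; a zero
  total is an error. Zero-total CMH strata are skipped with a warning.
* Permutation p-values use +1 smoothing; ties count as exceedances
  (conservative).
* `round_half_up()` is used for all reported percentages.
* Missing genotypes: excluded from both numerator and denominator of MAF,
  counted in missingness; "0 0" in the PED dialect; excluded supporting
  evidence nowhere in the MEI caller (a read either supports, spans, or is
  uninformative).
* Empty inputs return empty results where the operation is a filter
  (`filter_markers`, `collect_clip_clusters`) and errors where a statistic
  is undefined (`inflation_factor`, `allele_frequency` on an empty panel).
* Test problem sizes — 500-marker cohorts, 2-kb read loci, 100–200
  replicate calibrations — were chosen as the smallest sizes at which the
  verified properties are statistically meaningful; the suite completes in
  about a minute.

# Known limitations

* The homozygosity scanner assumes markers sorted within chromosome and
  treats chromosomes independently; no recombination-aware fine mapping.
* The MEI caller handles a single insertion per locus cleanly; nested or
  adjacent events resolve by closest-distance pairing and are flagged when
  ambiguous. Discordant mate-pair evidence is accepted but not required.
* The SINE body is positional, not aligned to a repeat library; subfamily
  attribution is out of scope.
* Mixed-model association, phased-haplotype inference, NMD beyond the
  50-nt rule, and quantitative RT-PCR are out of scope.
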