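---
title: "gbsmap: models and methods"
author: "gbsmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gbsmap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`gbsmap` implements a complete two-enzyme genotyping-by-sequencing (GBS)
analysis for a biparental recombinant-inbred-line (RIL) population:
reference-tag construction from genome assemblies, inline-barcode
demultiplexing, unique one-mismatch read mapping, SNP discovery with a
staged filter cascade, proportion-rule genotype calling, genetic-map
construction and QTL interval mapping. A seeded simulator generates every
input the pipeline consumes — parental assemblies, an F11
single-seed-descent population, two-year height phenotypes and barcoded
raw reads — together with complete truth tables, so the whole chain can
be exercised and validated without any external data.

This vignette records the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

# Reference tags

The mapping reference is not a genome but a set of fixed-length (64 bp)
**tags**: the two flanks of every PstI recognition site (CTGCAG). For a
site whose motif starts at 0-based position $p$, the forward tag is
`contig[p+1, p+65)` and the reverse tag is the reverse complement of
`contig[p-59, p+5)`. Both begin with the 5' overhang TGCAG that PstI
leaves, which is also the first thing a barcode-stripped read shows —
this makes tags and reads directly comparable, end to end, with no
alignment gaps. The overhang is *included* in the 64 bp; this convention
is forced by the read side (reads are accepted only if they start with
TGCAG and are then truncated to 64 bp), and tags must live in the same
coordinate system.

A flank is emitted only when it fits inside the contig and contains no
ambiguous base; every suppressed flank produces an exclusion record with
a reason code (`edge`, `ambiguous-base`), so the identity
`tags + exclusions = 2 x sites` holds exactly and is asserted
property-style in the tests. Tags containing N are excluded because a
one-mismatch ungapped mapper cannot use them meaningfully.

Tags from additional assemblies are merged only when their best
full-length match against the primary set has **at least 2
substitutions**. The rationale ties directly to the mapper: reads are
allowed one mismatch, so two reference tags closer than 2 mismatches
would make every read of that region multi-mapped and therefore
discarded. Secondary tags with no primary hit at all are included by
default (`add_no_hit = TRUE`), with a switch to disable, because the
alternative reading ("hit-based criteria only") is also defensible; a
"hit" for this purpose means at most 6 mismatches, i.e. the same 90%
identity bound used in the chloroplast screen.

Chloroplast screening removes tags with an ungapped full-length match to
either strand of a chloroplast genome at >= 90% identity over >= 64 bp —
for 64 bp tags, a Hamming distance of at most 6 at some window. It is
implemented with a pigeonhole chunk prefilter (7 chunks; any match with
<= 6 mismatches preserves at least one chunk exactly) followed by exact
Hamming verification, which is equivalent to the stated thresholds
without an external aligner.

# Demultiplexing

Inline barcodes are 4-8 nt and sit immediately 5' of the TGCAG overhang.
A read is assigned when (i) some barcode matches its 5' end exactly, (ii)
the following bases equal the overhang, and (iii) the barcode-stripped
read contains no N. Rejections are classified `no-barcode`,
`bad-overhang`, `contains-N`, `too-short`, and every input read lands in
exactly one class (a conservation law the tests assert).

Variable-length barcodes are resolved longest-match-first. The loader
rejects any barcode set in which one `barcode + TGCAG` string is a prefix
of another, which is precisely the condition under which
longest-match-first could mis-assign; with a validated set, assignment is
provably unambiguous. No mismatch rescue is attempted ("accurate
barcode" is read strictly).

Quality trimming removes the *maximal trailing run* of bases with Phred
< 20 — not everything after the first low-quality base — then truncates
to 64 bp from the 5' end; shorter reads are discarded. The N filter is
applied to the whole barcode-stripped read before trimming (the
strictest reading); `n_check = "retained"` restricts it to the kept 64
bases instead.

# Read mapping

Mapping is end-to-end, ungapped, over 64 bp on both sides, with
best-stratum semantics: an exact hit wins over any one-mismatch hit, a
read maps only if its best stratum contains exactly one tag, and ties are
never broken — they yield `ambiguous`. No reverse-complement search is
done: both flank orientations are already in the tag set and the
protocol fixes read orientation. Indels are out of scope by construction
(single-substitution tolerance over equal lengths).

The one-mismatch search uses the pigeonhole principle on the two 32 bp
halves: a read with at most one substitution matches at least one half
of its tag exactly. Half-table hash joins produce candidates; an exact
Hamming kernel (C++) verifies them. The tests require exact agreement
with a brute-force Hamming oracle, including duplicate-sequence
ambiguity classes and strata behaviour.

Because every mapped read covers all 64 tag positions, the pileup is
stored compactly: per-sample read counts per tag, population-wide
quality sums per position, and an explicit event list only for
non-reference base observations (at most one per read under the
contract). Per-sample reference depth at any offset is then
`reads(tag, sample) - non-reference events(tag, offset, sample)`, with
no loss of information.

# SNP discovery and the filter cascade

Candidate sites are tag offsets where at least two base classes occur;
the reference allele is the tag base, the alternative is the most
frequent non-reference base population-wide (alphabetical tie-break for
determinism), and a candidate needs more than 3 supporting reads (>= 4).

The **site quality** is our own score, because the original workflow's
external-caller score is not reproducible here: quality =
$-10\log_{10} P(X \ge k)$ with $X \sim \mathrm{Binom}(n, e)$, where $k$
is the alternative-read count, $n$ the site depth and $e$ the error rate
implied by the mean alternative base quality, capped at 3000. It is an
approximation with the same meaning (surprise of the alt reads under
pure sequencing error) and the same threshold semantics (>= 20 by
default, configurable).

The cascade applies, in order: alt-read fraction >= 0.1; base-quality
percentage difference <= 5, formalised as
$|\bar q_{ref} - \bar q_{alt}| / \max(\bar q_{ref}, \bar q_{alt}) \times 100$
(the source formula is unstated; this relative-difference reading is
flagged in the output metadata); site quality >= 20; total coverage >=
5 x population size; heterozygous samples <= 2%; population
alternative/reference read-count ratio >= 0.5 (a segregation-balance
filter — a sample-count interpretation is selectable); dominant-marker
removal, operationalised as *parent-null tags* (either parent with zero
mapped reads on the tag), since null alleles are indistinguishable from
missing data; and removal of sites where a parent's genotype is missing.
Each stage is a pure predicate evaluated on the full record set, so the
final surviving set is order-independent; only the intermediate ledger
counts depend on the published stage order, which is preserved so that
ledgers from a real run can be compared side by side.

# Genotype calling

With $p = ref/(ref+alt)$: hom-ref if $p > 0.8$, hom-alt if $p < 0.2$,
het in between — the boundaries 0.2 and 0.8 call het, because the
homozygous rules are strict inequalities. Provisional homozygotes with
depth < 3 and heterozygotes with depth < 6 are recoded missing. Markers
are kept for mapping only when the parents are homozygous for opposite
alleles; progeny are recoded a/b/h with `a` the parent-A allele. Parent
replicates can be merged by summing depths before calling
(`mergeSampleReplicates`).

# Linkage mapping

Co-segregating markers are collapsed before mapping, keeping the
highest-quality member of each group. "Identical" is operationalised as:
agreement at every progeny called in both, with at least 50% of progeny
shared — an exact-pattern-only mode is available. Markers with more than
20% missing calls are dropped (strict inequality).

Pair statistics treat heterozygous calls as missing: at F11 the expected
residual heterozygosity is $(1/2)^{10} \approx 0.001$, so the
information lost is negligible and a het-aware RIL likelihood is not
warranted. For a pair with $n_{par}$ parental and $n_{rec}$ recombinant
informative progeny, $\hat R = n_{rec}/n$ and the independence LOD is
$n_{par}\log_{10} 2(1-\hat R) + n_{rec}\log_{10} 2\hat R$ (with
$\hat R$ capped at 0.5). Groups are single-linkage components at LOD >=
6; singletons are reported as isolated.

Ordering minimises the sum of adjacent recombination fractions with a
seeded multi-start heuristic: greedy chain extension from several starts
followed by 2-opt segment-reversal polishing. On groups of up to 8
markers the tests require the heuristic to reach the exhaustive optimum;
at study scale the recovered order is required to correlate with truth
at |Spearman rho| >= 0.99 per chromosome. The original tool's
maximum-likelihood ordering and proprietary distance are not reproduced;
map lengths are comparable in scale, not bit-identical.

Distances: observed RIL fractions are first corrected for repeated
selfing with the Haldane-Waddington inverse $r = R/(2(1-R))$, then
mapped with Haldane's function $d = -50\ln(1-2r)$ (Kosambi selectable).
Adjacent fractions >= 0.5 are capped at 50 cM with a warning.

"Poor fit to the neighbouring markers" is not specified by the original
workflow; we use a double-crossover heuristic — a marker whose call
differs from two agreeing immediate neighbours in more than 3 progeny is
removed and the group re-ordered once — and label it as such in the map
ledger. The per-group ledger accounts for every input marker
(mapped + co-segregating + missing-filtered + isolated + poor-fit).

# QTL scanning

Genotype probabilities on a 1 cM grid come from the nearest informative
flanking markers, with distances converted to RIL-scale recombination
probabilities (Haldane, then Haldane-Waddington accumulation). At a
marker, called lines are 0/1; lines with no informative marker in a
group sit at 0.5.

The scan is Haley-Knott regression of the trait on expected parent-B
dosage: $LOD = (n/2)\log_{10}(RSS_0/RSS_1)$, variance explained
$= 100(1-RSS_1/RSS_0)$, and the effect is the fitted b-minus-a
class-mean difference with its standard error. At RIL levels of
genotype information the difference from mixture-model interval mapping
is negligible, which is why the simpler regression stands in. Degenerate
zero-residual fits are flagged and capped rather than reported as
infinite.

Permutation thresholds shuffle the trait across whole lines (preserving
the marker correlation structure), record the genome-wide maximum LOD of
each of 1,000 seeded permutations, and return the 95th percentile. The
seed is mandatory.

The cofactor-adjusted (restricted-MQM-style) scan includes user-supplied
cofactor markers as covariates, excluding any cofactor within 10 cM of
the test position (the window is configurable; the original cofactor
selection procedure is not described, so cofactors are explicit
arguments here). The joint model fits all selected loci additively and
F-tests all pairwise interactions against the additive fit. Marker x
binary-trait association uses the 2 x 2 Pearson chi-square without
continuity correction (the use case is ranking); zero-margin tables
return 0 with a flag, and perfect co-segregation is flagged.

# The simulator: what it emulates, and what it does not

The generator's defaults are the study conditions of the motivating
design: 7 chromosomes totalling 1,200 cM; ~1,300 polymorphic marker
tags; 138 F11 lines (10 selfing meioses past the F1, single seed each
generation, Haldane no-interference meiosis); two-enzyme PstI/MseI
fragments size-selected to 200-500 bp; 100 bp single-end reads with
4-8 nt inline barcodes; per-sample read counts log-normal between 5,204
and 65,549 — the published 0.5-6.5 M range scaled down ~100x to desk
scale (`depth_scale = 100` restores full scale); parents sequenced
deepest, emulating their repeated representation across libraries.

Height is controlled by three loci with the published per-year effect
sizes: a major 5H-style QTL at 29.7 cM (27.5 / 24.8 cm), a 3H-style QTL
at 51.6 cM (9.7 / 8.9 cm), and a 2H-style row-type locus at 80.5 cM
(-10.1 / -6.8 cm for the six-rowed class, which is the parent-B
homozygote; the allele acts recessively, so heterozygotes are
two-rowed). Two co-segregating markers are planted at the row-type
position (zero recombination), and one marker at each QTL position.
Residual variance uses a line deviation shared across years (SD 7.9 cm)
plus independent year noise (SD 5.5 cm); these two values were
calibrated analytically — from the closed-form variance decomposition,
not from test outcomes — so that the major QTL explains ~57%/55% of the
variance per year (inside the 55-62% band) and the between-year
correlation is ~0.89.

A marker-free region is planted on chromosome 5 at 31-47 cM, adjacent
to the major QTL, emulating the markerless gap near the major-QTL peak.
Its width is a design choice: at 16 cM the independence LOD across the
gap is ~10, so chromosome 5 remains one linkage group (as in the study
design, which recovered seven groups); a substantially wider gap would
split the chromosome at the LOD-6 grouping threshold and contradict the
conditions being emulated.

Sequence-level realism is deliberately limited: fillers between
restriction-site units are random DNA *scrubbed* of both recognition
motifs, with MseI sites planted explicitly at 210-430 bp so that every
fragment falls inside the selection window by construction. Base
qualities sit at a plateau of $-10\log_{10}(\texttt{error\_rate})$
(Q27 at the default 0.002) with stochastic low-quality 3' tails;
substitution errors are planted per base at the rate implied by that
base's quality, so qualities and errors are mutually consistent.
`error_rate = 0` disables substitution errors entirely. Dominant
(presence/absence) tags are created by destroying the PstI site in
parent B for 5% of sites — always parent B, because a site destroyed in
the reference parent leaves no reference tag and would be invisible to
every stage.

What the simulator does **not** model — and what passing tests therefore
do not show about real data: real barley sequence composition and
repeat content (tags here are unique by construction, so ambiguity rates
are far lower than in a 5 Gb genome); methylation-dependent site
accessibility; PCR duplicates; indels and structural variation; quality
miscalibration; crossover interference (Haldane only). Counts that
depend on the real assemblies and reads (mapping rates, survivor-chain
sizes) are therefore validated as bookkeeping identities on constructed
inputs, not as re-derived biology.

# Problem sizes used by the test-suite and acceptance checks

These are the package's chosen validation scales. Bookkeeping identities
run at the published magnitudes (343,854 sites; 633,331 + 71,519 +
97,764 - 568 = 802,046 tags; 1,949 -> 1,391 marker filtering; 1,968 ->
1,949 parent screening), since they are exact regardless of content.
Read-level end-to-end runs use 60-line populations with ~60 marker tags
and ~2,000 reads per sample, where every conservation law and recovery
property is checkable in seconds; 60 lines (not fewer) keeps a single
residual-heterozygous line below the 2% het filter, mirroring the
full-size behaviour. Genotype-level checks (map recovery, permutation
thresholds, QTL recovery over 50 phenotype replicates) run at the full
study scale: 7 chromosomes, ~1,300 markers, 138 lines, 1,000
permutations.

# Known limitations

* The mapper is exact-Hamming and ungapped; reads from indel-bearing
  haplotypes are unmapped rather than clipped.
* The site-quality score is a binomial-tail approximation, not a
  genotype-likelihood model; its absolute scale differs from external
  callers even though its threshold plays the same role.
* Marker ordering is a heuristic; optimality is only guaranteed (and
  only asserted) for small groups.
* The rMQM cofactor set is user-specified, not automatically selected.
* Map lengths depend on the chosen map function and the 50 cM gap cap;
  they are comparable across runs of this package, not across tools.
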