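---
title: "Homologue-specific primer design for gene cloning in polyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homologue-specific primer design for gene cloning in polyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Polyploid crops such as bread wheat carry two or three near-identical
copies of most genes, one per subgenome (homeologues), typically 90--97%
identical to each other, plus occasional paralogues. A PCR primer pair
designed naively against one copy will amplify several loci at once, and a
Sanger trace of the mixed product is unreadable. The standard remedy is
*allele-specific priming*: place the 3'-terminal base of each primer on a
position where the target copy differs from every off-target copy. A
single mismatch under the 3' terminus reduces Taq extension efficiency by
up to two orders of magnitude, so only the target copy amplifies
efficiently.

`homeoprimer` automates the whole design for cloning a *complete* gene:

1. locate the gene and its close homologues in the genome assembly,
2. extract each locus with flanking DNA,
3. align the extractions and classify every alignment column,
4. anchor primer candidates on discriminating columns and score them,
5. choose a minimum-penalty set of overlapping products that tiles the
   entire input sequence,
6. add internal primers so Sanger reads cover long products, and
7. verify the design by simulated PCR against every extracted locus.

```{r}
library(homeoprimer)
fx <- generate_fixture(fixture_spec(seed = 1))          # synthetic tetraploid
run <- design_primers(fx$input, genomes = fx$config, prefix = "T.300")
run
write_primer_csv(run$solution, "primers.csv", prefix = "T.300")
```

## Locating the target and its homologues

A local similarity search reports a locus as fragments (HSPs), so
fragments with the same query and subject are chained into **hit groups**
whenever consecutive subject intervals lie within `max_group_gap`
(default 1000) bases; chaining is per strand, since a mixed-strand group
would make extraction ill-defined, and the gap is measured
boundary-to-boundary. Groups are ranked by **total** bitscore -- the
genomic copy of the input should dominate on both identity and length --
and the top group is taken as the target locus. Up to
`n_homologue_groups` (default 3) further groups are kept as homologues
provided their **mean** bitscore exceeds `bitscore_floor` (default 200);
the mean is deliberately used for the floor (a group of many weak
fragments should not qualify) and the total for ranking. Groups failing
the floor are discarded with a recorded reason, and later qualifying
groups may still fill the quota.

Each selected group is widened by `start_buffer`/`end_buffer` (default
1000 bases each) so primers can sit outside the gene proper, clamped to
the chromosome (clamping is flagged, not an error -- buffers routinely
overrun scaffold ends), and minus-strand groups are reverse-complemented
with the buffers swapped so every extraction reads in query orientation.
Internally all coordinates are 0-based half-open on the forward strand;
1-based inclusive coordinates appear only at the I/O edges (tabular hits
in, oligo names out), so there is a single conversion point.

Hits can come from a precomputed 12-column tabular report, or from the
package's built-in search: exact 11-mer seeding, clustering of seed
positions along the subject (gap <= 1000), and a local affine alignment of
the query against each cluster window. Scores map to bitscores via fixed
Karlin--Altschul-style constants (lambda = 0.625, K = 0.41, match +2,
mismatch -3, gap open 5, extend 2); fidelity to any external tool's
scores is a non-goal -- only the ranking behaviour matters, and both input
routes produce identical downstream selections on the same loci.

If genome assemblies for more than one variety of the species are
configured, the single best locus from each additional genome is also
extracted (no bitscore floor): a same-locus copy from another variety
makes SNP identification more reliable by exposing *varietal* SNPs, which
must never anchor a primer (see below).

## The alignment and SNP classification

The multiple alignment is a centre-star progressive alignment with the
flanked target as centre: every other sequence is aligned to the target
with a local affine-gap alignment and the target-relative gap patterns
are merged (insertions from different rows sharing a slot are
left-aligned within it -- the classic centre-star simplification). The
pairwise scoring is match +5 / mismatch -4; the star legs use gap open
15 / extend 2.5. The stiffer gap costs matter: with a very cheap
extension a local alignment will happily chain a kilobase of
non-homologous flank through long gaps, aligning only chance matches, and
such junk regions then corrupt SNP evidence in both directions. The
generic `pairwise_align()` helper defaults to open 10 / extend 0.5 and
both values are caller-settable. External alignment backends (`muscle`,
`mafft`, `dialign`) are thin adapters that require the binary on the
PATH and fail with a clear message otherwise; the internal backend is the
default and needs no external software.

`scan_snps()` classifies every column whose target base is A/C/G/T:

* **discriminating** -- the target base differs from the base of *every*
  homologue row with evidence at that column. One matching homologue
  spoils the anchor: the polymerase would extend it.
* **evidence** -- a homologue row only testifies where it is credibly
  homologous: within its aligned extent *and* inside a sliding window
  (61 pair-columns, both-gap columns excluded) of at least 50% identity
  to the target. A partial homologue therefore neither confirms nor
  denies columns outside its homologous region -- crucial, because the
  off-target copy can still amplify elsewhere, and because random flank
  alignment would otherwise veto genuine anchors by chance matches.
  Columns with no evidence at all are not discriminating.
* **gap_discriminated** -- an internal gap in a homologue counts as a
  difference, but indel-anchored 3' ends behave less predictably, so
  these columns carry a penalty bonus (`w_gap`, default 2.0) and are only
  used when cleaner anchors are unavailable.
* any homologue showing **N** disables the column;
* **varietal_conflict** -- a same-locus row from another variety differs
  from the target. Varietal SNPs are never used as anchors: the variety
  actually being cloned may not carry them, in which case the "specific"
  primer would fail on its own template.

## Primer scoring

For every usable anchor and every length in 18--27, one forward candidate
ends (3') at the anchor and one reverse candidate's 3' end sits at the
anchor on the reverse strand. Candidates are scored with:

* **melting temperature** -- unified nearest-neighbour thermodynamics
  (per-stack enthalpies/entropies, terminal initiation terms, entropic
  monovalent-salt correction, `Tm = 1000 dH / (dS + R ln(C/4)) - 273.15`)
  at 50 mM monovalent cations and 500 nM primer;
* **self-annealing** (`self_any`) -- the best weighted complementary run
  over all ungapped antiparallel self-alignments (G/C pairs weigh 2,
  A/T pairs 1), with `self_end` restricted to runs involving a
  3'-terminal base;
* **hairpin** -- the longest intramolecular stem over all fold points
  with a loop of at least 3 bases.

The single-primer penalty is the weighted sum of deviations from the
optima (length 20, Tm 60 degC, GC 30--70%) plus the complementarity
terms and the gap-anchor bonus; the pair penalty adds a Tm-difference
term and a cross-dimer term. All weights are `design_parameters()`
fields. The published length/Tm/GC conventions of widely used primer
scorers are reproduced qualitatively, not numerically; the package never
shells out to one.

## Tiling the input with overlapping products

Per anchor and direction, the best-penalty candidate enters pairing (the
full length-by-length combination space per SNP pair is quadratic and
adds only the small Tm-difference/cross-dimer terms to the choice; the
complete candidate table is still reported). All forward/reverse
combinations with product size in `[product_min, product_max]` (default
500--2000) form the node set of a DAG; an edge admits product B after
product A when B starts after A, ends after A, and overlaps it by at
least `min_overlap` (default 50 bases -- enough for Sanger reads to
bridge junctions; the requirement is for *overlapping* products, the
amount is this package's choice). The minimum-total-penalty path whose
first product starts at or before the input region and whose last ends at
or after it is found exactly by shortest-path over the DAG; ties break on
the deterministic `(product_start, product_size, forward sequence)`
order, so a fixed input always yields byte-identical output. Products may
extend into the flanks -- the covering constraint applies to the bare
input region, not the flanked sequence. When no full cover exists a
greedy rightmost-reach partial cover is returned with the uncovered
intervals listed and a distinct exit code (2) from the command line.

### Sanger sequencing primers

A Sanger read is nominally `sanger_read = 700` bases; the final
`sanger_trim = 100` bases are discounted as low-quality, leaving 600
trusted bases per read. A product of size L therefore needs
`ceiling(L / 600) - 1` internal forward primers, placed near the
multiples of 600 from the product start (each the best unanchored
forward candidate within +/-50 bases; the window is widened once if
empty). This keeps consecutive read starts within one nominal read
length and makes the trusted parts of consecutive reads overlap. Internal
primers are forward-only and need no SNP anchor -- the amplicon is
already allele-pure. Under this model products of 805, 1234, 1331 and
1412 bases receive 1, 2, 2 and 2 internal primers respectively; a naive
`ceiling(L/700) - 1` rule would assign only one to the 1234- and
1331-base products, which does not match practice.

Oligo names follow `{prefix}.{start}-{end}.{F|R}` and
`{prefix}.{start}-{end}.split{k}.F`, with the embedded coordinates
behaving as a half-open interval so the product size is exactly
`end - start`.

## In-silico validation

`simulate_pcr()` is a deliberately binary model of the 3'-mismatch
effect: a site supports extension only when the final `terminal_exact`
(default 1) 3' bases match the template exactly, internal mismatches are
tolerated up to `max_internal_mm` (default 3, summed over the pair), and
products are capped at `max_product` (default 10 kb). Every binding site
of either primer on either strand within the mismatch budget is found
exhaustively, and every convergent site pair is reported. No attempt is
made to model amplification efficiency quantitatively -- the reported
suppression (up to ~100-fold) justifies a threshold model, and
`terminal_exact` can be raised to 2--3 for a stricter one. The
specificity report marks a pair PASS exactly when the target locus
amplifies and no homologue does.

## The synthetic polyploid fixtures

`generate_fixture()` builds the test world: an ancestral locus (gene plus
`flank_homology` = 1000 homologous bases each side) evolved along a star
phylogeny. The target copy carries its own branch substitutions --
`target_divergence` (default 0.5) times the smallest homeologue
divergence -- and each homeologue carries private substitutions at
disjoint positions, so pairwise target--homeologue identities equal the
requested values exactly in expectation (defaults 93, 93 and 80%,
GC 49%, with the 80% copy partial: homologous from 325 bases into the
gene to 10 bases past it). The target-branch sites are the planted,
recorded ground truth of discriminating columns. This branch structure is
what real subgenomes look like and is what makes homologue-specific
cloning feasible at all: if the target carried no private substitutions,
discriminating sites would only arise where *all* homeologues happened to
mutate the same position (a fraction of a percent of sites), and no
covered tiling could exist. Homologous flanks are likewise essential --
designs routinely place primers hundreds of bases into the flank, which
requires homologue evidence there.

A second-variety genome is the target locus with `varietal_snp_count`
(default 10) recorded substitutions. Scaffolds are random DNA at the
target GC with the loci embedded at recorded offsets; a truth table
(kind, region/gene/chromosome coordinates, ancestral and derived base)
is written as TSV. One seed governs everything and the caller's RNG
stream is restored, so fixtures are byte-identical per seed.

What the fixtures do *not* emulate: repeats and low-complexity sequence,
segmental duplications, real indel length spectra (indels are optional,
single-base, and off by default), sequencing gaps (N runs), and
assembly artefacts. Passing the suite therefore demonstrates the
pipeline's logic, not robustness to every pathology of a real assembly;
on real genomes the external-alignment backends and precomputed search
reports are the recommended fidelity path.

## Numerical and degenerate-input choices

* Out-of-range genome slices clamp and set a flag; empty intervals return
  an empty string.
* Hit tables may be empty (empty search report file -> empty table, not
  an error); an empty group list is an error only at selection time.
* A single-sequence alignment is valid (trivially gapless) and a
  no-homologue run warns and passes specificity trivially.
* Anchors too close to a sequence end simply generate candidates in one
  direction only; candidates containing N are dropped.
* All optimisation tie-breaks are lexicographic and documented above, so
  every stage is deterministic given its input.

## Problem sizes

The test suite runs entirely on generated data: unit fixtures use a
1.2 kb gene in 12 kb scaffolds (a full pipeline run takes ~15 s), and
the end-to-end acceptance checks use the 2.4 kb / 20 kb-scaffold
tetraploid described above (~1 min). Oracle comparisons use exhaustive
or brute-force re-derivations on deliberately small instances: strings of
at most 12 bases for the alignment DP, 18--27-mers for complementarity
enumeration, 50-hit instances for grouping, and at most ~12 products for
the tiling subset search.

## Known limitations

* The centre-star alignment left-aligns co-located insertions from
  different rows and never refines them; for heavily gapped loci an
  external aligner backend will give cleaner columns.
* The internal search is designed for assemblies that fit comfortably in
  memory per chromosome (fixtures are <= 10 Mb); genome-scale scans
  should import an external tabular report instead.
* The binary PCR model ignores primer--dimer competition, thermodynamic
  mismatch context (a 3' G:T wobble is treated like any mismatch) and
  product-length efficiency decay.
* Tm is computed for perfect duplexes only; a candidate binding a
  homologue with internal mismatches is judged by mismatch counts, not a
  duplex free-energy model.
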