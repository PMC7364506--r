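# homeoprimer

Homologue-specific primer design for cloning complete genes in polyploids.

## The problem

Polyploid crops (bread wheat being the canonical case) carry near-identical
copies of most genes on each subgenome. These homeologues are typically
90–97% identical to the target copy, so an ordinary primer pair amplifies
several loci at once and the Sanger trace of the mixed product is
unreadable. The established remedy is allele-specific priming: a primer
whose 3′-terminal base sits on a position where the target differs from
*every* off-target copy. Because a 3′-terminal mismatch cripples Taq
extension (up to ~100-fold), only the target locus amplifies.

`homeoprimer` automates the full design for cloning a complete gene from a
variety with no genome sequence of its own:

1. **Locate** the input gene and its close homologues in a genome assembly
   (built-in seed-and-extend search, or an imported 12-column tabular
   report). Local-alignment fragments are chained into hit groups (gap
   ≤ 1000 bases), ranked by total bitscore; the best group is the target
   locus and the next ≤ 3 groups with mean bitscore > 200 are homologues.
2. **Extract** each locus with 1000-base flank buffers (faidx random
   access; minus-strand loci reverse-complemented into query orientation).
3. **Align** the extractions (centre-star around the target, affine-gap
   local legs; or shell out to muscle/mafft/dialign) and classify every
   column: *discriminating* iff the target base differs from every
   homologue with credible evidence there, with gap-anchored columns
   deprioritised, N disabling a column, and differences against a
   second-variety copy flagged as varietal and banned from anchoring.
4. **Score** SNP-anchored candidates (lengths 18–27) with
   nearest-neighbour melting temperatures, GC, self-annealing, 3′-end and
   hairpin scores, and a weighted penalty (optimum: 20-mer, 60 °C).
5. **Tile** the input with overlapping products (500–2000 bases, overlap
   ≥ 50) by exact shortest-path optimisation of total pair penalty over a
   DAG of admissible product successions, then place internal forward
   primers so trusted Sanger reads (700-base reads, last 100 bases
   discounted) cover every product: `ceiling(size/600) − 1` per product.
6. **Validate** by in-silico PCR: exhaustive binding-site scan, a site
   extends only with an exact 3′-terminal match and ≤ 3 internal
   mismatches; a pair passes when exactly the target amplifies.

A synthetic tetraploid fixture generator (`generate_fixture()`) with a
recorded mutation truth table makes the whole pipeline testable without
any downloads.

## Worked example

```r
library(homeoprimer)

# a synthetic tetraploid: 2.4 kb gene on chr5A, homeologues on 4B/4D at 93%
# identity, a partial 80% homologue on 5B (homology starting 325 bases into
# the gene), 1 kb homologous flanks, and a second variety with 10 varietal SNPs
fx  <- generate_fixture(fixture_spec(seed = 1))
run <- design_primers(fx$input, genomes = fx$config, prefix = "T.300")
run
```

```
<primer_design> input 'gene' (2400 bases)
  homologues: 3  additional varieties: 1  discarded groups: 0
  usable SNP anchors: 152
<tiling_solution> 2 product(s), input fully covered, total penalty 10.03
  [1] 574-2283 (1709 bases, penalty 5.43)
  [2] 1812-3709 (1897 bases, penalty 4.61)
  + 5 internal sequencing primer(s)
<specificity_report> 2 pair(s): all PASS
  574-2283: PASS
  1812-3709: PASS
```

The gene occupies positions 1000–3400 of the flanked target; the two
products start in the 5′ flank (574) and end in the 3′ flank (3709),
overlap by 471 bases, and every primer's 3′ base sits on a SNP that
separates the target from all three homeologues — the in-silico PCR
confirms that each pair amplifies the target locus and none of the
homeologues. `write_primer_csv(run$solution, "primers.csv", prefix =
"T.300")` emits one row per oligo:

```
      oligo_name        sequence_5to3   type product_size tm_celsius
T.300.574-2283.F CGATCGTCGAGTAGCGGACA    PCR         1709      59.21
T.300.574-2283.R AGCGTCGGATTCGGCGTATA    PCR         1709      58.91
...
T.300.574-2283.split2.F AGAACCAGTCCGTAAGCGGC Sanger    1709      59.88
```

Names encode the product as a half-open interval, so the size is
`end − start` (574–2283 → 1709 bases); `splitk.F` primers are the internal
forward primers for Sanger sequencing, spaced so consecutive trusted reads
overlap. The 1709- and 1897-base products get 2 and 3 of them.

## Command line

```sh
inst/cli/homeoprimer --input gene.fa --config genomes.yaml \
    -s 1000 -e 1000 --min-product 500 --max-product 2000 \
    --prefix T.300 --out design/
```

`genomes.yaml` lists the assemblies (see `inst/extdata/example_config.yaml`);
`--guided` stops after the alignment so rows can be curated and the run
resumed with `--alignment`; `--hits` imports a precomputed tabular report.
Exit codes: 0 covered, 2 partial cover, 1 error. Outputs: `primers.csv`,
`alignment.fasta`/`.aln`, `candidates.csv`, `specificity.csv`,
`run_report.txt`.

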