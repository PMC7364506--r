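# Genome configuration for the primer-design pipeline.
# Exactly one genome must be marked primary: the target locus, its
# homologues and the flanking sequence are taken from it. Each additional
# genome should be another variety of the same species; one same-locus
# sequence is extracted from each so that varietal SNPs can be detected
# and excluded from primer anchoring.
genomes:
  - label: chinese_spring        # variety the assembly comes from
    fasta: genomes/iwgsc_refseq.fa   # relative paths resolve against this file
    primary: true
  - label: paragon
    fasta: genomes/paragon.fa
    primary: false

# optional overrides of design_parameters() defaults
params:
  product_min: 500
  product_max: 2000
  min_overlap: 50
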