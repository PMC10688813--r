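# Template run config for an 8-bacterial-species mock community
# (ZymoBIOMICS D6300-style standard). mockqc ships NO vendor data:
# download the vendor's full-length 16S reference FASTA and expected
# percentages yourself and point the paths below at them. Values here are
# placeholders. CLI flags override config entries.
#
# Usage: mockqc check --config this_file.yaml --out-dir results/
asv-table: path/to/asv_table.tsv          # TSV, first column 'asv_sequence'
reference: path/to/vendor_16S.fasta       # full-length 16S of expected members
species-map: path/to/species_map.tsv      # record_id<TAB>species
theoretical: path/to/theoretical.tsv      # species<TAB>percent, sums to 100
kmer-size: 8
bootstraps: 100
subsample-fraction: 0.125
confidence-threshold: 0.60
seed: 0
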