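# GRCh37 amylase locus definitions.
# Region strings are samtools-style: 1-based, both ends inclusive.
# AMY1: three near-identical ~20-kb paralogous units; reads are summed over
# all three and normalised by one unit length (20 kb).  No MAPQ filter: the
# repeat structure depresses local mapping quality.
# AMY2A / AMY2B: single-interval targets, MAPQ >= 20.
genome: GRCh37
loci:
  AMY1:
    unit_length: 20000
    mapq_min: 0
    target:
      - "chr1:104190000-104210000"
      - "chr1:104227213-104247214"
      - "chr1:104284138-104304150"
    reference:
      - "chr1:104059996-104070000"
      - "chr1:104460001-104469995"
  AMY2A:
    unit_length: 8240
    mapq_min: 20
    target:
      - "chr1:104153700-104161939"
    reference:
      - "chr1:104045000-104085000"
  AMY2B:
    unit_length: 20666
    mapq_min: 20
    target:
      - "chr1:104114335-104135000"
    reference:
      - "chr1:104000000-104100000"
      - "chr1:104304000-104500000"
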