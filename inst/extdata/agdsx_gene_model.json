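{
  "gene_id": "AGAP004050",
  "chrom": "2R",
  "strand": "-",
  "span": [48703664, 48788460],
  "cds": [[48713000, 48784999]],
  "cds_note": "Approximate coding-region bounds: exact UTR/CDS switch points between splice windows are not annotated here; the bounds reproduce the coding status of every base inside the 22-nt splice windows (coding from within exon 2 through the start of exon 5 on the female transcript).",
  "transcripts": [
    {
      "id": "AgdsxF",
      "sex_label": "female",
      "exons": [
        [48787046, 48788460],
        [48784185, 48785629],
        [48747693, 48747737],
        [48715161, 48715295],
        [48712957, 48714648],
        [48711528, 48712794],
        [48703664, 48706331]
      ]
    },
    {
      "id": "AgdsxM",
      "sex_label": "male",
      "exons": [
        [48787046, 48788460],
        [48784185, 48785629],
        [48747693, 48747737],
        [48715161, 48715295],
        [48711528, 48712794],
        [48703664, 48706331]
      ]
    }
  ]
}
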