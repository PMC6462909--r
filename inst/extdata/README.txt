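ssc_mirna_modules.tsv
  Transcription of a published systemic-sclerosis worked example: the 26
  miRNAs annotated as targets of the lncRNA ncRNA00201 (HNRNPU-AS1) that
  passed the prioritization filter (>= 7 modulated target genes, >= 2 PPI
  network modules hit). Columns: miRNA identifier; printed count of modulated
  target genes in the SSc transcriptome; module -> gene assignments encoded
  as "M1:GENE|GENE;M2:GENE". Values transcribed verbatim from the printed
  table; no computation was applied.
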