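mirna_id	n_deg_targets	module_genes
hsa-miR-30e-5p	22	M1:UBE2F|SOCS3|UBE2J1;M2:GNAI2
hsa-miR-206	20	M2:CXCL11;M5:GCH1
hsa-miR-30b-5p	20	M1:UBE2F|SOCS3|UBE2J1;M2:GNAI2
hsa-miR-30c-5p	20	M1:UBE2F|SOCS3|UBE2J1;M2:GNAI2
hsa-miR-9-5p	20	M2:CXCL11;M5:GCH1
hsa-miR-30a-5p	19	M1:UBE2F|SOCS3|UBE2J1;M2:GNAI2
hsa-miR-30d-5p	19	M1:UBE2F|SOCS3|UBE2J1;M2:GNAI2
hsa-miR-613	19	M2:CXCL11;M5:GCH1
hsa-miR-302c-3p	17	M1:SOCS3|IRF9;M5:GUCY1A3
hsa-miR-302e	13	M1:IRF9;M5:GUCY1A3
hsa-miR-372-3p	12	M1:IRF9;M5:GUCY1A3
hsa-miR-302a-3p	11	M1:IRF9;M5:GUCY1A3
hsa-miR-302b-3p	11	M1:IRF9;M5:GUCY1A3
hsa-miR-302d-3p	11	M1:IRF9;M5:GUCY1A3
hsa-miR-31-5p	11	M3:KDELR2;M5:PAX5|SPARC|GCH1
hsa-miR-520a-3p	11	M1:IRF9;M5:GUCY1A3
hsa-miR-520b	11	M1:IRF9;M5:GUCY1A3
hsa-miR-520c-3p	11	M1:IRF9;M5:GUCY1A3
hsa-miR-520d-3p	11	M1:IRF9;M5:GUCY1A3
hsa-miR-520e	11	M1:IRF9;M5:GUCY1A3
hsa-miR-181d-5p	10	M1:CBLB;M5:PAX5|BCL2;M4:AP1S3
hsa-miR-181a-5p	8	M1:CBLB;M5:BCL2;M4:AP1S3
hsa-miR-181b-5p	8	M1:CBLB;M5:BCL2;M4:AP1S3
hsa-miR-181c-5p	8	M1:CBLB;M5:BCL2;M4:AP1S3
hsa-miR-211-5p	7	M5:SPARC|BCL2;M6:PSME1
hsa-miR-204-5p	7	M5:SPARC|BCL2;M6:PSME1
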