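# 13 established late-stage AMD risk variants at 8 gene loci.
# control_freq / case_freq: risk-allele frequencies in 796 controls / 986 cases;
# or_per_allele: single-SNP additive logistic odds ratio per risk allele;
# ld_r2_with_first: published r^2 with the first SNP of the same locus group.
snps:
  - snp_id: rs1061170
    gene_label: CFH
    locus_group: CFH
    risk_allele: C
    other_allele: T
    control_freq: 0.365
    case_freq: 0.600
    or_per_allele: 2.74
  - snp_id: rs800292
    gene_label: CFH
    locus_group: CFH
    risk_allele: G
    other_allele: A
    control_freq: 0.761
    case_freq: 0.888
    or_per_allele: 2.43
    ld_r2_with_first: 0.150
  - snp_id: rs6677604
    gene_label: CFH
    locus_group: CFH
    risk_allele: G
    other_allele: A
    control_freq: 0.777
    case_freq: 0.884
    or_per_allele: 2.19
    ld_r2_with_first: 0.203
  - snp_id: rs10490924
    gene_label: ARMS2
    locus_group: ARMS2
    risk_allele: T
    other_allele: G
    control_freq: 0.189
    case_freq: 0.441
    or_per_allele: 3.13
  - snp_id: rs4151667
    gene_label: CFB
    locus_group: CFB
    risk_allele: T
    other_allele: A
    control_freq: 0.951
    case_freq: 0.982
    or_per_allele: 2.82
  - snp_id: rs438999
    gene_label: CFB
    locus_group: CFB
    risk_allele: T
    other_allele: C
    control_freq: 0.915
    case_freq: 0.962
    or_per_allele: 2.31
    ld_r2_with_first: 0.01
  - snp_id: rs2230199
    gene_label: C3
    locus_group: C3
    risk_allele: C
    other_allele: G
    control_freq: 0.175
    case_freq: 0.245
    or_per_allele: 1.52
  - snp_id: rs7412
    gene_label: APOE
    locus_group: APOE
    risk_allele: T
    other_allele: C
    control_freq: 0.079
    case_freq: 0.107
    or_per_allele: 1.41
  - snp_id: rs429358
    gene_label: APOE
    locus_group: APOE
    risk_allele: T
    other_allele: C
    control_freq: 0.881
    case_freq: 0.908
    or_per_allele: 1.35
    ld_r2_with_first: 0.783
  - snp_id: rs2285714
    gene_label: PLA2G12A
    locus_group: PLA2G12A
    risk_allele: T
    other_allele: C
    control_freq: 0.409
    case_freq: 0.443
    or_per_allele: 1.14
  - snp_id: rs493258
    gene_label: LIPC
    locus_group: LIPC
    risk_allele: C
    other_allele: T
    control_freq: 0.538
    case_freq: 0.580
    or_per_allele: 1.18
  - snp_id: rs10468017
    gene_label: LIPC
    locus_group: LIPC
    risk_allele: C
    other_allele: T
    control_freq: 0.707
    case_freq: 0.751
    or_per_allele: 1.26
    ld_r2_with_first: 0.367
  - snp_id: rs9621532
    gene_label: TIMP3
    locus_group: TIMP3
    risk_allele: A
    other_allele: C
    control_freq: 0.96
    case_freq: 0.974
    or_per_allele: 1.58
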