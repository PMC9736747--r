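# UMLS relationship attributes (RELA) retained when extracting horizontal
# disease relations, grouped into the two relation categories used by the
# integrated graph model. Edit these lists to analyse other diseases.
biorel:
  - gene_associated_with_disease
  - gene_involved_in_pathogenesis_of_disease
  - gene_mapped_to_disease
  - gene_product_malfunction_associated_with_disease
  - gene_product_is_biomarker_of
  - may_be_cytogenetic_abnormality_of_disease
  - may_be_molecular_abnormality_of_disease
medrel:
  - may_treat
  - regimen_has_accepted_use_for_disease
  - has_associated_finding
  - associated_finding_of
  - associated_disease
  - is_finding_of_disease
  - related_to
  - clinically_associated_with
  - co-occurs_with
  - may_be_associated_disease_of_disease
  - may_be_finding_of_disease
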