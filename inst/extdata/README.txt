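candidate_targets.csv
  Published summary table of 32 candidate p53 pathway inhibitor genes
  from a genome-wide siRNA reporter screen on A549 NSCLC cells:
  gene symbol, Entrez gene ID, average robust Z-score over the three
  primary replicate screens, fold induction of p53 reporter activity
  in the pooled-siRNA confirmation screen, and the number of siRNAs
  (out of four tested) that consistently induced at least a twofold
  increase in p53 activity across independent deconvolution
  experiments. Used to check the pool/deconvolution confirmation
  rules against printed counts.
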