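# Demo configuration for run_pipeline(): a small synthetic study that runs
# in a few seconds. Section defaults mirror the full-size study design
# (10 batches x 3 patients, 0.8/1.2 fold cuts, Tanimoto > 0.8).
seed: 1
simulate:
  itraq:
    n_proteins: 80
    frac_up: 0.1
    frac_down: 0.1
    up_fold: 2.0
    down_fold: 0.5
    noise_cv: 0.2
  compounds:
    n_compounds: 40
    fp_length: 128
    n_similar: 20
  network:
    n_targets: 60
    n_disease_targets: 40
    n_overlap: 12
    n_pathways: 10
    planted_pathway_size: 10
quant:
  thresholds:
    up: 1.2
    down: 0.8
    alpha: 0.05
    min_peptides: 2
    min_unused_score: 2.0
screen:
  tanimoto_threshold: 0.8
network:
  hub_cut: median
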