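# Default operating point for the boosted hippocampus segmenter.
# Flags given on the command line override these values.
rounds: 150          # boosting rounds T (Adaboost baseline preset: 400)
eta: 0.1             # learning rate (weight-update shrinkage)
minority-fraction: 0.5   # RUS target N
depth: 3             # weak-learner tree depth
m: 10                # training subjects per run
cv-rounds: 10        # cross-validation rounds
seed: 1
n: 10                # phantoms per generated cohort
noise-sd: 10         # phantom voxel noise standard deviation
side: left
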