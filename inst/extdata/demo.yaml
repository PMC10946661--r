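# Desk-scale demo pipeline: synthetic dish images, RF13 classifier.
#   grainpigment run --config demo.yaml
seed: 1
generator:
  classes: {NP: 3, A: 3, M: 3, AM: 3}
  image_size: 96
  replicates: 3
  hulled_fraction: 0.5
split:
  fractions: [0.6, 0.2, 0.2]
classifier:
  model_kind: rf13
  ntree: 500
  k: 13
evaluation:
  min_fraction: 0.01
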