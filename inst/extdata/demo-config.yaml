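# Small demonstration configuration for the pipeline CLI:
#   Rscript inst/cli/specsift.R run --config inst/extdata/demo-config.yaml --out demo_out --seed 1
simulation:
  nSubjects: 3
  trialsPerCondition: 8
  seed: 1
timeStride: 10
baselines:
  - method: decibel
    window: [-0.5, -0.2]
specWindow: [-0.5, 2]
subtractErp: true
stats:
  q: 0.05
  minTime: 3
  minChannels: 3
seed: 1
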