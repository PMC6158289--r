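# Demo end-to-end run: simulate a small planar wave scene with transient
# cargo, segment it, compute masked statistics and extract a kymograph.
# Runs in well under a minute:
#   Rscript inst/scripts/wavecargo.R run --config inst/extdata/demo_pipeline.yaml
seed: 1
outdir: wavecargo_demo
input:
  simulate:
    mode: planar
    width: 96
    height: 96
    nFrames: 12
    wavelength: 32
    waveSpeed: 4
    kappa: 0.5
stages:
  - segment
  - wavestats
  - kymo
segment:
  method: huang
  medianRadius: 4
  flatfieldRadius: 75
kymo:
  channel: cargo
  line: [0, 48, 95, 48]
  width: 3
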