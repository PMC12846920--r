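# Demo pipeline configuration: a small extinction-only cohort with a
# single amygdala shaft; see ?readPipelineConfig.
nParticipants: 4
seed: 11
phases: extinction
analysisRois:
  theta: AMY
  item: AMY
  context: AMY
nPerm: 300
timeStep: 0.05
generator:
  rois:
    AMY: 3
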