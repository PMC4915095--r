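# Example experiment configuration: ten-replicate high-LD run at the
# reduced (mini) scale. Unspecified values come from the scale preset.
ldLevel: hld
scale: mini
nReplicates: 10
baseSeed: 1
analysis:
  blend: 0.05
  nIterations: 3
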