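# Packaged demo: two synthetic populations of 10 neurons, full descriptor set.
# Run with: run_pipeline(system.file("extdata", "demo-config.yaml",
#                                    package = "dendrisig"), "demo_run")
seed: 1
groups:
- name: WT-like
  preset: wt_like
  n: 10
- name: TG-like
  preset: tg_like
  n: 10
solver:
  dt: 0.025
descriptors: [transfers, delays, electrotonic, epsp]
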