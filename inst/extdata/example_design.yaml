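# example simulation design: classic 2HT generator with trial-level
# log-normal RT emission (detection responses faster than guessing)
family: 2HT
variant: classic
n_subjects: 2
seed: 42
params:
  do: 0.6
  dn: 0.6
  g1: 0.3
  g2: 0.5
  g3: 0.7
rt_emission:
  class: [do, dn, go, gn]
  meanlog: [-0.4, -0.4, 0.1, 0.1]
  sdlog: [0.4, 0.4, 0.4, 0.4]
cl_emission:
  class: [do, dn, go, gn]
  high: [0.7, 0.7, 0.3, 0.3]
  medium: [0.2, 0.2, 0.4, 0.4]
  low: [0.1, 0.1, 0.3, 0.3]
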