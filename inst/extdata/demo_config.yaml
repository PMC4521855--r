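# Demonstration pipeline configuration: synthetic 156-month census with the
# four study-pattern intervention events fitted on the primate series.
seed: 42
scenario:
  seed: 42
  n_months: 156
events:
  - event: 1998-02
    pulse: yes
  - event: 2002-03
    step: yes
    pulse: yes
  - event: 2003-11
    step: yes
    pulse: yes
  - event: 2007-11
    step: yes
    pulse: yes
    lag: yes
breakpoints: ["2003-04", "2007-11"]
alpha: 0.05
n_boot: 2000
prune: yes
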