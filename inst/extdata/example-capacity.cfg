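# Example sweep for the dwsyn CLI: mean-field storage capacity over the
# potential depth and width, balanced coding.
experiment = capacity_meanfield
C = 1
r1 = 0.1
r2 = 1
r3 = 0
theta = 0
f = 0.5
c = 0.05
N = 5000
rule = balanced
sweep_r1 = 0.05,0.1,0.2
sweep_C = 0,1,2,3
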