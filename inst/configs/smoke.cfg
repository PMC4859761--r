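# Quick smoke grid: one AT design, one scenario axis point each.
theta = 0.33
rho0 = 0.05
models = A
gammas = 0.5
rho1s = 0.5
at_designs = 0.1:2:1.5
n_trials = 10
master_seed = 1
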