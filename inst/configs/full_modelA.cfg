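# Full model-A grid: six AT versions plus EWOC and EWOC-PO
# over the nine (gamma, rho1) scenarios.
theta = 0.33
rho0 = 0.05
models = A
gammas = 0.1, 0.5, 0.7
rho1s = 0.2, 0.5, 0.8
at_designs = 0.01:2:1.5, 0.1:2:1.5, 0.01:1.69:1.3, 0.1:1.69:1.3, 0.01:1.96:1.4, 0.1:1.96:1.4
ewoc_variants = binary, po
# desk-scale defaults; --full-scale restores 1000 trials and 4000+4000 MH
n_trials = 100
mh_burnin = 2000
mh_keep = 2000
master_seed = 1
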