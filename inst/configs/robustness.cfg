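# Robustness grids: generating models B-E with the two doubling AT
# versions plus EWOC and EWOC-PO (model D with gamma = 0.1 produces
# failed rows where its DLT curve crosses the grade>=1 curve).
theta = 0.33
rho0 = 0.05
models = B, C, D, E
gammas = 0.1, 0.5, 0.7
rho1s = 0.2, 0.5, 0.8
at_designs = 0.01:2:1.5, 0.1:2:1.5
ewoc_variants = binary, po
n_trials = 100
mh_burnin = 2000
mh_keep = 2000
master_seed = 1
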