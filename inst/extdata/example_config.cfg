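# domainflux study configuration (key = value); see ?run_config
seed = 1
n_steps = 24000
beads_per_subdomain = 56
k_tmd = 3
free_monomer = B
rmsf_threshold = 1.5
corr_threshold = 0.5
knn_k = 6
window = 20
protocols = freeDyn, tmDom, freeMon, freePP, fullTMD
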