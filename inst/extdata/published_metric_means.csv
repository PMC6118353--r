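metric,fs_mean,fs_se,ba_mean,ba_se,rr_mean,rr_se
species_number,25,1.9,12,1.4,12,1.4
link_density,3.6,0.21,2.2,0.24,2,0.18
connectance,0.15,0.005,0.2,0.009,0.19,0.01
vulnerability,3.5,0.2,2.1,0.23,1.9,0.18
generality,3.6,0.21,2.2,0.24,2,0.18
links,6.9,0.41,4.1,0.46,3.7,0.35
top_fraction,0.29,0.018,0.31,0.023,0.36,0.021
intermediate_fraction,0.47,0.02,0.34,0.044,0.37,0.024
basal_fraction,0.24,0.019,0.35,0.032,0.26,0.024
herbivore_fraction,0.26,0.033,0.28,0.031,0.24,0.029
omnivore_fraction,0.26,0.037,0.24,0.04,0.21,0.035
carnivore_fraction,0.24,0.027,0.14,0.028,0.29,0.03
cannibal_fraction,0.14,0.015,0.15,0.023,0.17,0.02
chain_length,1,0.043,0.79,0.056,1,0.049
trophic_level,2.1,0.06,1.9,0.085,2,0.069
max_similarity,0.68,0.017,0.57,0.046,0.52,0.05
clustering,0.29,0.034,0.26,0.047,0.25,0.037
path_length,1.9,0.023,1.7,0.059,1.7,0.048
compartmentalization,0.23,0.009,0.19,0.019,0.2,0.019
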