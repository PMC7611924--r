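# Toy pipeline configuration: a 2000-family cohort small enough to run
# end to end in well under two minutes. The genetic architecture is made
# deliberately concentrated (40 SNPs carrying 40% of trait variance) so
# that instruments exist at the relaxed selection threshold appropriate
# to a cohort of this size; the genome-wide 5e-8 rule needs biobank-scale
# n.
n_families = 2000
n_snps = 40
maf_min = 0.1
maf_max = 0.5
ld_block_size = 1
ld_rho = 0
var_explained = 0.40
shared_fraction = 0.6
p_thresh = 1e-4
n_boot = 200
seed = 7
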