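# Shared fixtures built in code.

assay_densities <- function() density_pair(mr = 1500, ml = 1500)

# Four published (AcKa, koff) pairs: 232I/anti-S, 232T/anti-S,
# 232I/anti-gp120, 232T/anti-gp120.
published_params <- function() {
  list(kinetic_params(3.03e-7, 7.75), kinetic_params(0.80e-7, 7.62),
       kinetic_params(7.74e-7, 7.70), kinetic_params(2.43e-7, 8.90))
}

# Noiseless curve: fractional "adhesion counts" equal to the exact model
# probability times a large cycle count, so the fit should invert the
# closed form to numerical precision.
noiseless_curve <- function(params, densities = assay_densities(),
                            tc = c(0.1, 0.2, 0.5, 1, 2, 5), n = 1e6) {
  pa <- adhesion_probability(tc, densities, params)
  adhesion_curve(
    data.frame(cell_pair_id = paste0("p", seq_along(tc)), tc = tc,
               n_cycles = n, n_adhesions = pa * n),
    densities, "noiseless")
}

table1_rows <- function() {
  read_genotype_rows(system.file("extdata", "sle_table1_rows.csv",
                                 package = "insitu2d"))
}
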