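# Small-scale simulation configurations used across tests. Genome and deme
# sizes are kept tiny so statistical checks can average over many replicates.

tiny_params <- function(model = "discrete_matching", n_pops = 6, n_coev = 1,
                        eta = 60, n_loci = 20, generations = 30, ...) {
  sim_params(n_pops = n_pops, n_loci_host = n_loci, n_loci_par = n_loci,
             n_coev = n_coev, model = model, eta_host = eta, eta_par = eta,
             generations = generations, ...)
}

# A hand-buildable metapopulation: demes supplied as a list of
# list(host =, parasite =) matrices.
manual_metapop <- function(demes, arch, params) {
  names(demes) <- paste0("pop", seq_along(demes))
  structure(list(demes = demes, arch = arch, params = params),
            class = "metapop")
}

# Monomorphic population: eta copies of one genome.
mono_pop <- function(genome, eta) {
  matrix(as.integer(genome), nrow = eta, ncol = length(genome), byrow = TRUE)
}

# Multiset fingerprint of a set of genomes (order-insensitive comparison).
genome_multiset <- function(pop) {
  sort(apply(pop, 1, paste, collapse = ""))
}

# Plain N x n_loci frequency matrix for one species of a metapopulation.
freq_matrix_for_tests <- function(mp, species) {
  do.call(rbind, lapply(mp$demes, function(d) colMeans(d[[species]])))
}
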