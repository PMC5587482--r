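model_code <- function(model) {
  match(model, c("discrete_matching", "quantitative_matching")) - 1L
}

#' Initialize a host-parasite metapopulation
#'
#' Builds the linear array of demes with every allele drawn independently as
#' "1" with probability 0.5 (a symmetric, uninformative starting point), and
#' draws the coevolutionary architecture unless one is supplied.
#'
#' @param params A [sim_params()] object.
#' @param arch Optional [coev_architecture()]; drawn from the current RNG when
#'   `NULL`.
#' @return An object of class `metapop`: a list with `demes` (each a list with
#'   integer 0/1 matrices `host` and `parasite`, individuals in rows), `arch`
#'   and `params`.
#' @examples
#' set.seed(1)
#' mp <- init_metapopulation(sim_params(n_pops = 3, n_loci_host = 8,
#'                                      n_loci_par = 8, eta_host = 10,
#'                                      eta_par = 10))
#' dim(mp$demes[[1]]$host)
#' @export
init_metapopulation <- function(params, arch = NULL) {
  validate_sim_params(params)
  if (is.null(arch)) {
    arch <- coev_architecture(params$n_loci_host, params$n_loci_par,
                              params$n_coev, params$model)
  }
  new_pop <- function(eta, L) {
    matrix(rbinom(eta * L, 1L, 0.5), nrow = eta, ncol = L)
  }
  demes <- lapply(seq_len(params$n_pops), function(k) {
    list(host = new_pop(params$eta_host, params$n_loci_host),
         parasite = new_pop(params$eta_par, params$n_loci_par))
  })
  names(demes) <- paste0("pop", seq_len(params$n_pops))
  structure(list(demes = demes, arch = arch, params = params),
            class = "metapop")
}

#' @export
print.metapop <- function(x, ...) {
  cat("<metapop> ", length(x$demes), " demes, ", x$params$model, "\n", sep = "")
  cat(sprintf("  host: %d x %d per deme; parasite: %d x %d per deme\n",
              x$params$eta_host, x$params$n_loci_host,
              x$params$eta_par, x$params$n_loci_par))
  invisible(x)
}

#' Additive phenotype from the coevolving loci
#'
#' The quantitative-matching phenotype: the count of "1" alleles at the
#' coevolving loci, scaled by their number so the result lies in `[0, 1]`.
#'
#' @param genome Integer 0/1 vector (one individual's genome).
#' @param coev_idx Indices of the coevolving loci (1-based, nonempty).
#' @return A scalar in `[0, 1]`.
#' @export
phenotype <- function(genome, coev_idx) {
  if (length(coev_idx) == 0) {
    stop("coev_idx must be nonempty", call. = FALSE)
  }
  sum(genome[coev_idx]) / length(coev_idx)
}

#' Infection probability for one host-parasite encounter
#'
#' Under the discrete matching model the probability is `1 - beta * M` where
#' `M` is the fraction of positionally paired coevolving loci whose alleles
#' differ; at `beta = 1` this is the classical matching-alleles model. Under
#' the quantitative matching model it is `exp(-beta * delta^2)` where `delta`
#' is the difference between the host and parasite additive phenotypes (see
#' [phenotype()]).
#'
#' @param host_genome,par_genome Integer 0/1 vectors.
#' @param model Infection model name.
#' @param beta Sensitivity parameter (`<= 1` required for the discrete model).
#' @param arch A [coev_architecture()] giving the coevolving locus indices.
#' @return A probability in `[0, 1]`.
#' @export
infection_probability <- function(host_genome, par_genome,
                                  model = c("discrete_matching",
                                            "quantitative_matching"),
                                  beta, arch) {
  model <- match.arg(model)
  if (beta < 0) stop("invalid `beta`: must be non-negative", call. = FALSE)
  if (model == "discrete_matching" && beta > 1) {
    stop("invalid `beta`: must be <= 1 under the discrete matching model",
         call. = FALSE)
  }
  .cpp_infection_probability(as.integer(host_genome), as.integer(par_genome),
                             model_code(model), beta,
                             as.integer(arch$host_idx),
                             as.integer(arch$par_idx))
}

#' Species-interaction stage: random encounters and survival
#'
#' Every host meets one parasite drawn uniformly with replacement from its
#' deme and survives with probability `1 - s * P`; every parasite meets one
#' host drawn the same way and survives with probability `P`, where `P` is the
#' encounter's infection probability. Empty survivor sets are legal and are
#' handled by [reproduce()]'s fallback.
#'
#' @param host_pop,par_pop Integer 0/1 genotype matrices (individuals x loci).
#' @param model,beta,arch As in [infection_probability()].
#' @param s Virulence in `[0, 1]`.
#' @return A list with `host` and `parasite`: each the survivors' genotype
#'   matrix, with the surviving row indices as attribute `"idx"`.
#' @export
encounter_and_select <- function(host_pop, par_pop, model, beta, s, arch) {
  idx <- .cpp_encounter_select(host_pop, par_pop, model_code(model), beta, s,
                               as.integer(arch$host_idx),
                               as.integer(arch$par_idx))
  hs <- host_pop[idx$host, , drop = FALSE]
  ps <- par_pop[idx$parasite, , drop = FALSE]
  attr(hs, "idx") <- idx$host
  attr(ps, "idx") <- idx$parasite
  list(host = hs, parasite = ps)
}

#' Sexual reproduction with recombination
#'
#' Restores the deme to its census size: each offspring is formed from two
#' parents drawn uniformly with replacement from the survivors, with the
#' gamete starting on a uniformly chosen parent and switching parental source
#' between adjacent loci `i, i+1` independently with probability `r[i]`.
#' If fewer than two survivors remain, parents are drawn from `fallback`
#' (normally the pre-selection population), so a deme never goes extinct.
#'
#' @param survivors Genotype matrix of surviving individuals.
#' @param r Vector of adjacent-locus recombination rates (length `n_loci - 1`).
#' @param eta Target census size (number of offspring to produce).
#' @param fallback Genotype matrix used as the parent pool when `survivors`
#'   has fewer than two rows.
#' @return An `eta` x `n_loci` integer 0/1 matrix of offspring.
#' @export
reproduce <- function(survivors, r, eta, fallback = survivors) {
  pool <- if (nrow(survivors) < 2L) fallback else survivors
  if (nrow(pool) < 1L) stop("no individuals available to reproduce",
                            call. = FALSE)
  .cpp_reproduce(pool, seq_len(nrow(pool)), as.numeric(r), as.integer(eta))
}

#' Per-genome mutation
#'
#' Independently for each genome, with probability `mu` exactly one uniformly
#' chosen locus is flipped to its alternative allele; otherwise the genome is
#' unchanged. `mu` is a per-genome (genome-wide), not per-locus, rate.
#'
#' @param pop Genotype matrix.
#' @param mu Per-genome mutation probability.
#' @return Mutated genotype matrix of the same shape.
#' @export
mutate_genomes <- function(pop, mu) {
  if (mu < 0 || mu > 1) stop("invalid `mu`: must be in [0, 1]", call. = FALSE)
  .cpp_mutate(pop, mu)
}

#' Stepping-stone migration across the metapopulation
#'
#' Linear stepping-stone dispersal realized as symmetric swaps: each adjacent
#' deme pair is visited once (left to right), each individual of the left deme
#' initiates an exchange with probability `m/2`, and the exchange partner is
#' drawn uniformly from the right deme. Deme sizes are exactly conserved, and
#' the two terminal demes -- having a single neighbour -- experience half the
#' migration rate of interior demes.
#'
#' @param metapop A `metapop` object.
#' @param m_host,m_par Per-individual migration probabilities. Default to the
#'   values in `metapop$params`.
#' @return The metapopulation after migration.
#' @export
migrate <- function(metapop, m_host = metapop$params$m_host,
                    m_par = metapop$params$m_par) {
  if (m_host < 0 || m_host > 1) stop("invalid `m_host`: must be in [0, 1]",
                                     call. = FALSE)
  if (m_par < 0 || m_par > 1) stop("invalid `m_par`: must be in [0, 1]",
                                   call. = FALSE)
  hosts <- .cpp_migrate(lapply(metapop$demes, `[[`, "host"), m_host)
  pars <- .cpp_migrate(lapply(metapop$demes, `[[`, "parasite"), m_par)
  for (k in seq_along(metapop$demes)) {
    metapop$demes[[k]]$host <- hosts[[k]]
    metapop$demes[[k]]$parasite <- pars[[k]]
  }
  metapop
}

#' Run the coevolution simulation
#'
#' Iterates the four-stage life cycle -- (1) species interactions,
#' (2) reproduction, (3) mutation, (4) migration -- for
#' `params$generations` generations over the full metapopulation. The
#' generation loop runs in compiled code but draws all randomness from R's
#' RNG, so a fixed `params$seed` (or a prior `set.seed()` call when
#' `params$seed` is `NULL`) makes runs bit-identical.
#'
#' @param params A [sim_params()] object.
#' @param arch Optional fixed [coev_architecture()].
#' @return The final `metapop` after `params$generations` life cycles.
#' @examples
#' mp <- run_simulation(sim_params(n_pops = 4, n_loci_host = 10,
#'                                 n_loci_par = 10, eta_host = 20,
#'                                 eta_par = 20, generations = 10, seed = 42))
#' allele_frequencies(mp, "host")
#' @export
run_simulation <- function(params, arch = NULL) {
  validate_sim_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  mp <- init_metapopulation(params, arch)
  if (params$generations == 0L) return(mp)
  res <- .cpp_run_generations(
    lapply(mp$demes, `[[`, "host"),
    lapply(mp$demes, `[[`, "parasite"),
    model_code(params$model), params$beta, params$s,
    as.integer(mp$arch$host_idx), as.integer(mp$arch$par_idx),
    as.numeric(params$r_host), as.numeric(params$r_par),
    params$mu_host, params$mu_par, params$m_host, params$m_par,
    params$generations)
  for (k in seq_along(mp$demes)) {
    mp$demes[[k]]$host <- res$host[[k]]
    mp$demes[[k]]$parasite <- res$parasite[[k]]
  }
  mp
}
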