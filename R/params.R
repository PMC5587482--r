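#' Simulation parameters for the coevolution simulator
#'
#' Bundles and validates every knob of the individual-based host-parasite
#' simulator: metapopulation geometry, genome sizes, the infection model and
#' its sensitivity, virulence, census sizes, and the per-generation mutation,
#' migration and recombination rates.
#'
#' @param n_pops Number of demes in the linear metapopulation.
#' @param n_loci_host,n_loci_par Number of diallelic loci per genome in each
#'   species. The evaluation harness fixes both at 100.
#' @param n_coev Number of coevolving loci per species (the remaining loci are
#'   selectively neutral markers).
#' @param model Infection model: `"discrete_matching"` (infection probability
#'   declines linearly with the fraction of mismatched coevolving loci) or
#'   `"quantitative_matching"` (Gaussian function of the host-parasite
#'   phenotype difference).
#' @param beta Sensitivity of infection to genetic (or phenotypic) mismatch.
#'   Must lie in `[0, 1]` for the discrete model so that probabilities stay
#'   non-negative; any non-negative value is allowed for the quantitative
#'   model.
#' @param s Virulence: the fitness cost of infection to the host, in `[0, 1]`.
#' @param eta_host,eta_par Census size of each deme, per species (constant
#'   over a run).
#' @param mu_host,mu_par Per-genome, per-generation mutation probabilities.
#'   A mutating genome flips exactly one uniformly chosen locus.
#' @param m_host,m_par Per-individual migration probabilities under the linear
#'   stepping-stone model.
#' @param r_host,r_par Recombination rates between adjacent loci, each in
#'   `[0, 0.5]`. A scalar is recycled to length `n_loci - 1`.
#' @param generations Number of life cycles to iterate.
#' @param seed Optional integer seed; when set, [run_simulation()] seeds the
#'   global RNG so runs are exactly reproducible.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [run_simulation()], [parameter_ranges()]
#' @examples
#' p <- sim_params(n_pops = 4, n_loci_host = 10, n_loci_par = 10,
#'                 eta_host = 20, eta_par = 20, generations = 5, seed = 1)
#' p$beta
#' @export
sim_params <- function(n_pops = 40,
                       n_loci_host = 100,
                       n_loci_par = 100,
                       n_coev = 1,
                       model = c("discrete_matching", "quantitative_matching"),
                       beta = NULL,
                       s = 0.75,
                       eta_host = 225,
                       eta_par = 225,
                       mu_host = 0.03,
                       mu_par = 0.03,
                       m_host = 0.005,
                       m_par = 0.005,
                       r_host = 0.25,
                       r_par = 0.25,
                       generations = 500,
                       seed = NULL) {
  model <- match.arg(model)
  if (is.null(beta)) {
    beta <- if (model == "discrete_matching") 0.9 else 3.0
  }
  if (length(r_host) == 1L) r_host <- rep(r_host, max(n_loci_host - 1L, 0L))
  if (length(r_par) == 1L) r_par <- rep(r_par, max(n_loci_par - 1L, 0L))

  p <- structure(
    list(n_pops = as.integer(n_pops),
         n_loci_host = as.integer(n_loci_host),
         n_loci_par = as.integer(n_loci_par),
         n_coev = as.integer(n_coev),
         model = model, beta = beta, s = s,
         eta_host = as.integer(eta_host), eta_par = as.integer(eta_par),
         mu_host = mu_host, mu_par = mu_par,
         m_host = m_host, m_par = m_par,
         r_host = r_host, r_par = r_par,
         generations = as.integer(generations),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_params")
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  chk <- function(ok, field, what) {
    if (!isTRUE(all(ok))) {
      stop(sprintf("invalid `%s`: %s", field, what), call. = FALSE)
    }
  }
  chk(p$n_pops >= 1L, "n_pops", "must be a positive integer")
  chk(p$n_loci_host >= 1L, "n_loci_host", "must be a positive integer")
  chk(p$n_loci_par >= 1L, "n_loci_par", "must be a positive integer")
  chk(p$n_coev >= 1L && p$n_coev <= min(p$n_loci_host, p$n_loci_par),
      "n_coev", "must satisfy 1 <= n_coev <= min(n_loci_host, n_loci_par)")
  chk(p$beta >= 0, "beta", "must be non-negative")
  if (p$model == "discrete_matching") {
    chk(p$beta <= 1, "beta",
        "must be <= 1 under the discrete matching model (infection probabilities would go negative)")
  }
  chk(p$s >= 0 && p$s <= 1, "s", "must lie in [0, 1]")
  chk(p$eta_host >= 2L, "eta_host", "must be at least 2")
  chk(p$eta_par >= 2L, "eta_par", "must be at least 2")
  for (f in c("mu_host", "mu_par", "m_host", "m_par")) {
    chk(p[[f]] >= 0 && p[[f]] <= 1, f, "must be a probability in [0, 1]")
  }
  chk(length(p$r_host) == p$n_loci_host - 1L, "r_host",
      "must have length n_loci_host - 1")
  chk(length(p$r_par) == p$n_loci_par - 1L, "r_par",
      "must have length n_loci_par - 1")
  chk(all(p$r_host >= 0 & p$r_host <= 0.5), "r_host",
      "entries must lie in [0, 0.5]")
  chk(all(p$r_par >= 0 & p$r_par <= 0.5), "r_par",
      "entries must lie in [0, 0.5]")
  chk(p$generations >= 0L, "generations", "must be non-negative")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> ", x$model, "\n", sep = "")
  cat(sprintf("  %d demes; host %d loci (eta=%d), parasite %d loci (eta=%d); %d coevolving\n",
              x$n_pops, x$n_loci_host, x$eta_host, x$n_loci_par, x$eta_par,
              x$n_coev))
  cat(sprintf("  beta=%.3g s=%.3g mu=(%.3g, %.3g) m=(%.3g, %.3g) generations=%d\n",
              x$beta, x$s, x$mu_host, x$mu_par, x$m_host, x$m_par,
              x$generations))
  invisible(x)
}

#' Read simulation parameters from a JSON or YAML configuration file
#'
#' Fields mirror the arguments of [sim_params()]; all are optional and
#' unspecified fields keep their defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `sim_params` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config extension '.", ext, "' (expected .json or .yaml)",
         call. = FALSE))
  unknown <- setdiff(names(cfg), names(formals(sim_params)))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_params, cfg)
}

#' Coevolutionary architecture: which loci interact across species
#'
#' Selects (or accepts) the indices of the coevolving loci in each genome and
#' derives the truth set of functionally coupled host-parasite locus pairs.
#' Under the discrete matching model coevolving loci are compared positionally
#' (host locus k with parasite locus k in the order drawn), so the functional
#' pairs are exactly those index pairs. Under the quantitative matching model
#' the loci contribute additively to a phenotype and are interchangeable, so
#' every coevolving host locus is functionally coupled to every coevolving
#' parasite locus (the full cross product).
#'
#' @param n_loci_host,n_loci_par Genome sizes.
#' @param n_coev Number of coevolving loci per species.
#' @param model Infection model (see [sim_params()]).
#' @param host_idx,par_idx Optional explicit locus indices (1-based). When
#'   `NULL`, drawn uniformly without replacement from the current RNG.
#' @return An object of class `coev_arch` with elements `host_idx`, `par_idx`
#'   and `functional_pairs` (a two-column integer matrix).
#' @examples
#' set.seed(1)
#' coev_architecture(10, 10, 2, "quantitative_matching")
#' @export
coev_architecture <- function(n_loci_host, n_loci_par, n_coev,
                              model = c("discrete_matching",
                                        "quantitative_matching"),
                              host_idx = NULL, par_idx = NULL) {
  model <- match.arg(model)
  if (is.null(host_idx)) host_idx <- sample.int(n_loci_host, n_coev)
  if (is.null(par_idx)) par_idx <- sample.int(n_loci_par, n_coev)
  host_idx <- as.integer(host_idx)
  par_idx <- as.integer(par_idx)
  if (length(host_idx) != length(par_idx)) {
    stop("host_idx and par_idx must have equal length", call. = FALSE)
  }
  if (anyDuplicated(host_idx) || anyDuplicated(par_idx)) {
    stop("coevolving locus indices must be unique within a species",
         call. = FALSE)
  }
  pairs <- if (model == "discrete_matching") {
    cbind(host = host_idx, parasite = par_idx)
  } else {
    as.matrix(expand.grid(host = host_idx, parasite = par_idx,
                          KEEP.OUT.ATTRS = FALSE))
  }
  structure(list(host_idx = host_idx, par_idx = par_idx,
                 functional_pairs = pairs, model = model),
            class = "coev_arch")
}

#' @export
print.coev_arch <- function(x, ...) {
  cat("<coev_arch> ", x$model, "\n", sep = "")
  cat("  host loci:     ", paste(x$host_idx, collapse = ", "), "\n")
  cat("  parasite loci: ", paste(x$par_idx, collapse = ", "), "\n")
  cat("  functional pairs:", nrow(x$functional_pairs), "\n")
  invisible(x)
}

#' Functional pairs as a tibble
#'
#' @param x A `coev_arch` object.
#' @param ... Unused.
#' @return A tibble with integer columns `host_locus` and `parasite_locus`.
#' @export
tidy.coev_arch <- function(x, ...) {
  tibble::tibble(host_locus = as.integer(x$functional_pairs[, 1]),
                 parasite_locus = as.integer(x$functional_pairs[, 2]))
}
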