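#' Parameter ranges for replicate simulations
#'
#' Uniform sampling bounds for the stochastic simulation parameters, with the
#' genome sizes and run length fixed (100 loci per species, 500 generations).
#' Defaults: migration `[0, 0.01]`, virulence `[0.6, 0.9]`, deme size
#' `[150, 300]`, genome-wide mutation `[0.01, 0.05]`, adjacent-locus
#' recombination `[0, 0.5]`, and infection sensitivity `[0.8, 1.0]` for the
#' discrete matching model or `[2.0, 4.0]` for the quantitative matching
#' model. Any bound can be overridden, e.g. to target low-migration draws
#' that produce strong local adaptation.
#'
#' @param model Infection model the `beta` bounds should follow.
#' @param beta,s,eta,mu,m,r Optional length-2 numeric `c(lower, upper)`
#'   overrides of the default bounds (`eta`, `mu` and `m` set both species).
#' @param eta_host,eta_par,mu_host,mu_par,m_host,m_par Optional per-species
#'   bound overrides (take precedence over the joint fields). Local
#'   adaptation of the parasite arises when the parasite's evolutionary
#'   potential exceeds the host's, so conditional studies of the strong-L
#'   regime are accelerated by biasing these (e.g. low `m_host`, high
#'   `m_par`).
#' @param n_loci,generations Fixed scalar overrides.
#' @return An object of class `param_ranges`.
#' @examples
#' parameter_ranges("discrete_matching", m_host = c(0, 0.002))
#' @export
parameter_ranges <- function(model = c("discrete_matching",
                                       "quantitative_matching"),
                             beta = NULL, s = NULL, eta = NULL, mu = NULL,
                             m = NULL, r = NULL,
                             eta_host = NULL, eta_par = NULL,
                             mu_host = NULL, mu_par = NULL,
                             m_host = NULL, m_par = NULL,
                             n_loci = 100L, generations = 500L) {
  model <- match.arg(model)
  rg <- list(
    beta = beta %||%
      (if (model == "discrete_matching") c(0.8, 1.0) else c(2.0, 4.0)),
    s = s %||% c(0.6, 0.9),
    eta_host = eta_host %||% eta %||% c(150, 300),
    eta_par = eta_par %||% eta %||% c(150, 300),
    mu_host = mu_host %||% mu %||% c(0.01, 0.05),
    mu_par = mu_par %||% mu %||% c(0.01, 0.05),
    m_host = m_host %||% m %||% c(0, 0.01),
    m_par = m_par %||% m %||% c(0, 0.01),
    r = r %||% c(0, 0.5),
    n_loci = n_loci,
    generations = generations)
  for (f in setdiff(names(rg), c("n_loci", "generations"))) {
    if (length(rg[[f]]) != 2 || rg[[f]][1] > rg[[f]][2]) {
      stop("invalid bounds for `", f, "`: need ordered c(lower, upper)",
           call. = FALSE)
    }
  }
  structure(c(rg, list(model = model)), class = "param_ranges")
}

#' Draw one simulation parameter set from uniform ranges
#'
#' Each stochastic field is drawn independently and uniformly from its bounds;
#' recombination rates are drawn per adjacent locus pair. Uses the current
#' RNG state.
#'
#' @param ranges A [parameter_ranges()] object.
#' @param n_coev Number of coevolving loci per species.
#' @param n_pops Number of demes.
#' @param seed Optional seed to store in the resulting [sim_params()] (for
#'   exact replay of the replicate that will be run from it).
#' @return A `sim_params` object.
#' @export
draw_parameters <- function(ranges, n_coev = 1, n_pops = 40, seed = NULL) {
  stopifnot(inherits(ranges, "param_ranges"))
  u <- function(b) runif(1, b[1], b[2])
  n_loci <- as.integer(ranges$n_loci)
  sim_params(
    n_pops = n_pops,
    n_loci_host = n_loci, n_loci_par = n_loci,
    n_coev = n_coev, model = ranges$model,
    beta = u(ranges$beta), s = u(ranges$s),
    eta_host = round(u(ranges$eta_host)), eta_par = round(u(ranges$eta_par)),
    mu_host = u(ranges$mu_host), mu_par = u(ranges$mu_par),
    m_host = u(ranges$m_host), m_par = u(ranges$m_par),
    r_host = runif(n_loci - 1, ranges$r[1], ranges$r[2]),
    r_par = runif(n_loci - 1, ranges$r[1], ranges$r[2]),
    generations = as.integer(ranges$generations),
    seed = seed)
}

#' Run one full evaluation replicate
#'
#' Simulates coevolution under `params`, measures local adaptation via the
#' exact simulated reciprocal cross-infection experiment, runs the full
#' host x parasite correlation scan, and scores it against the replicate's
#' true functional pairs at every level in `alpha_grid`. Fully reproducible
#' from `params$seed`.
#'
#' @param params A [sim_params()] object (give it a `seed` for replay).
#' @param alpha_grid Significance levels at which to score the scan.
#' @return An object of class `replicate_record`: a list with `params`,
#'   `arch`, `L`, `bin`, `cross_infection` (the N x N matrix), and `errors`
#'   (a tibble with one row per `alpha`: the [classify_errors()] columns plus
#'   `alpha`).
#' @export
run_replicate <- function(params, alpha_grid = c(0.001, 0.005, 0.01, 0.02)) {
  mp <- run_simulation(params)
  P <- cross_infection_matrix(mp, mode = "exact")
  la <- local_adaptation(P)
  fh <- allele_frequencies(mp, "host")
  fp <- allele_frequencies(mp, "parasite")
  scan <- coev_scan(fh, fp, alpha = alpha_grid[1])
  errors <- purrr::map_dfr(alpha_grid, function(a) {
    dplyr::bind_cols(tibble::tibble(alpha = a),
                     classify_errors(scan, mp$arch, alpha = a))
  })
  structure(list(params = params, arch = mp$arch, L = la$L, bin = la$bin,
                 cross_infection = P, errors = errors),
            class = "replicate_record")
}

#' @export
print.replicate_record <- function(x, ...) {
  cat(sprintf("<replicate_record> %s, %d coevolving, N=%d: L = %.4f (%s)\n",
              x$params$model, x$params$n_coev, x$params$n_pops, x$L, x$bin))
  invisible(x)
}

#' Flatten replicate records into a per-alpha tibble
#'
#' @param records A list of `replicate_record`s (or one record).
#' @return A tibble with one row per record x alpha: `replicate`, `seed`,
#'   `model`, `n_coev`, `n_pops`, `m_host`, `m_par`, `L`, `bin`, plus the
#'   error-report columns.
#' @export
records_table <- function(records) {
  if (inherits(records, "replicate_record")) records <- list(records)
  purrr::imap_dfr(records, function(r, i) {
    dplyr::bind_cols(
      tibble::tibble(replicate = i,
                     seed = r$params$seed %||% NA_integer_,
                     model = r$params$model,
                     n_coev = r$params$n_coev,
                     n_pops = r$params$n_pops,
                     m_host = r$params$m_host,
                     m_par = r$params$m_par,
                     L = r$L, bin = r$bin),
      r$errors)
  })
}

#' Accumulate replicates until every local-adaptation bin is filled
#'
#' Repeatedly draws parameters from `ranges`, runs [run_replicate()], and
#' keeps going until every bin in `target_bins` holds at least `min_per_bin`
#' records. All completed records are retained, including those in overfilled
#' or non-target bins. A draw budget caps the loop; exhaustion returns the
#' partial record set with a warning, never silently.
#'
#' @inheritParams draw_parameters
#' @param min_per_bin Minimum records per target bin.
#' @param alpha_grid Levels passed to [run_replicate()].
#' @param target_bins Bins that must be filled (subset of
#'   `c("minimal", "weak", "moderate", "strong")`). Restricting to one bin
#'   (with matching `ranges`, e.g. low migration for `"strong"`) accelerates
#'   conditional studies; downstream summaries condition on the realized bin.
#' @param max_draws Replicate budget (default `50 * min_per_bin` per target
#'   bin).
#' @param progress Print one line per completed replicate.
#' @return A list of `replicate_record`s.
#' @export
accumulate_bins <- function(ranges, n_coev = 1, n_pops = 40, min_per_bin = 30,
                            alpha_grid = c(0.001, 0.005, 0.01, 0.02),
                            target_bins = c("minimal", "weak", "moderate",
                                            "strong"),
                            max_draws = 50 * min_per_bin * length(target_bins),
                            progress = FALSE) {
  stopifnot(min_per_bin >= 1)
  target_bins <- match.arg(target_bins, several.ok = TRUE)
  records <- list()
  fill <- setNames(rep(0L, length(target_bins)), target_bins)
  draws <- 0L
  while (any(fill < min_per_bin) && draws < max_draws) {
    draws <- draws + 1L
    seed <- sample.int(.Machine$integer.max, 1)
    params <- draw_parameters(ranges, n_coev = n_coev, n_pops = n_pops,
                              seed = seed)
    rec <- run_replicate(params, alpha_grid)
    records[[length(records) + 1L]] <- rec
    if (rec$bin %in% target_bins) fill[rec$bin] <- fill[rec$bin] + 1L
    if (progress) {
      message(sprintf("replicate %d: L = %.4f (%s) [%s]", draws, rec$L,
                      rec$bin,
                      paste(sprintf("%s %d/%d", names(fill), fill,
                                    min_per_bin), collapse = ", ")))
    }
  }
  if (any(fill < min_per_bin)) {
    short <- names(fill)[fill < min_per_bin]
    warning(sprintf(
      "replicate budget (%d draws) exhausted before filling bin(s): %s",
      max_draws, paste(short, collapse = ", ")), call. = FALSE)
  }
  records
}

#' Detection power and type I error rates by local-adaptation bin
#'
#' For each bin: the number of replicates, the detection power (fraction of
#' replicates in which every functional pair was significant), and the mean
#' and median per-replicate type I error rate, all at significance level
#' `alpha`. Bins with no replicates are absent from the output rather than
#' reported as zero.
#'
#' @param records A list of `replicate_record`s.
#' @param alpha One level from the records' alpha grid.
#' @return A tibble with columns `bin`, `n`, `power`, `mean_type1`,
#'   `median_type1`.
#' @export
power_table <- function(records, alpha = 0.01) {
  tbl <- records_table(records)
  tbl <- dplyr::filter(tbl, .data$alpha == !!alpha)
  if (nrow(tbl) == 0) {
    stop("no records scored at alpha = ", alpha, call. = FALSE)
  }
  tbl |>
    dplyr::mutate(bin = factor(.data$bin, levels = la_bins, ordered = TRUE)) |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     power = mean(.data$full_detection),
                     mean_type1 = mean(.data$type1_rate),
                     median_type1 = median(.data$type1_rate),
                     .groups = "drop") |>
    dplyr::arrange(.data$bin)
}

#' Per-replicate type I error rate against local adaptation
#'
#' The relationship behind the scan's calibration: type I inflation is driven
#' by gene flow, and strong local adaptation arises only under weak gene
#' flow, so the per-replicate type I rate falls toward `alpha` as `L` grows.
#'
#' @inheritParams power_table
#' @return A list of class `type1_profile` with `points` (one row per
#'   replicate: `L`, `bin`, `type1_rate`, `m_product`) and `medians` (per-bin
#'   median type I rate), plus the `alpha` used. Has an [autoplot()] method.
#' @export
type1_vs_L <- function(records, alpha = 0.001) {
  tbl <- records_table(records)
  tbl <- dplyr::filter(tbl, .data$alpha == !!alpha)
  if (nrow(tbl) == 0) {
    stop("no records scored at alpha = ", alpha, call. = FALSE)
  }
  points <- tbl |>
    dplyr::transmute(L = .data$L,
                     bin = factor(.data$bin, levels = la_bins,
                                  ordered = TRUE),
                     type1_rate = .data$type1_rate,
                     m_product = .data$m_host * .data$m_par)
  medians <- points |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     median_type1 = median(.data$type1_rate),
                     median_L = median(.data$L), .groups = "drop")
  structure(list(points = points, medians = medians, alpha = alpha),
            class = "type1_profile")
}

#' @export
print.type1_profile <- function(x, ...) {
  cat(sprintf("<type1_profile> alpha = %g, %d replicates\n", x$alpha,
              nrow(x$points)))
  print(x$medians)
  invisible(x)
}

#' Fraction of replicates exceeding local-adaptation thresholds
#'
#' For each threshold, the fraction of replicates whose local adaptation `L`
#' exceeds it, grouped by model and number of coevolving loci. Thresholds
#' 0.11 and 0.23 bracket the midrange and the largest empirical estimates
#' from published reciprocal cross-infection studies.
#'
#' @param records A list of `replicate_record`s.
#' @param thresholds Numeric vector of thresholds.
#' @return A tibble: `model`, `n_coev`, `threshold`, `n`, `fraction`.
#' @export
exceedance_by_loci <- function(records, thresholds = c(0.11, 0.23)) {
  if (length(thresholds) == 0) stop("need at least one threshold",
                                    call. = FALSE)
  tbl <- records_table(records) |>
    dplyr::distinct(.data$replicate, .keep_all = TRUE)
  purrr::map_dfr(thresholds, function(th) {
    tbl |>
      dplyr::group_by(model = .data$model, n_coev = .data$n_coev) |>
      dplyr::summarise(threshold = th, n = dplyr::n(),
                       fraction = mean(.data$L > th), .groups = "drop")
  }) |>
    dplyr::arrange(.data$model, .data$n_coev, .data$threshold)
}
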