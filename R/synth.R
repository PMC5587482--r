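#' Synthetic frequency tables with planted interspecific correlations
#'
#' Generates paired host/parasite frequency tables for testing the scan
#' independently of the coevolution simulator. Each planted pair's host and
#' parasite columns are drawn from a bivariate Gaussian on the logit scale
#' with the requested correlation and mapped through the inverse logit, a
#' Gaussian copula that keeps frequencies strictly inside (0, 1) while making
#' the target correlation interpretable; all other columns are independent
#' logit-normal noise. The empirical correlation of a planted pair converges
#' on its target as the number of populations grows (the rank correlation is
#' preserved exactly by the monotone transform; the Pearson correlation is
#' attenuated only mildly at `sd_logit = 1`).
#'
#' @param n_pops Number of populations (>= 4).
#' @param n_host_loci,n_par_loci Number of loci per species.
#' @param true_pairs Data frame with columns `host_locus`, `parasite_locus`
#'   (1-based indices) and `rho` (`|rho| < 1`), or `NULL` for a pure null
#'   dataset. A locus may appear in at most one pair.
#' @param mean_logit,sd_logit Mean and standard deviation of the latent
#'   Gaussian (logit-scale allele frequency distribution across
#'   populations).
#' @return An object of class `synth_scan_truth`: a list with frequency
#'   tables `host` and `parasite`, the `true_pairs` tibble, and
#'   `neutral_host`/`neutral_par` index vectors.
#' @examples
#' set.seed(7)
#' sy <- synth_correlated_frequencies(40, 10, 10,
#'   true_pairs = data.frame(host_locus = 2, parasite_locus = 5, rho = 0.9))
#' sc <- coev_scan(sy$host, sy$parasite, alpha = 0.01)
#' sc$significant[2, 5]
#' @export
synth_correlated_frequencies <- function(n_pops, n_host_loci, n_par_loci,
                                         true_pairs = NULL,
                                         mean_logit = 0, sd_logit = 1) {
  if (n_pops < 4) stop("need n_pops >= 4", call. = FALSE)
  if (is.null(true_pairs)) {
    true_pairs <- tibble::tibble(host_locus = integer(0),
                                 parasite_locus = integer(0),
                                 rho = numeric(0))
  }
  true_pairs <- tibble::as_tibble(true_pairs)
  if (nrow(true_pairs) > 0) {
    if (any(abs(true_pairs$rho) >= 1)) {
      stop("invalid target correlation: |rho| must be < 1", call. = FALSE)
    }
    if (anyDuplicated(true_pairs$host_locus) ||
        anyDuplicated(true_pairs$parasite_locus)) {
      stop("each locus may appear in at most one planted pair",
           call. = FALSE)
    }
    if (any(true_pairs$host_locus < 1 | true_pairs$host_locus > n_host_loci) ||
        any(true_pairs$parasite_locus < 1 |
            true_pairs$parasite_locus > n_par_loci)) {
      stop("planted pair indices out of range", call. = FALSE)
    }
  }
  ZH <- matrix(rnorm(n_pops * n_host_loci), n_pops, n_host_loci)
  ZP <- matrix(rnorm(n_pops * n_par_loci), n_pops, n_par_loci)
  for (i in seq_len(nrow(true_pairs))) {
    h <- true_pairs$host_locus[i]
    p <- true_pairs$parasite_locus[i]
    r <- true_pairs$rho[i]
    # correlate the parasite latent column with the host's
    ZP[, p] <- r * ZH[, h] + sqrt(1 - r^2) * ZP[, p]
  }
  to_table <- function(Z, prefix) {
    freqs <- stats::plogis(mean_logit + sd_logit * Z)
    colnames(freqs) <- sprintf("%s%03d", prefix, seq_len(ncol(Z)))
    tibble::as_tibble(cbind(tibble::tibble(population =
                                             paste0("pop", seq_len(n_pops))),
                            tibble::as_tibble(freqs)))
  }
  structure(list(
    host = to_table(ZH, "H"),
    parasite = to_table(ZP, "P"),
    true_pairs = true_pairs,
    neutral_host = setdiff(seq_len(n_host_loci), true_pairs$host_locus),
    neutral_par = setdiff(seq_len(n_par_loci), true_pairs$parasite_locus)),
    class = "synth_scan_truth")
}

#' @export
print.synth_scan_truth <- function(x, ...) {
  cat(sprintf("<synth_scan_truth> %d populations, %d host x %d parasite loci, %d planted pair(s)\n",
              nrow(x$host), ncol(x$host) - 1, ncol(x$parasite) - 1,
              nrow(x$true_pairs)))
  invisible(x)
}
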