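#' Per-population allele frequencies
#'
#' Census frequency of allele "1" at every locus in every deme, for one
#' species of a metapopulation (or for a plain list of genotype matrices).
#'
#' @param x A `metapop` object or a list of integer 0/1 genotype matrices
#'   (one per deme, individuals in rows).
#' @param species For a `metapop`: `"host"` or `"parasite"`.
#' @param prefix Prefix for locus labels (default `"H"` for host, `"P"` for
#'   parasite, `"L"` otherwise).
#' @return A frequency table: a tibble whose first column `population` holds
#'   deme labels and whose remaining columns (one per locus) hold frequencies
#'   in `[0, 1]`.
#' @export
allele_frequencies <- function(x, species = c("host", "parasite"),
                               prefix = NULL) {
  if (inherits(x, "metapop")) {
    species <- match.arg(species)
    pops <- lapply(x$demes, `[[`, species)
    if (is.null(prefix)) prefix <- if (species == "host") "H" else "P"
  } else {
    pops <- x
    if (is.null(prefix)) prefix <- "L"
  }
  if (length(pops) == 0) stop("no demes supplied", call. = FALSE)
  if (any(vapply(pops, nrow, 0L) == 0L)) {
    stop("empty deme: cannot compute allele frequencies", call. = FALSE)
  }
  n_loci <- unique(vapply(pops, ncol, 0L))
  if (length(n_loci) != 1L) {
    stop("all demes must share the same locus count", call. = FALSE)
  }
  freqs <- do.call(rbind, lapply(pops, colMeans))
  labels <- if (is.null(names(pops))) paste0("pop", seq_along(pops)) else names(pops)
  colnames(freqs) <- sprintf("%s%03d", prefix, seq_len(n_loci))
  tibble::as_tibble(cbind(tibble::tibble(population = labels),
                          tibble::as_tibble(freqs)))
}

# Strip the population column of a frequency table into a plain matrix with
# deme labels as rownames. Accepts a matrix unchanged.
freq_matrix <- function(tbl) {
  if (is.matrix(tbl)) return(tbl)
  stopifnot(is.data.frame(tbl))
  if (!"population" %in% names(tbl)) {
    stop("frequency table must have a `population` column", call. = FALSE)
  }
  m <- as.matrix(tbl[setdiff(names(tbl), "population")])
  rownames(m) <- as.character(tbl$population)
  storage.mode(m) <- "double"
  m
}

check_paired_tables <- function(fh, fp, min_pops = 2L) {
  if (nrow(fh) != nrow(fp)) {
    stop("host and parasite tables must cover the same populations (",
         nrow(fh), " vs ", nrow(fp), ")", call. = FALSE)
  }
  if (nrow(fh) < min_pops) {
    stop("need at least ", min_pops, " populations", call. = FALSE)
  }
}

#' Spatial covariance matrix between host and parasite allele frequencies
#'
#' Covariance across the N demes between every host-locus frequency and every
#' parasite-locus frequency, using the population normalization (divide by N).
#' The normalization cancels in the correlation, so downstream significance
#' calls do not depend on it; dividing by N keeps the matrix consistent with
#' the genotype-covariance decomposition of local adaptation (see
#' [local_adaptation_via_covariance()]).
#'
#' @param fh,fp Frequency tables (tibbles from [allele_frequencies()] or
#'   plain matrices) with matching deme order.
#' @return An `n_host_loci` x `n_par_loci` matrix; rows are host loci.
#' @export
covariance_matrix <- function(fh, fp) {
  H <- freq_matrix(fh)
  P <- freq_matrix(fp)
  check_paired_tables(H, P, min_pops = 2L)
  N <- nrow(H)
  crossprod(scale(H, center = TRUE, scale = FALSE),
            scale(P, center = TRUE, scale = FALSE)) / N
}

#' Spatial correlation matrix between host and parasite allele frequencies
#'
#' Transforms the covariance matrix into Pearson correlations. Pairs where
#' either locus is monomorphic across all demes (zero spatial variance) have
#' no defined correlation: they are returned as `NA` and flagged in the
#' `"undefined"` attribute.
#'
#' @inheritParams covariance_matrix
#' @return A matrix of correlations in `[-1, 1]` (or `NA`), with a logical
#'   attribute `"undefined"` of the same shape.
#' @export
correlation_matrix <- function(fh, fp) {
  H <- freq_matrix(fh)
  P <- freq_matrix(fp)
  check_paired_tables(H, P, min_pops = 3L)
  N <- nrow(H)
  C <- covariance_matrix(H, P)
  sd_h <- sqrt(colMeans(scale(H, center = TRUE, scale = FALSE)^2))
  sd_p <- sqrt(colMeans(scale(P, center = TRUE, scale = FALSE)^2))
  undefined <- outer(sd_h == 0, sd_p == 0, `|`)
  denom <- outer(sd_h, sd_p)
  rho <- C / denom
  rho[undefined] <- NA_real_
  # clamp floating-point overshoot
  rho[!undefined & rho > 1] <- 1
  rho[!undefined & rho < -1] <- -1
  attr(rho, "undefined") <- undefined
  rho
}

#' t statistic for a spatial correlation
#'
#' `t = rho * sqrt(N - 2) / sqrt(1 - rho^2)`, referred to a Student's
#' t-distribution with `N - 2` degrees of freedom. A correlation of exactly
#' +/-1 yields an infinite statistic (significant at any level).
#'
#' @param rho Correlation(s) in `[-1, 1]`; vectorized.
#' @param n_pops Number of populations N (>= 3).
#' @return t statistic(s), `Inf`/`-Inf` at `|rho| = 1`, `NA` propagated.
#' @export
t_statistic <- function(rho, n_pops) {
  if (n_pops < 3) stop("need n_pops >= 3 for a t statistic", call. = FALSE)
  out <- rho * sqrt(n_pops - 2) / sqrt(1 - rho^2)
  out[!is.na(rho) & rho >= 1] <- Inf
  out[!is.na(rho) & rho <= -1] <- -Inf
  out
}

#' Interspecific correlation scan for coevolving loci
#'
#' The core screening method: computes spatial covariances and correlations
#' between all host x parasite locus pairs, converts each correlation to a t
#' statistic with `N - 2` degrees of freedom, and flags pairs whose statistic
#' exceeds the critical value at level `alpha`. Because 0/1 allele labels are
#' arbitrary (relabeling flips the sign of a correlation), the test is
#' two-tailed by default. No multiple-testing correction is applied: the
#' screen is run at raw `alpha` and its operating characteristics are studied
#' via [classify_errors()] and the replicate harness.
#'
#' @inheritParams covariance_matrix
#' @param alpha Significance level in (0, 1).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param p_adjust Optional multiple-testing correction applied to the
#'   per-pair p-values before thresholding: any method accepted by
#'   [stats::p.adjust()] (e.g. `"bonferroni"`, `"BH"`). The default
#'   `"none"` is the screening regime whose operating characteristics the
#'   replicate harness studies.
#' @return An object of class `coev_scan` with matrices `cov`, `rho`, `t`,
#'   `p_value`, `significant` and `undefined`, plus `n_pops`, `alpha` and
#'   `alternative`. Use [tidy()] for the long per-pair table and [glance()]
#'   for a one-row summary.
#' @examples
#' set.seed(1)
#' sy <- synth_correlated_frequencies(n_pops = 30, n_host_loci = 5,
#'                                    n_par_loci = 5,
#'                                    true_pairs = data.frame(
#'                                      host_locus = 1, parasite_locus = 1,
#'                                      rho = 0.9))
#' sc <- coev_scan(sy$host, sy$parasite, alpha = 0.01)
#' dplyr::filter(tidy(sc), significant)
#' @export
coev_scan <- function(fh, fp, alpha = 0.01, alternative = "two.sided",
                      p_adjust = "none") {
  H <- freq_matrix(fh)
  P <- freq_matrix(fp)
  check_paired_tables(H, P, min_pops = 3L)
  rho <- correlation_matrix(H, P)
  undefined <- attr(rho, "undefined")
  attr(rho, "undefined") <- NULL
  N <- nrow(H)
  t <- t_statistic(rho, N)
  scan <- structure(
    list(cov = covariance_matrix(H, P), rho = rho, t = t,
         p_value = NULL, significant = NULL, undefined = undefined,
         n_pops = N, alpha = alpha, alternative = alternative),
    class = "coev_scan")
  p <- scan_p_values(t, N, alternative)
  if (!identical(p_adjust, "none")) {
    p[] <- stats::p.adjust(as.vector(p), method = p_adjust)
  }
  scan$p_value <- p
  scan$significant <- significant_pairs(scan, alpha)
  scan
}

scan_p_values <- function(t, n_pops, alternative = "two.sided") {
  df <- n_pops - 2
  switch(alternative,
    two.sided = 2 * pt(-abs(t), df),
    greater = pt(t, df, lower.tail = FALSE),
    less = pt(t, df),
    stop("unknown alternative: ", alternative, call. = FALSE))
}

#' Significance calls at a given level
#'
#' Recomputes the boolean significance matrix of a scan at level `alpha`:
#' a pair is significant when its p-value falls below `alpha` (equivalently,
#' for the two-tailed test, when `|t|` exceeds the critical value of the
#' t-distribution with `N - 2` degrees of freedom). Pairs with undefined
#' correlations are never significant.
#'
#' @param scan A `coev_scan` object.
#' @param alpha Significance level in (0, 1).
#' @return A logical matrix, same shape as `scan$rho`.
#' @export
significant_pairs <- function(scan, alpha) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("invalid `alpha`: must lie strictly between 0 and 1", call. = FALSE)
  }
  sig <- scan$p_value < alpha
  sig[is.na(sig)] <- FALSE
  sig
}

#' @export
print.coev_scan <- function(x, ...) {
  cat(sprintf("<coev_scan> %d host x %d parasite loci over %d populations\n",
              nrow(x$rho), ncol(x$rho), x$n_pops))
  cat(sprintf("  alpha = %g (%s): %d significant, %d undefined of %d pairs\n",
              x$alpha, x$alternative, sum(x$significant), sum(x$undefined),
              length(x$rho)))
  invisible(x)
}

#' Long per-pair table of a correlation scan
#'
#' @param x A `coev_scan` object.
#' @param ... Unused.
#' @return A tibble with one row per host x parasite locus pair: `host_locus`,
#'   `parasite_locus`, `covariance`, `correlation`, `t`, `p_value`,
#'   `significant`.
#' @export
tidy.coev_scan <- function(x, ...) {
  hl <- rownames(x$rho) %||% as.character(seq_len(nrow(x$rho)))
  pl <- colnames(x$rho) %||% as.character(seq_len(ncol(x$rho)))
  tibble::tibble(
    host_locus = rep(hl, times = length(pl)),
    parasite_locus = rep(pl, each = length(hl)),
    covariance = as.vector(x$cov),
    correlation = as.vector(x$rho),
    t = as.vector(x$t),
    p_value = as.vector(x$p_value),
    significant = as.vector(x$significant))
}

#' One-row summary of a correlation scan
#'
#' @param x A `coev_scan` object.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, `alpha`, counts of significant and
#'   undefined pairs, and the significant fraction.
#' @export
glance.coev_scan <- function(x, ...) {
  tibble::tibble(
    n_pops = x$n_pops,
    n_host_loci = nrow(x$rho),
    n_par_loci = ncol(x$rho),
    alpha = x$alpha,
    n_significant = sum(x$significant),
    n_undefined = sum(x$undefined),
    prop_significant = sum(x$significant) / length(x$significant))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_pair_matrix <- function(truth) {
  if (inherits(truth, "coev_arch")) return(truth$functional_pairs)
  if (is.data.frame(truth)) {
    return(cbind(host = as.integer(truth$host_locus),
                 parasite = as.integer(truth$parasite_locus)))
  }
  if (is.matrix(truth) && ncol(truth) == 2) return(truth)
  stop("truth must be a coev_arch, a two-column matrix, or a data frame ",
       "with host_locus/parasite_locus columns", call. = FALSE)
}

#' Score significance calls against the known functional pairs
#'
#' Type I errors are significant calls outside the truth set (between neutral
#' loci, or between coevolving loci that are not functionally paired); the
#' rate divides by the total possible number of such errors,
#' `n_host * n_par - n_functional` (undefined pairs stay in the denominator).
#' Type II errors are functional pairs not called significant; the rate
#' divides by the number of functional pairs. `full_detection` is `TRUE` only
#' when every functional pair is called -- partial identification counts as
#' failure.
#'
#' @param scan A `coev_scan` object, or a logical significance matrix.
#' @param truth A [coev_architecture()], a two-column index matrix, or a data
#'   frame with `host_locus` and `parasite_locus` columns (1-based indices).
#' @param alpha Optional level at which to re-threshold a `coev_scan` before
#'   scoring (defaults to the scan's own level).
#' @return A one-row tibble: `type1_count`, `type1_possible`, `type1_rate`,
#'   `type2_count`, `type2_possible`, `type2_rate`, `full_detection`, and a
#'   list-column `detected_pairs` holding the detected subset of the truth
#'   set.
#' @export
classify_errors <- function(scan, truth, alpha = NULL) {
  sig <- if (inherits(scan, "coev_scan")) {
    if (is.null(alpha)) scan$significant else significant_pairs(scan, alpha)
  } else {
    scan
  }
  pairs <- as_pair_matrix(truth)
  n_total <- length(sig)
  n_func <- nrow(pairs)
  truth_mask <- matrix(FALSE, nrow(sig), ncol(sig))
  truth_mask[pairs] <- TRUE
  type1_count <- sum(sig & !truth_mask)
  hit <- sig[pairs]
  type2_count <- sum(!hit)
  detected <- tibble::tibble(host_locus = pairs[hit, 1],
                             parasite_locus = pairs[hit, 2])
  tibble::tibble(
    type1_count = type1_count,
    type1_possible = n_total - n_func,
    type1_rate = type1_count / (n_total - n_func),
    type2_count = type2_count,
    type2_possible = n_func,
    type2_rate = type2_count / n_func,
    full_detection = all(hit),
    detected_pairs = list(detected))
}
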