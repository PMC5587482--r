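make_tables <- function(H, P) {
  list(
    h = tibble::as_tibble(cbind(
      tibble::tibble(population = paste0("pop", seq_len(nrow(H)))),
      tibble::as_tibble(`colnames<-`(H, sprintf("H%03d", seq_len(ncol(H))))))),
    p = tibble::as_tibble(cbind(
      tibble::tibble(population = paste0("pop", seq_len(nrow(P)))),
      tibble::as_tibble(`colnames<-`(P, sprintf("P%03d", seq_len(ncol(P))))))))
}

test_that("allele frequencies are census counts per deme and locus", {
  pops <- list(a = matrix(0L, 3, 4),
               b = rbind(c(0L, 1L, 1L, 0L), c(0L, 1L, 0L, 1L),
                         c(0L, 1L, 1L, 0L), c(0L, 1L, 0L, 1L)))
  ft <- allele_frequencies(pops)
  expect_equal(unname(unlist(ft[1, -1])), rep(0, 4))
  expect_equal(unname(unlist(ft[2, -1])), c(0, 1, 0.5, 0.5))
  expect_true(all(freq_matrix(ft) >= 0 & freq_matrix(ft) <= 1))
  expect_error(allele_frequencies(list(matrix(0L, 0, 3))), "empty")
  expect_error(allele_frequencies(list(matrix(0L, 2, 3), matrix(0L, 2, 4))),
               "locus count")
})

test_that("covariances match a direct summation oracle", {
  H <- cbind(c(0.1, 0.5, 0.9), c(0.3, 0.3, 0.3))
  P <- cbind(c(0.2, 0.4, 0.9), c(0.8, 0.1, 0.4))
  C <- covariance_matrix(H, P)
  # brute-force population covariance
  oracle <- function(x, y) mean(x * y) - mean(x) * mean(y)
  for (i in 1:2) for (j in 1:2) {
    expect_equal(C[i, j], oracle(H[, i], P[, j]), tolerance = 1e-12)
  }
  # constant parasite column -> zero column
  Pc <- cbind(P, rep(0.6, 3))
  expect_equal(unname(covariance_matrix(H, Pc)[, 3]), c(0, 0))
  # host column equal to parasite column -> entry equals that variance
  expect_equal(covariance_matrix(H, H)[1, 1], oracle(H[, 1], H[, 1]))
  expect_error(covariance_matrix(H, P[1:2, ]), "same populations")
})

test_that("correlations are bounded, signed, and undefined when monomorphic", {
  x <- c(0.1, 0.4, 0.8, 0.2)
  H <- cbind(x, rep(0.5, 4))
  P <- cbind(x, 1 - x)
  rho <- correlation_matrix(H, P)
  expect_equal(rho[1, 1], 1)
  expect_equal(rho[1, 2], -1)
  expect_true(is.na(rho[2, 1]))
  expect_true(attr(rho, "undefined")[2, 1])
  expect_true(all(abs(rho[!is.na(rho)]) <= 1))
})

test_that("the t statistic matches independent arithmetic", {
  # rho * sqrt(N - 2) / sqrt(1 - rho^2) evaluated independently
  expect_equal(t_statistic(0, 30), 0)
  expect_equal(t_statistic(0.5, 30), 0.5 * sqrt(28) / sqrt(0.75),
               tolerance = 1e-12)
  expect_equal(t_statistic(0.5, 30), 3.05505, tolerance = 1e-5)
  expect_equal(t_statistic(-0.7, 12), -t_statistic(0.7, 12))
  expect_equal(t_statistic(1, 10), Inf)
  expect_error(t_statistic(0.5, 2), "n_pops")
})

test_that("significance thresholds follow the t distribution with N-2 df", {
  # N = 40, alpha = 0.01 two-tailed: critical t(38) ~ 2.7116
  crit <- qt(1 - 0.01 / 2, df = 38)
  expect_equal(crit, 2.71156, tolerance = 1e-4)
  N <- 40
  rho_sig <- 0.44   # |t| = 3.02 > crit
  rho_ns <- 0.40    # |t| = 2.69 < crit
  set.seed(5)
  base <- rnorm(N)
  sy <- list()
  for (r in c(rho_sig, rho_ns)) {
    # build exact-correlation columns via QR trick
    e <- residuals(lm(rnorm(N) ~ base))
    y <- r * scale(base)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
    sy[[length(sy) + 1]] <- y
  }
  Hm <- matrix(scale(base)[, 1] / 10 + 0.5, ncol = 1)
  Pm <- cbind(sy[[1]] / 10 + 0.5, sy[[2]] / 10 + 0.5)
  sc <- coev_scan(Hm, Pm, alpha = 0.01)
  expect_equal(unname(sc$rho[1, ]), c(rho_sig, rho_ns), tolerance = 1e-10)
  expect_true(sc$significant[1, 1])
  expect_false(sc$significant[1, 2])
  expect_error(significant_pairs(sc, 1.5), "alpha")
  expect_error(significant_pairs(sc, 0), "alpha")
})

test_that("monomorphic loci are never significant but stay in the scan", {
  x <- c(0.1, 0.4, 0.8, 0.2, 0.6)
  H <- cbind(x, rep(0.3, 5))
  P <- cbind(x, x)
  sc <- coev_scan(H, P, alpha = 0.05)
  expect_true(all(!sc$significant[2, ]))
  expect_true(all(sc$undefined[2, ]))
  expect_equal(sum(sc$undefined), 2)
  td <- tidy(sc)
  expect_equal(nrow(td), 4)
  expect_true(all(is.na(td$correlation[td$host_locus == "2"])))
})

test_that("thresholding is monotone in |rho| for fixed N", {
  rhos <- seq(-0.95, 0.95, by = 0.05)
  p <- scan_p <- 2 * pt(-abs(t_statistic(rhos, 25)), 23)
  ord <- order(abs(rhos))
  expect_true(all(diff(p[ord]) <= 1e-12))
})

test_that("allele relabeling flips rho but preserves |t| and calls", {
  set.seed(8)
  sy <- synth_correlated_frequencies(20, 6, 6,
                                     true_pairs = data.frame(
                                       host_locus = 2, parasite_locus = 3,
                                       rho = 0.8))
  sc1 <- coev_scan(sy$host, sy$parasite, alpha = 0.05)
  flipped <- sy$parasite
  flipped[[4]] <- 1 - flipped[[4]]  # parasite locus 3 (after population col)
  sc2 <- coev_scan(sy$host, flipped, alpha = 0.05)
  expect_equal(sc2$rho[, 3], -sc1$rho[, 3])
  expect_equal(abs(sc2$t), abs(sc1$t))
  expect_equal(sc2$p_value, sc1$p_value)
  expect_identical(sc2$significant, sc1$significant)
})

test_that("the scan is invariant under joint deme permutation", {
  set.seed(9)
  sy <- synth_correlated_frequencies(15, 5, 5,
                                     true_pairs = data.frame(
                                       host_locus = 1, parasite_locus = 1,
                                       rho = 0.7))
  perm <- sample(15)
  sc1 <- coev_scan(sy$host, sy$parasite, alpha = 0.05)
  sc2 <- coev_scan(sy$host[perm, ], sy$parasite[perm, ], alpha = 0.05)
  expect_equal(sc2$rho, sc1$rho, tolerance = 1e-12)
  expect_identical(sc2$significant, sc1$significant)
})

test_that("error classification counts against the functional truth set", {
  sig <- matrix(FALSE, 4, 4)
  truth <- cbind(host = 2L, parasite = 3L)
  # nothing significant
  r0 <- classify_errors(sig, truth)
  expect_equal(r0$type1_rate, 0)
  expect_equal(r0$type2_rate, 1)
  expect_false(r0$full_detection)
  # only the functional pair significant
  sig[2, 3] <- TRUE
  r1 <- classify_errors(sig, truth)
  expect_equal(r1$type1_rate, 0)
  expect_equal(r1$type2_rate, 0)
  expect_true(r1$full_detection)
  expect_equal(nrow(r1$detected_pairs[[1]]), 1)
  # everything significant on a 100 x 100 scan with one functional pair
  all_sig <- matrix(TRUE, 100, 100)
  r2 <- classify_errors(all_sig, cbind(host = 7L, parasite = 9L))
  expect_equal(r2$type1_count, 9999)
  expect_equal(r2$type1_possible, 9999)
  expect_equal(r2$type1_rate, 1)
  expect_equal(r2$type2_rate, 0)
  # partial detection with multiple pairs is not full detection
  sig3 <- matrix(FALSE, 4, 4)
  sig3[1, 1] <- TRUE
  r3 <- classify_errors(sig3, cbind(host = c(1L, 2L), parasite = c(1L, 2L)))
  expect_equal(r3$type2_count, 1)
  expect_false(r3$full_detection)
})

test_that("optional p-value adjustment only removes calls", {
  set.seed(11)
  sy <- synth_correlated_frequencies(30, 8, 8,
                                     true_pairs = data.frame(
                                       host_locus = 1, parasite_locus = 1,
                                       rho = 0.95))
  raw <- coev_scan(sy$host, sy$parasite, alpha = 0.05)
  bonf <- coev_scan(sy$host, sy$parasite, alpha = 0.05,
                    p_adjust = "bonferroni")
  expect_true(all(bonf$p_value >= raw$p_value - 1e-15))
  expect_true(all(!(bonf$significant & !raw$significant)))
  expect_true(bonf$significant[1, 1])  # the strong planted pair survives
})

test_that("glance summarizes a scan in one row", {
  set.seed(10)
  sy <- synth_correlated_frequencies(12, 4, 3)
  g <- glance(coev_scan(sy$host, sy$parasite, alpha = 0.05))
  expect_equal(nrow(g), 1)
  expect_equal(g$n_host_loci, 4)
  expect_equal(g$n_par_loci, 3)
  expect_equal(g$n_pops, 12)
  expect_equal(g$prop_significant, g$n_significant / 12)
})
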