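test_that("initialization is symmetric and correctly shaped", {
  set.seed(10)
  p <- tiny_params(eta = 200, n_loci = 100)
  mp <- init_metapopulation(p)
  expect_length(mp$demes, 6)
  expect_equal(dim(mp$demes[[1]]$host), c(200, 100))
  expect_equal(dim(mp$demes[[3]]$parasite), c(200, 100))
  freqs <- unlist(lapply(mp$demes, function(d) mean(d$host)))
  expect_lt(abs(mean(freqs) - 0.5), 0.01)
  expect_true(all(unlist(mp$demes) %in% c(0L, 1L)))
})

test_that("phenotype is the scaled count of 1 alleles", {
  expect_equal(phenotype(rep(0, 10), c(2, 5)), 0)
  expect_equal(phenotype(rep(1, 10), c(2, 5)), 1)
  expect_equal(phenotype(c(1, 0, 0, 0), c(1, 2)), 0.5)
  expect_error(phenotype(c(1, 0), integer(0)), "nonempty")
})

test_that("infection probability matches both models' closed forms", {
  a <- coev_architecture(4, 4, 2, "discrete_matching",
                         host_idx = c(1, 2), par_idx = c(1, 2))
  # perfect match
  expect_equal(infection_probability(c(1, 1, 0, 0), c(1, 1, 0, 0),
                                     "discrete_matching", 0.9, a), 1)
  # total mismatch: 1 - beta
  expect_equal(infection_probability(c(1, 1, 0, 0), c(0, 0, 0, 0),
                                     "discrete_matching", 0.9, a), 0.1)
  # half mismatch
  expect_equal(infection_probability(c(1, 0, 0, 0), c(0, 0, 0, 0),
                                     "discrete_matching", 0.8, a), 0.6)
  aq <- coev_architecture(4, 4, 1, "quantitative_matching",
                          host_idx = 1, par_idx = 1)
  expect_equal(infection_probability(c(1, 0, 0, 0), c(1, 0, 0, 0),
                                     "quantitative_matching", 2, aq), 1)
  expect_equal(infection_probability(c(1, 0, 0, 0), c(0, 0, 0, 0),
                                     "quantitative_matching", 2, aq),
               exp(-2))
  expect_error(infection_probability(c(1, 0), c(1, 0), "discrete_matching",
                                     1.2, aq), "beta")
})

test_that("selection survival matches the fitness rules", {
  set.seed(21)
  a <- coev_architecture(5, 5, 1, "discrete_matching", host_idx = 3,
                         par_idx = 3)
  host <- mono_pop(c(0, 0, 1, 0, 0), 4000)
  par_match <- mono_pop(c(0, 0, 1, 0, 0), 4000)
  # P = 1 everywhere, s = 0.6: host survival ~ 0.4, parasite survival 1
  res <- encounter_and_select(host, par_match, "discrete_matching",
                              beta = 0.9, s = 0.6, a)
  expect_lt(abs(nrow(res$host) / 4000 - 0.4), 0.03)
  expect_equal(nrow(res$parasite), 4000)
  # P = 0 everywhere (total mismatch, beta = 1): all hosts, no parasites
  par_mism <- mono_pop(c(0, 0, 0, 0, 0), 4000)
  res0 <- encounter_and_select(host, par_mism, "discrete_matching",
                               beta = 1, s = 0.6, a)
  expect_equal(nrow(res0$host), 4000)
  expect_equal(nrow(res0$parasite), 0)
  # matched monomorphic populations: P = 1 regardless of beta, so host
  # survival ~ 1 - s and parasite survival ~ 1
  res2 <- encounter_and_select(host, par_match, "discrete_matching",
                               beta = 0.8, s = 0.5, a)
  expect_lt(abs(nrow(res2$host) / 4000 - 0.5), 0.03)
  expect_lt(abs(nrow(res2$parasite) / 4000 - 1.0), 1e-9)
  # survivors are subsets of input rows
  expect_true(all(attr(res$host, "idx") %in% seq_len(4000)))
})

test_that("selection under mismatch matches Monte-Carlo expectations", {
  set.seed(22)
  a <- coev_architecture(3, 3, 1, "discrete_matching", host_idx = 1,
                         par_idx = 1)
  host <- mono_pop(c(1, 0, 0), 5000)
  par <- mono_pop(c(0, 0, 0), 5000)  # mismatched: P = 1 - 0.8 = 0.2
  res <- encounter_and_select(host, par, "discrete_matching", beta = 0.8,
                              s = 0.5, a)
  expect_lt(abs(nrow(res$host) / 5000 - 0.9), 0.02)      # 1 - 0.5 * 0.2
  expect_lt(abs(nrow(res$parasite) / 5000 - 0.2), 0.02)  # W_p = P
})

test_that("reproduction returns eta offspring built from parental gametes", {
  set.seed(30)
  g <- matrix(c(1, 0, 1, 0, 1, 0), nrow = 2, ncol = 6, byrow = TRUE)
  g[2, ] <- g[1, ]
  off <- reproduce(g, r = rep(0.3, 5), eta = 10)
  expect_equal(dim(off), c(10, 6))
  for (i in 1:10) expect_equal(off[i, ], g[1, ])  # identical parents

  # r = 0: every offspring equals one parent exactly
  ab <- rbind(rep(0L, 8), rep(1L, 8))
  off0 <- reproduce(ab, r = rep(0, 7), eta = 50)
  expect_true(all(rowSums(off0) %in% c(0, 8)))

  # r = 0.5 with all-0 / all-1 parents: source switches are visible as
  # allele changes; mean switch count ~ 0.5 * (n_loci - 1) among offspring
  # with distinct parents (half of them; same-parent draws show 0 switches)
  set.seed(31)
  n <- 20000
  offr <- reproduce(ab, r = rep(0.5, 7), eta = n)
  switches <- rowSums(abs(offr[, -1, drop = FALSE] -
                            offr[, -8, drop = FALSE]))
  # Expected switches for a gamete with two distinct parents: 0.5 * 7; for
  # same-parent draws 0. Parents are drawn with replacement so half the
  # offspring have distinct parents: overall expectation 1.75.
  expect_lt(abs(mean(switches) - 0.5 * 7 / 2), 0.1)

  # fallback pool when fewer than two survivors remain
  empty <- ab[integer(0), , drop = FALSE]
  offf <- reproduce(empty, r = rep(0, 7), eta = 5, fallback = ab)
  expect_equal(dim(offf), c(5, 8))
})

test_that("mutation flips at most one locus per genome", {
  set.seed(40)
  pop <- matrix(0L, 100, 10)
  expect_identical(mutate_genomes(pop, 0), pop)
  m1 <- mutate_genomes(pop, 1)
  expect_true(all(rowSums(abs(m1 - pop)) == 1))
  # binomial expectation: mu = 0.04, eta = 250 -> ~10 flipped genomes
  flips <- replicate(200, {
    sum(rowSums(abs(mutate_genomes(matrix(0L, 250, 10), 0.04))) > 0)
  })
  expect_lt(abs(mean(flips) - 10), 0.5)
})

test_that("migration conserves individuals and halves edge-deme rates", {
  set.seed(50)
  p <- tiny_params(n_pops = 5, eta = 100, n_loci = 6, generations = 0)
  mp <- init_metapopulation(p)
  # m = 0: no-op
  expect_identical(migrate(mp, 0, 0)$demes, mp$demes)
  # single deme: no-op at any m
  p1 <- tiny_params(n_pops = 1, eta = 20, n_loci = 6, generations = 0)
  mp1 <- init_metapopulation(p1)
  expect_identical(migrate(mp1, 0.5, 0.5)$demes, mp1$demes)

  # conservation: deme sizes unchanged, species-wide genome multiset intact
  moved <- migrate(mp, 0.3, 0.1)
  expect_true(all(vapply(moved$demes, function(d) nrow(d$host), 0L) == 100))
  before <- genome_multiset(do.call(rbind, lapply(mp$demes, `[[`, "host")))
  after <- genome_multiset(do.call(rbind, lapply(moved$demes, `[[`, "host")))
  expect_identical(before, after)

  # expected emigrants: interior ~ 2 per generation at m = 0.01, eta = 200;
  # edge ~ 1 (tag individuals by unique genomes and count moves out)
  set.seed(51)
  n_reps <- 400
  interior <- edge <- 0
  pe <- sim_params(n_pops = 3, n_loci_host = 18, n_loci_par = 2,
                   eta_host = 200, eta_par = 2, generations = 0,
                   n_coev = 1, m_host = 0.01)
  for (rep in 1:n_reps) {
    demes <- lapply(1:3, function(k) {
      host <- matrix(0L, 200, 18)
      host[, k] <- 1L  # deme-of-origin tag
      list(host = host, parasite = matrix(0L, 2, 2))
    })
    mp3 <- manual_metapop(demes, coev_architecture(18, 2, 1,
                                                   "discrete_matching",
                                                   host_idx = 10,
                                                   par_idx = 1), pe)
    out <- migrate(mp3, 0.01, 0)
    interior <- interior + sum(out$demes[[1]]$host[, 2]) +
      sum(out$demes[[3]]$host[, 2])
    edge <- edge + sum(out$demes[[2]]$host[, 1]) +
      sum(out$demes[[2]]$host[, 3])
  }
  # deme 2 (interior) expects 2 emigrants/gen; demes 1 and 3 (edges) 1 each
  expect_lt(abs(interior / n_reps - 2), 0.2)
  expect_lt(abs(edge / n_reps - 2), 0.2)  # two edges x 1 emigrant
})

test_that("a full run is deterministic, binary, and size-conserving", {
  p <- tiny_params(generations = 15, seed = 123)
  mp1 <- run_simulation(p)
  mp2 <- run_simulation(p)
  expect_identical(mp1$demes, mp2$demes)
  expect_identical(mp1$arch$host_idx, mp2$arch$host_idx)
  for (d in mp1$demes) {
    expect_true(all(d$host %in% c(0L, 1L)))
    expect_equal(nrow(d$host), p$eta_host)
    expect_equal(nrow(d$parasite), p$eta_par)
  }
  # generations = 0 returns the initialized state
  p0 <- tiny_params(generations = 0, seed = 9)
  mp0 <- run_simulation(p0)
  freqs <- colMeans(do.call(rbind, lapply(mp0$demes, `[[`, "host")))
  expect_lt(abs(mean(freqs) - 0.5), 0.05)
})

test_that("with beta = 0 coevolving loci drift like neutral loci", {
  # no infection differential => no selection on anything; compare the
  # across-deme variance of the coevolving locus frequency with that of
  # neutral loci, averaged over replicates
  set.seed(60)
  n_rep <- 30
  coev_var <- neut_var <- numeric(n_rep)
  for (i in 1:n_rep) {
    p <- tiny_params(n_pops = 8, eta = 50, n_loci = 20, generations = 40,
                     beta = 0, s = 0.8, m_host = 0.002, m_par = 0.002)
    mp <- run_simulation(p)
    fh <- freq_matrix_for_tests(mp, "host")
    vs <- apply(fh, 2, var)
    coev_var[i] <- vs[mp$arch$host_idx]
    neut_var[i] <- mean(vs[-mp$arch$host_idx])
  }
  se <- sd(coev_var - neut_var) / sqrt(n_rep)
  expect_lt(abs(mean(coev_var) - mean(neut_var)), 3 * se + 1e-12)
})

test_that("under pure drift heterozygosity decays at rate 1/eta", {
  set.seed(61)
  eta <- 40
  gens <- 40
  n_rep <- 25
  ratio <- numeric(n_rep)
  for (i in 1:n_rep) {
    p <- sim_params(n_pops = 1, n_loci_host = 30, n_loci_par = 30,
                    n_coev = 1, beta = 0, s = 0, eta_host = eta,
                    eta_par = 2, mu_host = 0, mu_par = 0, m_host = 0,
                    m_par = 0, r_host = 0.5, r_par = 0.5,
                    generations = gens)
    mp <- run_simulation(p)
    f0 <- 0.5  # initialization frequency
    f <- colMeans(mp$demes[[1]]$host)
    ratio[i] <- mean(2 * f * (1 - f)) / (2 * f0 * 0.5)
  }
  expected <- (1 - 1 / eta)^gens
  se <- sd(ratio) / sqrt(n_rep)
  expect_lt(abs(mean(ratio) - expected), 3 * se + 0.02)
})

test_that("realized infection rates match the pairing expectation", {
  set.seed(62)
  p <- tiny_params(n_pops = 2, eta = 300, n_loci = 10, generations = 5)
  mp <- run_simulation(p)
  # exact expectation over all ordered pairs vs large resampling
  Px <- cross_infection_matrix(mp, mode = "exact")
  Ps <- cross_infection_matrix(mp, mode = "sampled", sample_size = 40000)
  se <- sqrt(0.25 / 40000)
  expect_lt(max(abs(Px - Ps)), 4 * se)
})
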