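# Replicate records used by the acceptance-level tests. Built once per test
# run and cached: full-scale simulations (100 loci per species, 40 demes,
# 500 generations) are expensive, and several tests condition on different
# local-adaptation bins of the same record pools.
#
# Strong parasite local adaptation arises when the parasite's evolutionary
# potential exceeds the host's, so bin filling is accelerated by biasing the
# migration draws (low host movement, high parasite movement) while keeping
# every other parameter on its default uniform range. Downstream power and
# error summaries condition on the realized L bin, not on the prior.

.record_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .record_cache)) {
    assign(key, build(), envir = .record_cache)
  }
  get(key, envir = .record_cache)
}

strong_records_discrete <- function() {
  cached("strong_discrete", function() {
    set.seed(20260101)
    rg <- parameter_ranges("discrete_matching",
                           m_host = c(0, 0.0005), m_par = c(0.006, 0.01))
    accumulate_bins(rg, n_coev = 1, n_pops = 40, min_per_bin = 10,
                    alpha_grid = c(0.001, 0.01), target_bins = "strong",
                    max_draws = 80)
  })
}

moderate_records_discrete <- function() {
  cached("moderate_discrete", function() {
    set.seed(20260202)
    rg <- parameter_ranges("discrete_matching",
                           m_host = c(0, 0.002), m_par = c(0.004, 0.01))
    accumulate_bins(rg, n_coev = 1, n_pops = 40, min_per_bin = 6,
                    alpha_grid = c(0.001, 0.01), target_bins = "moderate",
                    max_draws = 60)
  })
}

moderate_records_quantitative <- function() {
  cached("moderate_quant", function() {
    set.seed(20260303)
    rg <- parameter_ranges("quantitative_matching",
                           m_host = c(0, 0.002), m_par = c(0.004, 0.01))
    accumulate_bins(rg, n_coev = 1, n_pops = 40, min_per_bin = 6,
                    alpha_grid = c(0.001, 0.01), target_bins = "moderate",
                    max_draws = 60)
  })
}

# Union of all full-scale records (spans bins; used for the type I error
# versus L relationship).
all_fullscale_records <- function() {
  c(strong_records_discrete(), moderate_records_discrete(),
    moderate_records_quantitative())
}

bin_of <- function(records) vapply(records, function(r) r$bin, "")

detected_at <- function(records, alpha) {
  vapply(records, function(r) {
    r$errors$full_detection[r$errors$alpha == alpha]
  }, TRUE)
}

type1_at <- function(records, alpha) {
  vapply(records, function(r) {
    r$errors$type1_rate[r$errors$alpha == alpha]
  }, 0)
}
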