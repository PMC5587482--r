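#include <Rcpp.h>
#include <R_ext/Random.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Haploid binary genomes, individual-major storage.
//
// Randomness: the generation loop burns ~1e9 uniforms per full-scale run
// (one per adjacent-locus interval per gamete), so the engine uses an
// internal xoshiro256++ stream. The stream is (re)seeded from R's RNG at
// every entry point, so set.seed() on the R side still gives bit-identical
// runs.

namespace {

static uint64_t rng_s[4];

inline uint64_t rotl64(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

inline uint64_t next_u64() {
  const uint64_t result = rotl64(rng_s[0] + rng_s[3], 23) + rng_s[0];
  const uint64_t t = rng_s[1] << 17;
  rng_s[2] ^= rng_s[0];
  rng_s[3] ^= rng_s[1];
  rng_s[1] ^= rng_s[2];
  rng_s[0] ^= rng_s[3];
  rng_s[2] ^= t;
  rng_s[3] = rotl64(rng_s[3], 45);
  return result;
}

inline double next_unif() { return (next_u64() >> 11) * 0x1.0p-53; }

// uniform on {0, ..., n-1}; n is at most a few hundred here so the modulo
// bias of the double path is negligible and floor(u * n) < n always holds.
inline int next_index(int n) { return (int)(next_unif() * n); }

uint64_t splitmix64(uint64_t& x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// Pull 64 bits of entropy from R's RNG and expand into the xoshiro state.
void seed_from_R() {
  uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t seed = (hi << 32) ^ lo;
  for (int i = 0; i < 4; ++i) rng_s[i] = splitmix64(seed);
}

struct Pop {
  int n = 0;
  int L = 0;
  std::vector<uint8_t> g;  // g[i * L + l]
  const uint8_t* row(int i) const { return g.data() + (size_t)i * L; }
  uint8_t* row(int i) { return g.data() + (size_t)i * L; }
};

enum Model { DISCRETE = 0, QUANTITATIVE = 1 };

Pop pop_from_matrix(const IntegerMatrix& m) {
  Pop p;
  p.n = m.nrow();
  p.L = m.ncol();
  p.g.resize((size_t)p.n * p.L);
  for (int i = 0; i < p.n; ++i)
    for (int l = 0; l < p.L; ++l) p.g[(size_t)i * p.L + l] = (uint8_t)m(i, l);
  return p;
}

IntegerMatrix matrix_from_pop(const Pop& p) {
  IntegerMatrix m(p.n, p.L);
  for (int i = 0; i < p.n; ++i)
    for (int l = 0; l < p.L; ++l) m(i, l) = p.g[(size_t)i * p.L + l];
  return m;
}

// Infection probability for one host-parasite encounter. Only the
// coevolving loci enter; indices are 0-based here.
double infect_prob(const uint8_t* h, const uint8_t* p, int model, double beta,
                   const std::vector<int>& hidx, const std::vector<int>& pidx) {
  const int k = (int)hidx.size();
  if (model == DISCRETE) {
    int mismatch = 0;
    for (int j = 0; j < k; ++j)
      if (h[hidx[j]] != p[pidx[j]]) ++mismatch;
    return 1.0 - beta * ((double)mismatch / k);
  }
  int ch = 0, cp = 0;
  for (int j = 0; j < k; ++j) {
    ch += h[hidx[j]];
    cp += p[pidx[j]];
  }
  const double delta = ((double)ch - (double)cp) / k;
  return std::exp(-beta * delta * delta);
}

// Species interaction stage: every individual of each species meets one
// randomly drawn partner of the other species (uniform, with replacement)
// and survives a Bernoulli draw on its fitness: W_h = 1 - s * P for hosts,
// W_p = P for parasites. Returns surviving row indices.
void encounter_select(const Pop& host, const Pop& par, int model, double beta,
                      double s, const std::vector<int>& hidx,
                      const std::vector<int>& pidx,
                      std::vector<int>& host_surv, std::vector<int>& par_surv) {
  host_surv.clear();
  par_surv.clear();
  for (int i = 0; i < host.n; ++i) {
    int j = next_index(par.n);
    double P = infect_prob(host.row(i), par.row(j), model, beta, hidx, pidx);
    if (next_unif() <= 1.0 - s * P) host_surv.push_back(i);
  }
  for (int j = 0; j < par.n; ++j) {
    int i = next_index(host.n);
    double P = infect_prob(host.row(i), par.row(j), model, beta, hidx, pidx);
    if (next_unif() <= P) par_surv.push_back(j);
  }
}

// Sexual reproduction back to census size eta: each offspring takes two
// parents uniformly with replacement from the survivor pool, the gamete
// starts on a random parent and switches parental source between adjacent
// loci l-1, l with probability r[l-1]. If fewer than two survivors remain
// the pre-selection population serves as the parent pool.
Pop reproduce(const Pop& pop, const std::vector<int>& pool,
              const std::vector<double>& r, int eta) {
  const int L = pop.L;
  const std::vector<int>* parents = &pool;
  std::vector<int> all;
  if ((int)pool.size() < 2) {
    all.resize(pop.n);
    for (int i = 0; i < pop.n; ++i) all[i] = i;
    parents = &all;
  }
  const int np = (int)parents->size();
  Pop off;
  off.n = eta;
  off.L = L;
  off.g.resize((size_t)eta * L);
  for (int i = 0; i < eta; ++i) {
    const uint8_t* a = pop.row((*parents)[next_index(np)]);
    const uint8_t* b = pop.row((*parents)[next_index(np)]);
    uint8_t* o = off.row(i);
    int cur = (next_unif() < 0.5) ? 0 : 1;
    o[0] = cur ? b[0] : a[0];
    for (int l = 1; l < L; ++l) {
      if (next_unif() < r[l - 1]) cur ^= 1;
      o[l] = cur ? b[l] : a[l];
    }
  }
  return off;
}

// Per-genome mutation: with probability mu exactly one uniformly chosen
// locus flips to the alternative allele.
void mutate(Pop& pop, double mu) {
  if (mu <= 0) return;
  for (int i = 0; i < pop.n; ++i) {
    if (next_unif() < mu) {
      int l = next_index(pop.L);
      pop.row(i)[l] ^= 1;
    }
  }
}

// Linear stepping-stone migration with symmetric swaps. Each edge (k, k+1)
// is processed once, left to right: every individual of deme k initiates a
// swap with probability m/2 and exchanges places with a uniformly chosen
// individual of deme k+1. Interior demes sit on two edges and so see twice
// the per-edge exchange rate of the two terminal demes.
void migrate(std::vector<Pop>& demes, double m) {
  if (m <= 0 || demes.size() < 2) return;
  const double half = m / 2.0;
  const int L = demes[0].L;
  for (size_t k = 0; k + 1 < demes.size(); ++k) {
    Pop& a = demes[k];
    Pop& b = demes[k + 1];
    for (int i = 0; i < a.n; ++i) {
      if (next_unif() < half) {
        int j = next_index(b.n);
        uint8_t* ra = a.row(i);
        uint8_t* rb = b.row(j);
        for (int l = 0; l < L; ++l) std::swap(ra[l], rb[l]);
      }
    }
  }
}

std::vector<int> to_index0(const IntegerVector& idx1) {
  std::vector<int> out(idx1.size());
  for (int i = 0; i < idx1.size(); ++i) out[i] = idx1[i] - 1;
  return out;
}

std::vector<double> to_vec(const NumericVector& x) {
  return std::vector<double>(x.begin(), x.end());
}

}  // namespace

// [[Rcpp::export(name = ".cpp_infection_probability")]]
double cpp_infection_probability(IntegerVector host_genome,
                                 IntegerVector par_genome, int model,
                                 double beta, IntegerVector host_idx,
                                 IntegerVector par_idx) {
  std::vector<uint8_t> h(host_genome.begin(), host_genome.end());
  std::vector<uint8_t> p(par_genome.begin(), par_genome.end());
  return infect_prob(h.data(), p.data(), model, beta, to_index0(host_idx),
                     to_index0(par_idx));
}

// [[Rcpp::export(name = ".cpp_encounter_select")]]
List cpp_encounter_select(IntegerMatrix host, IntegerMatrix par, int model,
                          double beta, double s, IntegerVector host_idx,
                          IntegerVector par_idx) {
  seed_from_R();
  Pop h = pop_from_matrix(host), p = pop_from_matrix(par);
  std::vector<int> hs, ps;
  encounter_select(h, p, model, beta, s, to_index0(host_idx),
                   to_index0(par_idx), hs, ps);
  IntegerVector hi(hs.size()), pi(ps.size());
  for (size_t i = 0; i < hs.size(); ++i) hi[i] = hs[i] + 1;
  for (size_t i = 0; i < ps.size(); ++i) pi[i] = ps[i] + 1;
  return List::create(_["host"] = hi, _["parasite"] = pi);
}

// [[Rcpp::export(name = ".cpp_reproduce")]]
IntegerMatrix cpp_reproduce(IntegerMatrix pop, IntegerVector survivors,
                            NumericVector r, int eta) {
  seed_from_R();
  Pop p = pop_from_matrix(pop);
  return matrix_from_pop(reproduce(p, to_index0(survivors), to_vec(r), eta));
}

// [[Rcpp::export(name = ".cpp_mutate")]]
IntegerMatrix cpp_mutate(IntegerMatrix pop, double mu) {
  seed_from_R();
  Pop p = pop_from_matrix(pop);
  mutate(p, mu);
  return matrix_from_pop(p);
}

// [[Rcpp::export(name = ".cpp_migrate")]]
List cpp_migrate(List demes, double m) {
  seed_from_R();
  const int N = demes.size();
  std::vector<Pop> pops(N);
  for (int k = 0; k < N; ++k) pops[k] = pop_from_matrix(demes[k]);
  migrate(pops, m);
  List out(N);
  for (int k = 0; k < N; ++k) out[k] = matrix_from_pop(pops[k]);
  out.attr("names") = demes.attr("names");
  return out;
}

// [[Rcpp::export(name = ".cpp_run_generations")]]
List cpp_run_generations(List host_demes, List par_demes, int model,
                         double beta, double s, IntegerVector host_idx,
                         IntegerVector par_idx, NumericVector r_host,
                         NumericVector r_par, double mu_host, double mu_par,
                         double m_host, double m_par, int generations) {
  seed_from_R();
  const int N = host_demes.size();
  std::vector<Pop> hosts(N), pars(N);
  for (int k = 0; k < N; ++k) {
    hosts[k] = pop_from_matrix(host_demes[k]);
    pars[k] = pop_from_matrix(par_demes[k]);
  }
  const std::vector<int> hidx = to_index0(host_idx), pidx = to_index0(par_idx);
  const std::vector<double> rh = to_vec(r_host), rp = to_vec(r_par);
  std::vector<int> hs, ps;

  for (int gen = 0; gen < generations; ++gen) {
    // (1) species interactions  (2) reproduction  (3) mutation
    for (int k = 0; k < N; ++k) {
      encounter_select(hosts[k], pars[k], model, beta, s, hidx, pidx, hs, ps);
      hosts[k] = reproduce(hosts[k], hs, rh, hosts[k].n);
      pars[k] = reproduce(pars[k], ps, rp, pars[k].n);
      mutate(hosts[k], mu_host);
      mutate(pars[k], mu_par);
    }
    // (4) migration
    migrate(hosts, m_host);
    migrate(pars, m_par);
    if (gen % 50 == 0) Rcpp::checkUserInterrupt();
  }

  List oh(N), op(N);
  for (int k = 0; k < N; ++k) {
    oh[k] = matrix_from_pop(hosts[k]);
    op[k] = matrix_from_pop(pars[k]);
  }
  return List::create(_["host"] = oh, _["parasite"] = op);
}
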