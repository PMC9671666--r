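// Forward Wright-Fisher simulator of deleterious-load dynamics.
//
// Diploid individual-based model with a sparse representation: each
// haplotype stores the sorted indices of loci carrying the deleterious
// (derived) allele. Fitness is multiplicative across loci,
//   w = prod (1 - h s_l)^[het] (1 - s_l)^[hom],
// parents are sampled proportional to fitness, sexual offspring arise from
// two free-recombination gametes, clonal (apomictic) offspring copy the
// mother's diploid genotype; facultative apomixis clones with probability
// 1 - sigma. Mutation adds Poisson(L u) new deleterious alleles per gamete
// (clonal offspring receive Poisson(2 L u)). Loci fixed in every
// population are folded into a permanent log-fitness term and recycled
// (infinite-sites approximation at finite L).
//
// The simulator owns a mt19937_64 RNG so runs are reproducible across
// platforms independent of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

typedef std::vector<int> Hap;

struct Ind {
  Hap h1, h2;
};

struct Pop {
  std::vector<Ind> inds;
  double fixed_logw = 0.0;
};

struct Sim {
  std::mt19937_64 rng;
  int L = 0;
  double u = 0.0;   // per-locus per-haplotype mutation rate
  double h = 0.0;
  std::vector<double> s;
  bool gamma_dfe = false;
  double gamma_shape = 1.0, gamma_mean = 0.05, s_fixed = 0.05;
  std::map<std::string, Pop> pops;
  uint64_t bitpool = 0;
  int bitcount = 0;

  bool coin() {
    if (bitcount == 0) { bitpool = rng(); bitcount = 64; }
    bool b = bitpool & 1u;
    bitpool >>= 1;
    --bitcount;
    return b;
  }
  double unif() {
    return std::generate_canonical<double, 53>(rng);
  }
  double draw_s() {
    if (!gamma_dfe) return s_fixed;
    std::gamma_distribution<double> g(gamma_shape, gamma_mean / gamma_shape);
    double v = g(rng);
    return v > 1.0 ? 1.0 : v;
  }
};

static Sim* get(SEXP ptr) {
  Rcpp::XPtr<Sim> p(ptr);
  return p.get();
}

// count het / hom loci of an individual (two-pointer merge)
static inline void het_hom(const Ind& ind, int& het, int& hom,
                           const std::vector<double>& s, double hcoef,
                           double* logw) {
  size_t i = 0, j = 0;
  het = 0; hom = 0;
  double lw = 0.0;
  const Hap& a = ind.h1; const Hap& b = ind.h2;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) {
      ++hom; lw += std::log(1.0 - s[a[i]]); ++i; ++j;
    } else if (a[i] < b[j]) {
      ++het; lw += std::log(1.0 - hcoef * s[a[i]]); ++i;
    } else {
      ++het; lw += std::log(1.0 - hcoef * s[b[j]]); ++j;
    }
  }
  for (; i < a.size(); ++i) { ++het; lw += std::log(1.0 - hcoef * s[a[i]]); }
  for (; j < b.size(); ++j) { ++het; lw += std::log(1.0 - hcoef * s[b[j]]); }
  if (logw) *logw = lw;
}

// gamete with free recombination: hom loci always transmitted, het loci
// with probability 1/2, plus Poisson(L u) fresh mutations
static Hap gamete(Sim* S, const Ind& par) {
  Hap g;
  g.reserve(par.h1.size());
  size_t i = 0, j = 0;
  const Hap& a = par.h1; const Hap& b = par.h2;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) { g.push_back(a[i]); ++i; ++j; }
    else if (a[i] < b[j]) { if (S->coin()) g.push_back(a[i]); ++i; }
    else { if (S->coin()) g.push_back(b[j]); ++j; }
  }
  for (; i < a.size(); ++i) if (S->coin()) g.push_back(a[i]);
  for (; j < b.size(); ++j) if (S->coin()) g.push_back(b[j]);
  return g;
}

static void mutate_hap(Sim* S, Hap& g) {
  std::poisson_distribution<int> pois(S->u * S->L);
  int nmut = pois(S->rng);
  for (int m = 0; m < nmut; ++m) {
    int locus = (int)(S->unif() * S->L);
    if (locus >= S->L) locus = S->L - 1;
    Hap::iterator it = std::lower_bound(g.begin(), g.end(), locus);
    if (it == g.end() || *it != locus) g.insert(it, locus);
  }
}

static std::vector<double> fitnesses(Sim* S, Pop& pop) {
  std::vector<double> w(pop.inds.size());
  int het, hom;
  double lw;
  for (size_t k = 0; k < pop.inds.size(); ++k) {
    het_hom(pop.inds[k], het, hom, S->s, S->h, &lw);
    w[k] = std::exp(lw);
  }
  return w;
}

// one generation; parent pools allow the introgression pulse (each parent
// drawn from the donor pool with probability f)
static void next_generation(Sim* S, Pop& pop, const std::string& mode,
                            double sigma, Pop* donor, double f, int gen_idx) {
  std::vector<double> w = fitnesses(S, pop);
  double tot = 0.0;
  for (double x : w) tot += x;
  if (tot <= 0.0)
    stop("population extinct (all fitness zero) at generation %d", gen_idx);
  std::discrete_distribution<int> pick(w.begin(), w.end());

  std::vector<double> wd;
  std::discrete_distribution<int> pickd;
  if (donor) {
    wd = fitnesses(S, *donor);
    pickd = std::discrete_distribution<int>(wd.begin(), wd.end());
  }

  size_t N = pop.inds.size();
  std::vector<Ind> next(N);
  for (size_t k = 0; k < N; ++k) {
    bool sexual = (mode == "sexual");
    if (!sexual && sigma > 0.0)
      sexual = (sigma >= 1.0) ? true : (S->unif() < sigma);
    // draw a parent from the donor pool with probability f
    Pop* pm = (donor && S->unif() < f) ? donor : &pop;
    const Ind& mother = (pm == donor) ? donor->inds[pickd(S->rng)]
                                      : pop.inds[pick(S->rng)];
    if (sexual) {
      Pop* pf = (donor && S->unif() < f) ? donor : &pop;
      const Ind& father = (pf == donor) ? donor->inds[pickd(S->rng)]
                                        : pop.inds[pick(S->rng)];
      next[k].h1 = gamete(S, mother);
      next[k].h2 = gamete(S, father);
    } else {
      next[k].h1 = mother.h1;
      next[k].h2 = mother.h2;
    }
    mutate_hap(S, next[k].h1);
    mutate_hap(S, next[k].h2);
  }
  pop.inds.swap(next);
}

// fold loci fixed (hom in every individual of every population) into the
// permanent fitness term and free them for reuse
static void purge_fixed(Sim* S) {
  std::vector<int> cnt(S->L, 0);
  long total_haps = 0;
  for (auto& pp : S->pops) {
    total_haps += 2 * (long)pp.second.inds.size();
    for (auto& ind : pp.second.inds) {
      for (int l : ind.h1) cnt[l]++;
      for (int l : ind.h2) cnt[l]++;
    }
  }
  std::vector<char> fixed(S->L, 0);
  bool any = false;
  for (int l = 0; l < S->L; ++l)
    if (cnt[l] == total_haps && total_haps > 0) { fixed[l] = 1; any = true; }
  if (!any) return;
  for (auto& pp : S->pops) {
    double add = 0.0;
    for (int l = 0; l < S->L; ++l)
      if (fixed[l]) add += std::log(1.0 - S->s[l]);
    pp.second.fixed_logw += add;
    for (auto& ind : pp.second.inds) {
      Hap nh;
      for (int l : ind.h1) if (!fixed[l]) nh.push_back(l);
      ind.h1.swap(nh);
      Hap nh2;
      for (int l : ind.h2) if (!fixed[l]) nh2.push_back(l);
      ind.h2.swap(nh2);
    }
  }
  for (int l = 0; l < S->L; ++l)
    if (fixed[l]) S->s[l] = S->draw_s();
}

// [[Rcpp::export(name = ".fwd_new")]]
SEXP fwd_new(int L, double u, double h, double s_fixed, bool gamma_dfe,
             double gamma_shape, double gamma_mean, int seed) {
  Sim* S = new Sim();
  S->rng.seed((uint64_t)seed);
  S->L = L;
  S->u = u;
  S->h = h;
  S->s_fixed = s_fixed;
  S->gamma_dfe = gamma_dfe;
  S->gamma_shape = gamma_shape;
  S->gamma_mean = gamma_mean;
  S->s.resize(L);
  for (int l = 0; l < L; ++l) S->s[l] = S->draw_s();
  Rcpp::XPtr<Sim> ptr(S, true);
  return ptr;
}

// [[Rcpp::export(name = ".fwd_add_pop")]]
void fwd_add_pop(SEXP sim, std::string name, int N, double q0) {
  Sim* S = get(sim);
  Pop pop;
  pop.inds.resize(N);
  if (q0 > 0.0) {
    for (auto& ind : pop.inds) {
      for (int l = 0; l < S->L; ++l) {
        if (S->unif() < q0) ind.h1.push_back(l);
        if (S->unif() < q0) ind.h2.push_back(l);
      }
    }
  }
  S->pops[name] = pop;
}

// [[Rcpp::export(name = ".fwd_run")]]
NumericMatrix fwd_run(SEXP sim, std::string name, int gens, std::string mode,
                      double sigma, int purge_every = 100) {
  Sim* S = get(sim);
  if (S->pops.find(name) == S->pops.end()) stop("unknown population");
  Pop& pop = S->pops[name];
  NumericMatrix out(gens, 6);
  colnames(out) = CharacterVector::create("gen", "mean_w", "mean_het",
                                          "mean_hom", "seg_sites", "min_load");
  for (int g = 0; g < gens; ++g) {
    next_generation(S, pop, mode, mode == "sexual" ? 1.0 : sigma, nullptr,
                    0.0, g);
    // record
    int het, hom;
    double lw, sw = 0.0, sh = 0.0, so = 0.0;
    int minload = -1;
    std::vector<int> seen;
    std::vector<char> mark(S->L, 0);
    for (auto& ind : pop.inds) {
      het_hom(ind, het, hom, S->s, S->h, &lw);
      sw += std::exp(lw + pop.fixed_logw);
      sh += het;
      so += hom;
      int load = het + 2 * hom;
      if (minload < 0 || load < minload) minload = load;
      for (int l : ind.h1) mark[l] = 1;
      for (int l : ind.h2) mark[l] = 1;
    }
    int seg = 0;
    for (int l = 0; l < S->L; ++l) seg += mark[l];
    double N = (double)pop.inds.size();
    out(g, 0) = g + 1;
    out(g, 1) = sw / N;
    out(g, 2) = sh / N;
    out(g, 3) = so / N;
    out(g, 4) = seg;
    out(g, 5) = minload;
    if (purge_every > 0 && (g + 1) % purge_every == 0) purge_fixed(S);
  }
  return out;
}

// [[Rcpp::export(name = ".fwd_split")]]
void fwd_split(SEXP sim, std::string src, std::string name_a,
               std::string name_b, int Na, int Nb) {
  Sim* S = get(sim);
  if (S->pops.find(src) == S->pops.end()) stop("unknown population");
  Pop& p = S->pops[src];
  std::uniform_int_distribution<int> pick(0, (int)p.inds.size() - 1);
  Pop a, b;
  a.fixed_logw = b.fixed_logw = p.fixed_logw;
  a.inds.reserve(Na);
  b.inds.reserve(Nb);
  for (int k = 0; k < Na; ++k) a.inds.push_back(p.inds[pick(S->rng)]);
  for (int k = 0; k < Nb; ++k) b.inds.push_back(p.inds[pick(S->rng)]);
  S->pops.erase(src);
  S->pops[name_a] = a;
  S->pops[name_b] = b;
}

// [[Rcpp::export(name = ".fwd_pulse")]]
void fwd_pulse(SEXP sim, std::string donor, std::string recipient, double f,
               std::string mode, double sigma) {
  Sim* S = get(sim);
  if (S->pops.find(donor) == S->pops.end() ||
      S->pops.find(recipient) == S->pops.end())
    stop("unknown population");
  next_generation(S, S->pops[recipient], mode,
                  mode == "sexual" ? 1.0 : sigma, &S->pops[donor], f, 0);
}

// [[Rcpp::export(name = ".fwd_freqs")]]
NumericVector fwd_freqs(SEXP sim, std::string name) {
  Sim* S = get(sim);
  if (S->pops.find(name) == S->pops.end()) stop("unknown population");
  Pop& p = S->pops[name];
  NumericVector out(S->L);
  for (auto& ind : p.inds) {
    for (int l : ind.h1) out[l] += 1.0;
    for (int l : ind.h2) out[l] += 1.0;
  }
  double denom = 2.0 * p.inds.size();
  for (int l = 0; l < S->L; ++l) out[l] /= denom;
  return out;
}

// [[Rcpp::export(name = ".fwd_mean_w")]]
double fwd_mean_w(SEXP sim, std::string name) {
  Sim* S = get(sim);
  Pop& p = S->pops[name];
  int het, hom;
  double lw, sw = 0.0;
  for (auto& ind : p.inds) {
    het_hom(ind, het, hom, S->s, S->h, &lw);
    sw += std::exp(lw + p.fixed_logw);
  }
  return sw / p.inds.size();
}
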