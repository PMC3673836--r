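#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// A haplotype is a piecewise-constant map from position to founder-haplotype
// label: brk[i] is the start of segment i (brk[0] == 0), segments run to the
// next breakpoint or to the chromosome end; lab[i] is the label on segment i.
struct Hap {
  std::vector<double> brk;
  std::vector<int> lab;
};

static void push_seg(Hap &g, double start, int label) {
  if (!g.lab.empty() && g.lab.back() == label) return; // merge equal labels
  g.brk.push_back(start);
  g.lab.push_back(label);
}

// One meiosis for one chromosome. Crossover count ~ Poisson(rate * L),
// positions uniform (no interference), starting haplotype a fair coin,
// strand alternates at every crossover. RNG call order (rpois, runif * k,
// coin) is part of the contract: the pure-R path reproduces it exactly.
static Hap meiosis_hap(const Hap &h1, const Hap &h2, double L, double rate,
                       int &ncross) {
  int k = (int)R::rpois(rate * L);
  std::vector<double> x((size_t)k);
  for (int i = 0; i < k; i++) x[(size_t)i] = R::runif(0.0, L);
  std::sort(x.begin(), x.end());
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  ncross = k;

  Hap g;
  double a = 0.0;
  for (int i = 0; i <= k; i++) {
    double b = (i < k) ? x[(size_t)i] : L;
    if (b > a) {
      const Hap &h = (cur == 0) ? h1 : h2;
      size_t j = (size_t)(std::upper_bound(h.brk.begin(), h.brk.end(), a) -
                          h.brk.begin());
      if (j > 0) j--;
      for (; j < h.brk.size() && h.brk[j] < b; j++) {
        push_seg(g, std::max(h.brk[j], a), h.lab[j]);
      }
      a = b;
    }
    cur = 1 - cur;
  }
  return g;
}

// Maximal intervals where the two haplotypes carry the same founder label
// (autozygosity as fully penetrant IBD). Sweep over the union of breakpoints.
static void autozygous_sweep(const Hap &h1, const Hap &h2, double L,
                             std::vector<double> &starts,
                             std::vector<double> &ends) {
  size_t i = 0, j = 0;
  double pos = 0.0, run_start = -1.0;
  while (pos < L) {
    double end1 = (i + 1 < h1.brk.size()) ? h1.brk[i + 1] : L;
    double end2 = (j + 1 < h2.brk.size()) ? h2.brk[j + 1] : L;
    double nxt = std::min(end1, end2);
    bool eq = (h1.lab[i] == h2.lab[j]);
    if (eq) {
      if (run_start < 0) run_start = pos;
    } else if (run_start >= 0) {
      starts.push_back(run_start);
      ends.push_back(pos);
      run_start = -1.0;
    }
    pos = nxt;
    if (end1 == nxt) i++;
    if (end2 == nxt) j++;
  }
  if (run_start >= 0) {
    starts.push_back(run_start);
    ends.push_back(L);
  }
}

static Hap hap_from_list(const List &h) {
  Hap out;
  NumericVector brk = h["brk"];
  IntegerVector lab = h["lab"];
  out.brk.assign(brk.begin(), brk.end());
  out.lab.assign(lab.begin(), lab.end());
  return out;
}

static List hap_to_list(const Hap &h) {
  return List::create(_["brk"] = NumericVector(h.brk.begin(), h.brk.end()),
                      _["lab"] = IntegerVector(h.lab.begin(), h.lab.end()));
}

// parent: list per chromosome of list(h1 = list(brk, lab), h2 = ...).
// Returns per chromosome list(brk, lab, n_crossovers).
// [[Rcpp::export]]
List cpp_meiosis(List parent, NumericVector chrom_len, double rate) {
  int nc = parent.size();
  List out(nc);
  for (int c = 0; c < nc; c++) {
    List chr = parent[c];
    Hap h1 = hap_from_list(chr["h1"]);
    Hap h2 = hap_from_list(chr["h2"]);
    int ncross = 0;
    Hap g = meiosis_hap(h1, h2, chrom_len[c], rate, ncross);
    out[c] = List::create(
        _["brk"] = NumericVector(g.brk.begin(), g.brk.end()),
        _["lab"] = IntegerVector(g.lab.begin(), g.lab.end()),
        _["n_crossovers"] = ncross);
  }
  return out;
}

// genome: list per chromosome of list(h1, h2). Returns autozygous intervals.
// [[Rcpp::export]]
List cpp_extract_autozygous(List genome, NumericVector chrom_len) {
  std::vector<int> chrom;
  std::vector<double> starts, ends;
  for (int c = 0; c < genome.size(); c++) {
    List chr = genome[c];
    Hap h1 = hap_from_list(chr["h1"]);
    Hap h2 = hap_from_list(chr["h2"]);
    std::vector<double> st, en;
    autozygous_sweep(h1, h2, chrom_len[c], st, en);
    for (size_t k = 0; k < st.size(); k++) {
      chrom.push_back(c + 1);
      starts.push_back(st[k]);
      ends.push_back(en[k]);
    }
  }
  return List::create(
      _["chrom"] = IntegerVector(chrom.begin(), chrom.end()),
      _["start"] = NumericVector(starts.begin(), starts.end()),
      _["end"] = NumericVector(ends.begin(), ends.end()));
}

// Gene-dropping over a fixed pedigree, n_reps independent replicates.
// father/mother are 1-based indices into the member list (0 = founder),
// members in topological order; focal is 1-based. Gametes from fathers use
// male_rate, from mothers female_rate. Returns raw (pre-filter) autozygous
// segments of the focal individual, tagged by replicate.
// [[Rcpp::export]]
List cpp_run_model(IntegerVector father, IntegerVector mother, int focal,
                   NumericVector chrom_len, double male_rate,
                   double female_rate, int n_reps) {
  int n_ind = father.size();
  int n_chr = chrom_len.size();
  std::vector<int> rep_out, chrom_out;
  std::vector<double> start_out, end_out;

  // genomes[i][c][h]
  std::vector<std::vector<std::vector<Hap> > > genomes(
      (size_t)n_ind, std::vector<std::vector<Hap> >(
                         (size_t)n_chr, std::vector<Hap>(2)));

  for (int r = 1; r <= n_reps; r++) {
    int label = 0;
    for (int i = 0; i < n_ind; i++) {
      if (father[i] == 0) { // founder: two fresh single-label haplotypes
        int l1 = ++label, l2 = ++label;
        for (int c = 0; c < n_chr; c++) {
          for (int h = 0; h < 2; h++) {
            Hap &hp = genomes[(size_t)i][(size_t)c][(size_t)h];
            hp.brk.assign(1, 0.0);
            hp.lab.assign(1, h == 0 ? l1 : l2);
          }
        }
      } else {
        int f = father[i] - 1, m = mother[i] - 1;
        int nc_unused = 0;
        for (int c = 0; c < n_chr; c++) {
          genomes[(size_t)i][(size_t)c][0] =
              meiosis_hap(genomes[(size_t)f][(size_t)c][0],
                          genomes[(size_t)f][(size_t)c][1], chrom_len[c],
                          male_rate, nc_unused);
        }
        for (int c = 0; c < n_chr; c++) {
          genomes[(size_t)i][(size_t)c][1] =
              meiosis_hap(genomes[(size_t)m][(size_t)c][0],
                          genomes[(size_t)m][(size_t)c][1], chrom_len[c],
                          female_rate, nc_unused);
        }
      }
    }
    int fi = focal - 1;
    for (int c = 0; c < n_chr; c++) {
      std::vector<double> st, en;
      autozygous_sweep(genomes[(size_t)fi][(size_t)c][0],
                       genomes[(size_t)fi][(size_t)c][1], chrom_len[c], st,
                       en);
      for (size_t k = 0; k < st.size(); k++) {
        rep_out.push_back(r);
        chrom_out.push_back(c + 1);
        start_out.push_back(st[k]);
        end_out.push_back(en[k]);
      }
    }
  }
  return List::create(
      _["rep"] = IntegerVector(rep_out.begin(), rep_out.end()),
      _["chrom"] = IntegerVector(chrom_out.begin(), chrom_out.end()),
      _["start"] = NumericVector(start_out.begin(), start_out.end()),
      _["end"] = NumericVector(end_out.begin(), end_out.end()));
}
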