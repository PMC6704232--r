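// Windowed McCaskill partition function for local accessibility.
//
// Energy model (reduced): a base pair directly stacked on its inner
// neighbor contributes the nearest-neighbor stacking dG37; a pair whose
// inner neighbor is not paired closes a loop and contributes a constant
// loop penalty. Pairs: AU/UA/CG/GC/GU/UG, minimum 3 unpaired nucleotides
// in a hairpin, maximum pair span spanL. For every sliding window of
// length min(W, n) the Boltzmann probability that each u-stretch is fully
// unpaired is computed by an inside/outside recursion; per-stretch values
// are averaged over all windows containing the stretch and assigned to the
// stretch's 3'-most position.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct FoldParams {
  double wcstack[4][4]; // dG37 keyed by 5'->3' dinucleotide of one strand
  double wobble_dg;     // stacks involving a GU pair
  double loop_dg;       // loop-closure penalty
  double rt;
  int span_l;
};

inline bool is_wc(int x, int y) {
  return (x == 0 && y == 3) || (x == 3 && y == 0) ||
         (x == 1 && y == 2) || (x == 2 && y == 1);
}

inline bool can_pair(int x, int y) {
  if (x > 3 || y > 3) return false; // ambiguous bases never pair
  return is_wc(x, y) || (x == 2 && y == 3) || (x == 3 && y == 2);
}

class WindowPF {
public:
  WindowPF(const std::vector<int>& s, const FoldParams& p)
      : s_(s), p_(p), n_((int)s.size()),
        q_(n_ * n_, 0.0), qb_(n_ * n_, 0.0), qhat_(n_ * n_, 0.0) {
    for (int i = 0; i < n_; ++i) q_[i * n_ + i] = 1.0; // open single base
    fill_inside();
    fill_outside();
  }

  // partition function of interval [i, j]; 1 for empty intervals
  double Q(int i, int j) const {
    if (i > j) return 1.0;
    return q_[i * n_ + j];
  }

  double Z() const { return Q(0, n_ - 1); }

  // Boltzmann probability that [a, b] is entirely unpaired
  double prob_unpaired(int a, int b) const {
    double num = Q(0, a - 1) * Q(b + 1, n_ - 1);
    const double wloop = std::exp(-p_.loop_dg / p_.rt);
    int ilo = std::max(0, b + 1 - p_.span_l);
    for (int i = ilo; i <= a - 1; ++i) {
      int jhi = std::min(n_ - 1, i + p_.span_l);
      for (int j = b + 1; j <= jhi; ++j) {
        if (!pairok(i, j)) continue;
        num += qhat_[i * n_ + j] * wloop * Q(i + 1, a - 1) * Q(b + 1, j - 1);
      }
    }
    return num / Z();
  }

private:
  const std::vector<int>& s_;
  const FoldParams& p_;
  int n_;
  std::vector<double> q_, qb_, qhat_;

  bool pairok(int i, int j) const {
    return j - i - 1 >= 3 && j - i <= p_.span_l && can_pair(s_[i], s_[j]);
  }

  // stacking energy of outer pair (i, j) on inner pair (i+1, j-1)
  double stack_dg(int i, int j) const {
    if (is_wc(s_[i], s_[j]) && is_wc(s_[i + 1], s_[j - 1]))
      return p_.wcstack[s_[i]][s_[i + 1]];
    return p_.wobble_dg;
  }

  void fill_inside() {
    const double wloop = std::exp(-p_.loop_dg / p_.rt);
    for (int d = 1; d < n_; ++d) {
      for (int i = 0; i + d < n_; ++i) {
        int j = i + d;
        if (pairok(i, j)) {
          double inner_q = Q(i + 1, j - 1);
          double inner_qb = (i + 1 <= j - 1) ? qb_[(i + 1) * n_ + j - 1] : 0.0;
          double v = wloop * (inner_q - inner_qb);
          if (inner_qb > 0.0)
            v += std::exp(-stack_dg(i, j) / p_.rt) * inner_qb;
          qb_[i * n_ + j] = v;
        }
        double tot = Q(i, j - 1);
        int klo = std::max(i, j - p_.span_l);
        for (int k = klo; k <= j - 4; ++k) {
          double b = qb_[k * n_ + j];
          if (b > 0.0) tot += Q(i, k - 1) * b;
        }
        q_[i * n_ + j] = tot;
      }
    }
  }

  // qhat(i,j): partition function of everything outside pair (i,j), the
  // energy of (i,j) itself excluded (it lives in qb); computed for
  // decreasing span so enclosing pairs are available.
  void fill_outside() {
    const double wloop = std::exp(-p_.loop_dg / p_.rt);
    for (int d = n_ - 1; d >= 4; --d) {
      for (int i = 0; i + d < n_; ++i) {
        int j = i + d;
        if (!pairok(i, j)) continue;
        double v = Q(0, i - 1) * Q(j + 1, n_ - 1);
        if (i - 1 >= 0 && j + 1 < n_ && pairok(i - 1, j + 1))
          v += std::exp(-stack_dg(i - 1, j + 1) / p_.rt) *
               qhat_[(i - 1) * n_ + j + 1];
        int klo = std::max(0, j + 1 - p_.span_l);
        for (int k = klo; k <= i - 1; ++k) {
          int lhi = std::min(n_ - 1, k + p_.span_l);
          for (int l = j + 1; l <= lhi; ++l) {
            if (k == i - 1 && l == j + 1) continue;
            if (!pairok(k, l)) continue;
            v += wloop * qhat_[k * n_ + l] * Q(k + 1, i - 1) * Q(j + 1, l - 1);
          }
        }
        qhat_[i * n_ + j] = v;
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
NumericVector plfold_lap_cpp(IntegerVector seq, int u, int span_l, int w,
                             NumericMatrix wcstack, double wobble_dg,
                             double loop_dg, double rt) {
  int n = seq.size();
  if (n < u) stop("sequence shorter than the unpaired-stretch length u");
  FoldParams p;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) p.wcstack[a][b] = wcstack(a, b);
  p.wobble_dg = wobble_dg;
  p.loop_dg = loop_dg;
  p.rt = rt;
  p.span_l = span_l;

  int wp = std::min(w, n); // windows truncated to the sequence
  std::vector<double> sum(n, 0.0);
  std::vector<int> cnt(n, 0);

  for (int ws = 0; ws + wp <= n; ++ws) {
    std::vector<int> sub(seq.begin() + ws, seq.begin() + ws + wp);
    WindowPF pf(sub, p);
    for (int a = 0; a + u <= wp; ++a) {
      double pu = pf.prob_unpaired(a, a + u - 1);
      int pos = ws + a + u - 1; // 3'-most position of the stretch
      sum[pos] += pu;
      cnt[pos] += 1;
    }
    Rcpp::checkUserInterrupt();
  }

  NumericVector lap(n, NA_REAL);
  for (int i = 0; i < n; ++i)
    if (cnt[i] > 0) lap[i] = sum[i] / cnt[i];
  return lap;
}
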