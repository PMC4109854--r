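// Homotypic CRM scoring: Viterbi-style maximum over clusters of
// non-overlapping motif sites (either strand), scored as
//   sum(site log2-odds) + sum over transitions of log2(p (1-p)^gap)
// with p = 1/(1 + gap_expectation) (geometric within-cluster gaps), and
// a cluster-opening cost of -log2(p). The reported region score is the
// best cluster score floored at zero (empty cluster allowed), i.e. a
// log2 likelihood ratio of "cluster of real sites" vs "random DNA".

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Detail {
  double score;                 // floored at 0
  std::vector<int> starts;      // 0-based site starts (best cluster)
  std::vector<int> strands;     // +1 forward, -1 reverse
  std::vector<double> site_lo;  // per-site log2-odds
};

// Site log2-odds at every start for one strand. N (code 4) contributes 0.
inline void site_scores(const std::vector<int>& s, const NumericMatrix& lo,
                        std::vector<double>& out) {
  const int w = lo.nrow();
  const int n = (int)s.size() - w + 1;
  out.assign(n > 0 ? n : 0, 0.0);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < w; ++j) {
      int b = s[i + j];
      if (b < 4) acc += lo(j, b);
    }
    out[i] = acc;
  }
}

Detail score_one(const std::vector<int>& seq, const NumericMatrix& lofwd,
                 const NumericMatrix& lorev, double gap_expectation,
                 bool traceback) {
  Detail res;
  res.score = 0.0;
  const int w = lofwd.nrow();
  const int L = (int)seq.size();
  if (L < w) return res;

  const double p = 1.0 / (1.0 + gap_expectation);
  const double lp = std::log2(p);
  const double lg = std::log2(1.0 - p);

  std::vector<double> fs, rs;
  site_scores(seq, lofwd, fs);
  site_scores(seq, lorev, rs);
  const int n = (int)fs.size();

  // D for each (start, strand); running max M of D_j - end_j * lg over
  // sites already ended (end_j <= current start).
  std::vector<double> Df(n), Dr(n);
  std::vector<int> Pf, Pr;           // predecessor (2*j+strandbit), -1 none
  if (traceback) { Pf.assign(n, -1); Pr.assign(n, -1); }
  double M = R_NegInf;
  int Margmax = -1;
  double best = R_NegInf;
  int bestidx = -1;

  for (int i = 0; i < n; ++i) {
    if (i - w >= 0) {  // site starting at i-w ends exactly at i
      int j = i - w;
      double e = (double)(j + w);
      double cf = Df[j] - e * lg;
      if (cf > M) { M = cf; Margmax = 2 * j; }
      double cr = Dr[j] - e * lg;
      if (cr > M) { M = cr; Margmax = 2 * j + 1; }
    }
    double chain = (M == R_NegInf) ? R_NegInf : M + (double)i * lg;
    bool use_chain = chain > 0.0;  // vs opening a fresh cluster (cost -lp)
    double base = lp + (use_chain ? chain : 0.0);
    Df[i] = fs[i] + base;
    Dr[i] = rs[i] + base;
    if (traceback) {
      Pf[i] = use_chain ? Margmax : -1;
      Pr[i] = use_chain ? Margmax : -1;
    }
    if (Df[i] > best) { best = Df[i]; bestidx = 2 * i; }
    if (Dr[i] > best) { best = Dr[i]; bestidx = 2 * i + 1; }
  }

  if (best <= 0.0 || bestidx < 0) return res;
  res.score = best;
  if (traceback) {
    int cur = bestidx;
    while (cur >= 0) {
      int i = cur / 2, str = (cur % 2) ? -1 : 1;
      res.starts.push_back(i);
      res.strands.push_back(str);
      res.site_lo.push_back(str > 0 ? fs[i] : rs[i]);
      cur = (str > 0) ? Pf[i] : Pr[i];
    }
    std::reverse(res.starts.begin(), res.starts.end());
    std::reverse(res.strands.begin(), res.strands.end());
    std::reverse(res.site_lo.begin(), res.site_lo.end());
  }
  return res;
}

// log2-odds matrices (forward and reverse complement) from a
// probability matrix and a background frequency vector.
inline void make_lo(const NumericMatrix& prob, const double* bg,
                    NumericMatrix& lofwd, NumericMatrix& lorev) {
  const int w = prob.nrow();
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b) {
      double v = std::log2(prob(j, b) / bg[b]);
      lofwd(j, b) = v;
      lorev(w - 1 - j, 3 - b) = v;
    }
}

} // namespace

// [[Rcpp::export]]
List cpp_crm_score_detail(IntegerVector seq, NumericMatrix prob,
                          NumericVector background, double gap_expectation) {
  std::vector<int> s(seq.begin(), seq.end());
  double bg[4] = {background[0], background[1], background[2], background[3]};
  int w = prob.nrow();
  NumericMatrix lofwd(w, 4), lorev(w, 4);
  make_lo(prob, bg, lofwd, lorev);
  Detail d = score_one(s, lofwd, lorev, gap_expectation, true);
  return List::create(_["score"] = d.score,
                      _["site_start"] = wrap(d.starts),
                      _["site_strand"] = wrap(d.strands),
                      _["site_log_odds"] = wrap(d.site_lo));
}

// Score every sequence against every PWM. probs: list of w x 4
// probability matrices. background: length 4 for a fixed model, or
// length 0 to estimate a 0-order model per sequence (add-one smoothed).
// Flat-array rewrite of the score_one recurrence (identical scores).
// [[Rcpp::export]]
NumericMatrix cpp_crm_scan(List seqs, List probs, NumericVector background,
                           double gap_expectation) {
  const int ns = seqs.size(), np = probs.size();
  const bool local_bg = background.size() == 0;
  NumericMatrix out(ns, np);
  const double p = 1.0 / (1.0 + gap_expectation);
  const double lp = std::log2(p), lg = std::log2(1.0 - p);

  std::vector<std::vector<int> > enc(ns);
  std::vector<std::array<double, 4> > l2bgs(ns);
  for (int i = 0; i < ns; ++i) {
    IntegerVector v = seqs[i];
    enc[i].assign(v.begin(), v.end());
    std::array<double, 4> f;
    if (local_bg) {
      double cnt[4] = {1, 1, 1, 1};  // add-one smoothing
      double tot = 4;
      for (size_t k = 0; k < enc[i].size(); ++k)
        if (enc[i][k] < 4) { cnt[enc[i][k]] += 1; tot += 1; }
      for (int b = 0; b < 4; ++b) f[b] = std::log2(cnt[b] / tot);
    } else {
      for (int b = 0; b < 4; ++b) f[b] = std::log2(background[b]);
    }
    l2bgs[i] = f;
  }

  std::vector<double> l2p, lof, lor, fs, rs, Df, Dr;
  for (int m = 0; m < np; ++m) {
    NumericMatrix prob = probs[m];
    const int w = prob.nrow();
    l2p.assign(w * 4, 0.0);
    for (int j = 0; j < w; ++j)
      for (int b = 0; b < 4; ++b) l2p[j * 4 + b] = std::log2(prob(j, b));
    lof.assign(w * 4, 0.0);
    lor.assign(w * 4, 0.0);

    for (int i = 0; i < ns; ++i) {
      const std::vector<int>& s = enc[i];
      const double* l2bg = l2bgs[i].data();
      for (int j = 0; j < w; ++j)
        for (int b = 0; b < 4; ++b) {
          double v = l2p[j * 4 + b] - l2bg[b];
          lof[j * 4 + b] = v;
          lor[(w - 1 - j) * 4 + (3 - b)] = v;
        }
      const int n = (int)s.size() - w + 1;
      if (n <= 0) { out(i, m) = 0.0; continue; }
      fs.assign(n, 0.0); rs.assign(n, 0.0);
      for (int s0 = 0; s0 < n; ++s0) {
        double a = 0.0, r = 0.0;
        const int* sp = &s[s0];
        for (int j = 0; j < w; ++j) {
          int b = sp[j];
          if (b < 4) { a += lof[j * 4 + b]; r += lor[j * 4 + b]; }
        }
        fs[s0] = a; rs[s0] = r;
      }
      Df.assign(n, 0.0); Dr.assign(n, 0.0);
      double M = -HUGE_VAL, best = -HUGE_VAL;
      for (int s0 = 0; s0 < n; ++s0) {
        if (s0 - w >= 0) {
          int j = s0 - w;
          double e = (double)(j + w);
          double cf = Df[j] - e * lg; if (cf > M) M = cf;
          double cr = Dr[j] - e * lg; if (cr > M) M = cr;
        }
        double chain = M + (double)s0 * lg;
        double base = lp + (chain > 0.0 ? chain : 0.0);
        Df[s0] = fs[s0] + base; Dr[s0] = rs[s0] + base;
        if (Df[s0] > best) best = Df[s0];
        if (Dr[s0] > best) best = Dr[s0];
      }
      out(i, m) = best > 0.0 ? best : 0.0;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
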