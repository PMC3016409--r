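// Fast enumeration of Mendelian-consistent haplotype configurations for a
// single nuclear family, used as the hot path for trio/sib-pair resources
// inside the Monte Carlo loop.  Haplotypes are encoded as integers (bit i
// set = minor allele at locus i+1).  Results are identical to the R-level
// preprocessing + enumeration path; equality is asserted by the test
// suite against a brute-force oracle.

#include <Rcpp.h>
#include <set>
#include <utility>
#include <vector>

using namespace Rcpp;

typedef std::pair<int, int> HapPair;

// All unordered haplotype pairs consistent with one individual's
// genotypes; g1/g2 hold allele codes 1/2 with 0 = missing.
static std::vector<HapPair> pairs_for(const IntegerVector& g1,
                                      const IntegerVector& g2,
                                      const std::set<int>* allowed,
                                      double cap) {
  int n = g1.size();
  std::vector<HapPair> acc;
  acc.push_back(HapPair(0, 0));
  for (int i = 0; i < n; ++i) {
    int bit = 1 << i;
    std::vector<HapPair> next;
    next.reserve(acc.size() * 4);
    if (g1[i] == 0) {
      for (size_t r = 0; r < acc.size(); ++r) {
        for (int a = 0; a < 2; ++a)
          for (int b = 0; b < 2; ++b)
            next.push_back(HapPair(acc[r].first + a * bit,
                                   acc[r].second + b * bit));
      }
    } else if (g1[i] == g2[i]) {
      int a = (g1[i] == 2) ? bit : 0;
      for (size_t r = 0; r < acc.size(); ++r)
        next.push_back(HapPair(acc[r].first + a, acc[r].second + a));
    } else {
      for (size_t r = 0; r < acc.size(); ++r) {
        next.push_back(HapPair(acc[r].first, acc[r].second + bit));
        next.push_back(HapPair(acc[r].first + bit, acc[r].second));
      }
    }
    if (next.size() > cap)
      stop("haplotype pair expansion exceeds cap");
    acc.swap(next);
  }
  std::set<HapPair> uniq;
  for (size_t r = 0; r < acc.size(); ++r) {
    int lo = std::min(acc[r].first, acc[r].second);
    int hi = std::max(acc[r].first, acc[r].second);
    if (allowed != 0 &&
        (allowed->find(lo) == allowed->end() ||
         allowed->find(hi) == allowed->end()))
      continue;
    uniq.insert(HapPair(lo, hi));
  }
  return std::vector<HapPair>(uniq.begin(), uniq.end());
}

// [[Rcpp::export(name = ".enum_nuclear_cpp")]]
IntegerMatrix enum_nuclear_cpp(IntegerVector fg1, IntegerVector fg2,
                               IntegerVector mg1, IntegerVector mg2,
                               IntegerMatrix kg1, IntegerMatrix kg2,
                               Nullable<IntegerVector> allowed_,
                               double cap) {
  std::set<int> allowed_set;
  const std::set<int>* allowed = 0;
  if (allowed_.isNotNull()) {
    IntegerVector av(allowed_);
    allowed_set.insert(av.begin(), av.end());
    allowed = &allowed_set;
  }
  std::vector<HapPair> fp = pairs_for(fg1, fg2, allowed, cap);
  std::vector<HapPair> mp = pairs_for(mg1, mg2, allowed, cap);
  int nk = kg1.nrow();
  std::vector< std::vector<HapPair> > ko(nk);  // ordered (mat, pat)
  std::vector<int> ord(nk);
  for (int k = 0; k < nk; ++k) {
    IntegerVector a = kg1(k, _), b = kg2(k, _);
    std::vector<HapPair> u = pairs_for(a, b, allowed, cap);
    std::vector<HapPair> o;
    for (size_t r = 0; r < u.size(); ++r) {
      o.push_back(u[r]);
      if (u[r].first != u[r].second)
        o.push_back(HapPair(u[r].second, u[r].first));
    }
    ko[k] = o;
    ord[k] = k;
  }
  // process offspring in order of fewest possibilities
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return ko[a].size() < ko[b].size(); });

  struct Cfg {
    int fi, mi;
    std::vector<HapPair> kid;  // indexed by original child position
  };
  std::vector<Cfg> cfgs;
  // seed from the first (minimum-possibility) child
  int first = ord[0];
  for (size_t r = 0; r < ko[first].size(); ++r) {
    const HapPair& o = ko[first][r];
    for (size_t mi = 0; mi < mp.size(); ++mi) {
      if (mp[mi].first != o.first && mp[mi].second != o.first) continue;
      for (size_t fi = 0; fi < fp.size(); ++fi) {
        if (fp[fi].first != o.second && fp[fi].second != o.second) continue;
        Cfg c;
        c.fi = fi;
        c.mi = mi;
        c.kid.assign(nk, HapPair(-1, -1));
        c.kid[first] = o;
        cfgs.push_back(c);
      }
    }
  }
  for (int kk = 1; kk < nk && !cfgs.empty(); ++kk) {
    int ci = ord[kk];
    std::vector<Cfg> next;
    for (size_t r = 0; r < cfgs.size(); ++r) {
      const HapPair& F = fp[cfgs[r].fi];
      const HapPair& M = mp[cfgs[r].mi];
      for (size_t s = 0; s < ko[ci].size(); ++s) {
        const HapPair& o = ko[ci][s];
        if (M.first != o.first && M.second != o.first) continue;
        if (F.first != o.second && F.second != o.second) continue;
        Cfg c = cfgs[r];
        c.kid[ci] = o;
        next.push_back(c);
      }
      if (next.size() > cap)
        stop("configuration count exceeds cap");
    }
    cfgs.swap(next);
  }
  IntegerMatrix out(cfgs.size(), 4 + 2 * nk);
  for (size_t r = 0; r < cfgs.size(); ++r) {
    out(r, 0) = fp[cfgs[r].fi].first;
    out(r, 1) = fp[cfgs[r].fi].second;
    out(r, 2) = mp[cfgs[r].mi].first;
    out(r, 3) = mp[cfgs[r].mi].second;
    for (int k = 0; k < nk; ++k) {
      out(r, 4 + 2 * k) = cfgs[r].kid[k].first;
      out(r, 5 + 2 * k) = cfgs[r].kid[k].second;
    }
  }
  return out;
}
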