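#include <Rcpp.h>
#include <map>
#include <utility>
using namespace Rcpp;

// Extended haplotype homozygosity machinery.
//
// A "walk" starts at a core SNP with a set of haplotype columns and extends
// site by site in one direction, refining a partition of the haplotypes by
// their alleles.  EHH at marker x is the fraction of haplotype pairs that are
// identical at every SNP from the core through x.  iHH is the trapezoidal
// integral of EHH over genetic distance (cM).  Traversal stops when EHH
// falls below `cutoff`, at the chromosome end (flagged truncated), or when
// the physical gap between adjacent SNPs exceeds `max_gap` bp.

static inline double pairs_of(double k) { return k * (k - 1.0) / 2.0; }

// One refinement step: split groups by the allele at row `site`.
// Returns the new number of identical pairs.  Uses flat relabel/count
// scratch vectors (no allocation churn in the hot loop).
static double refine(const IntegerMatrix &X, int site,
                     const std::vector<int> &cols, std::vector<int> &grp,
                     int &ngrp) {
  static thread_local std::vector<int> relab, cnt;
  relab.assign(2 * ngrp, -1);
  int next = 0;
  const size_t n = cols.size();
  for (size_t h = 0; h < n; ++h) {
    int key = 2 * grp[h] + X(site, cols[h]);
    if (relab[key] < 0) relab[key] = next++;
    grp[h] = relab[key];
  }
  cnt.assign(next, 0);
  for (size_t h = 0; h < n; ++h) cnt[grp[h]]++;
  ngrp = next;
  double pr = 0.0;
  for (int g = 0; g < next; ++g) pr += pairs_of((double)cnt[g]);
  return pr;
}

struct WalkResult {
  double ihh;
  bool truncated;   // hit chromosome end while EHH still >= cutoff
  std::vector<int> sites;
  std::vector<double> ehh;
};

// ehh0: EHH at the core itself (1.0 for allele-partitioned walks, pooled
// homozygosity for pooled walks, in which case `preset` carries the initial
// partition by core allele).
static WalkResult walk(const IntegerMatrix &X, int core, int dir,
                       const std::vector<int> &cols,
                       const NumericVector &cm, const NumericVector &pos,
                       double cutoff, double max_gap, double ehh0,
                       bool split_core) {
  WalkResult res;
  res.ihh = 0.0;
  res.truncated = false;
  int n = cols.size();
  double denom = pairs_of((double)n);
  std::vector<int> grp(n, 0);
  int ngrp = 1;
  double ehh_prev = ehh0;
  if (split_core) {
    double pr = refine(X, core, cols, grp, ngrp);
    ehh_prev = denom > 0 ? pr / denom : 0.0;
  }
  int cur = core;
  int nsites = X.nrow();
  while (true) {
    int nxt = cur + dir;
    if (nxt < 0 || nxt >= nsites) {
      if (ehh_prev >= cutoff && ehh_prev > 0) res.truncated = true;
      break;
    }
    if (std::abs(pos[nxt] - pos[cur]) > max_gap) break;
    double pr = refine(X, nxt, cols, grp, ngrp);
    double ehh = denom > 0 ? pr / denom : 0.0;
    double dcm = std::abs(cm[nxt] - cm[cur]);
    res.ihh += 0.5 * (ehh_prev + ehh) * dcm;
    res.sites.push_back(nxt);
    res.ehh.push_back(ehh);
    ehh_prev = ehh;
    cur = nxt;
    if (ehh < cutoff || ehh <= 0.0) break;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_ehh_decay(IntegerMatrix X, int core, IntegerVector cols,
                   NumericVector cm, NumericVector pos,
                   double cutoff, double max_gap) {
  std::vector<int> cc(cols.begin(), cols.end());
  WalkResult L = walk(X, core - 1, -1, cc, cm, pos, cutoff, max_gap, 1.0, false);
  WalkResult R = walk(X, core - 1, +1, cc, cm, pos, cutoff, max_gap, 1.0, false);
  return List::create(
    _["left_sites"] = wrap(L.sites), _["left_ehh"] = wrap(L.ehh),
    _["right_sites"] = wrap(R.sites), _["right_ehh"] = wrap(R.ehh),
    _["ihh"] = L.ihh + R.ihh,
    _["truncated"] = L.truncated || R.truncated);
}

// iHH for every site, separately for carriers of allele 1 (derived when
// polarized accordingly) and allele 0.  der[i] in {0,1} gives the allele
// treated as "derived" at site i; NA_INTEGER skips the site.
// [[Rcpp::export]]
List cpp_ihs_all(IntegerMatrix X, IntegerVector der, NumericVector cm,
                 NumericVector pos, double cutoff, double max_gap) {
  int n_sites = X.nrow(), n_hap = X.ncol();
  NumericVector ihh_d(n_sites, NA_REAL), ihh_a(n_sites, NA_REAL);
  LogicalVector trunc(n_sites, false);
  for (int s = 0; s < n_sites; ++s) {
    if (der[s] == NA_INTEGER) continue;
    std::vector<int> cd, ca;
    for (int h = 0; h < n_hap; ++h) {
      if (X(s, h) == der[s]) cd.push_back(h); else ca.push_back(h);
    }
    if (cd.size() < 2 || ca.size() < 2) continue;
    WalkResult dl = walk(X, s, -1, cd, cm, pos, cutoff, max_gap, 1.0, false);
    WalkResult dr = walk(X, s, +1, cd, cm, pos, cutoff, max_gap, 1.0, false);
    WalkResult al = walk(X, s, -1, ca, cm, pos, cutoff, max_gap, 1.0, false);
    WalkResult ar = walk(X, s, +1, ca, cm, pos, cutoff, max_gap, 1.0, false);
    ihh_d[s] = dl.ihh + dr.ihh;
    ihh_a[s] = al.ihh + ar.ihh;
    trunc[s] = dl.truncated || dr.truncated || al.truncated || ar.truncated;
  }
  return List::create(_["ihh_der"] = ihh_d, _["ihh_anc"] = ihh_a,
                      _["truncated"] = trunc);
}

// Pooled-allele EHH walk for one population: partition starts from the core
// alleles themselves; EHH(core) is the pooled homozygosity at the core.
static double pooled_ihh_dir(const IntegerMatrix &X, int s, int dir,
                             const std::vector<int> &cols,
                             const IntegerMatrix &Y,
                             const std::vector<int> &ycols,
                             const NumericVector &cm, const NumericVector &pos,
                             double cutoff, double max_gap,
                             double &other_ihh, bool &trunc) {
  // joint walk over two populations: stop when EHH < cutoff in BOTH
  int n1 = cols.size(), n2 = ycols.size();
  double den1 = pairs_of((double)n1), den2 = pairs_of((double)n2);
  std::vector<int> g1(n1, 0), g2(n2, 0);
  int ng1 = 1, ng2 = 1;
  double e1 = refine(X, s, cols, g1, ng1) / den1;
  double e2 = refine(Y, s, ycols, g2, ng2) / den2;
  double ihh1 = 0.0, ihh2 = 0.0;
  int cur = s, nsites = X.nrow();
  trunc = false;
  while (true) {
    int nxt = cur + dir;
    if (nxt < 0 || nxt >= nsites) {
      if (e1 >= cutoff || e2 >= cutoff) trunc = true;
      break;
    }
    if (std::abs(pos[nxt] - pos[cur]) > max_gap) break;
    double p1 = refine(X, nxt, cols, g1, ng1) / den1;
    double p2 = refine(Y, nxt, ycols, g2, ng2) / den2;
    double dcm = std::abs(cm[nxt] - cm[cur]);
    ihh1 += 0.5 * (e1 + p1) * dcm;
    ihh2 += 0.5 * (e2 + p2) * dcm;
    e1 = p1; e2 = p2;
    cur = nxt;
    if ((e1 < cutoff && e2 < cutoff) || (e1 <= 0 && e2 <= 0)) break;
  }
  other_ihh = ihh2;
  return ihh1;
}

// [[Rcpp::export]]
List cpp_xpehh_all(IntegerMatrix Xt, IntegerMatrix Xr, NumericVector cm,
                   NumericVector pos, double cutoff, double max_gap) {
  int n_sites = Xt.nrow();
  std::vector<int> ct, cr;
  for (int h = 0; h < Xt.ncol(); ++h) ct.push_back(h);
  for (int h = 0; h < Xr.ncol(); ++h) cr.push_back(h);
  NumericVector it(n_sites, NA_REAL), ir(n_sites, NA_REAL);
  LogicalVector trunc(n_sites, false);
  for (int s = 0; s < n_sites; ++s) {
    double o1 = 0.0, o2 = 0.0;
    bool tl = false, tr_ = false;
    double l1 = pooled_ihh_dir(Xt, s, -1, ct, Xr, cr, cm, pos, cutoff,
                               max_gap, o1, tl);
    double r1 = pooled_ihh_dir(Xt, s, +1, ct, Xr, cr, cm, pos, cutoff,
                               max_gap, o2, tr_);
    it[s] = l1 + r1;
    ir[s] = o1 + o2;
    trunc[s] = tl || tr_;
  }
  return List::create(_["ihh_target"] = it, _["ihh_ref"] = ir,
                      _["truncated"] = trunc);
}
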