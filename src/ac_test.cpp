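#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Audic-Claverie conditional model for tag counts in two libraries of
// totals N1, N2 (r = N2/N1):
//   P(y | x) = r^y * (x+y)! / ( x! * y! * (1+r)^(x+y+1) )
// i.e. y | x ~ NegBinomial(size = x+1, prob = 1/(1+r)).
// Tail sums are accumulated term by term in long double via the exact
// recurrences
//   P(y+1)/P(y) = r/(1+r) * (x+y+1)/(y+1)
//   P(y-1)/P(y) = (1+r)/r * y/(x+y)
// starting from the observed point, with periodic rescaling so the
// accumulator never overflows, stopping once the running term has passed
// the distribution mode and fallen below 1e-18 of the accumulated mass.

static long double log_pmf(long double x, long double y,
                           long double logr, long double log1pr) {
  return y * logr + lgammal(x + y + 1.0L) - lgammal(x + 1.0L)
         - lgammal(y + 1.0L) - (x + y + 1.0L) * log1pr;
}

// log of sum_{y' in tail} P(y'|x), tail starting at y0 inclusive,
// direction dir = +1 (upper) or -1 (lower, bounded at 0).
static long double log_tail(long double x, double y0d, int dir,
                            long double r, long double logr,
                            long double log1pr) {
  const long double eps = 1e-18L;
  long double y0 = (long double)y0d;
  long double logt0 = log_pmf(x, y0, logr, log1pr);
  long double mode = x * r;  // mode of NB(size = x+1, prob = 1/(1+r))
  long double acc = 1.0L;    // in units of exp(logt0 + offset)
  long double term = 1.0L;
  long double offset = 0.0L;
  long double yy = y0;
  for (;;) {
    if (dir < 0 && yy <= 0.0L) break;
    long double ratio;
    if (dir > 0) {
      ratio = (r / (1.0L + r)) * (x + yy + 1.0L) / (yy + 1.0L);
    } else {
      ratio = ((1.0L + r) / r) * yy / (x + yy);
    }
    term *= ratio;
    yy += dir;
    acc += term;
    bool past_mode = (dir > 0) ? (yy > mode) : (yy < mode);
    if (past_mode && term < eps * acc) break;
    if (term > 1e300L) {  // rescale to avoid overflow of acc
      acc /= term;
      offset += logl(term);
      term = 1.0L;
    }
    if (dir < 0 && yy <= 0.0L) break;
  }
  return logt0 + offset + logl(acc);
}

// [[Rcpp::export(name = ".ac_pvalue_cpp")]]
NumericVector ac_pvalue_cpp(NumericVector x, NumericVector y,
                            NumericVector n1, NumericVector n2,
                            int alternative) {
  // alternative: 0 = two.sided, 1 = less (y depleted), 2 = greater
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    long double r = (long double)n2[i] / (long double)n1[i];
    long double logr = logl(r);
    long double log1pr = log1pl(r);
    long double p;
    if (alternative == 1) {
      p = expl(log_tail(x[i], y[i], -1, r, logr, log1pr));
    } else if (alternative == 2) {
      p = expl(log_tail(x[i], y[i], +1, r, logr, log1pr));
    } else {
      long double lo = log_tail(x[i], y[i], -1, r, logr, log1pr);
      long double hi = log_tail(x[i], y[i], +1, r, logr, log1pr);
      long double m = lo < hi ? lo : hi;
      p = 2.0L * expl(m);
    }
    if (p > 1.0L) p = 1.0L;
    out[i] = (double)p;
  }
  return out;
}
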