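#include <Rcpp.h>
using namespace Rcpp;

// Size-only Gillespie simulation of a linear birth-death process.
// One lineage at time 0; returns the number of extant descendants at
// time t, conditioned on survival (>= 1 descendant) by rejection.
// Uses R's RNG so results are governed by set.seed().
static long survive_size(double lambda, double mu, double t, long max_attempts,
                         long *attempts_used) {
  const double total = lambda + mu;
  const double p_birth = lambda / total;
  for (long a = 0; a < max_attempts; ++a) {
    long n = 1;
    double tau = 0.0;
    for (;;) {
      tau += R::exp_rand() / (total * n);
      if (tau > t) break;
      if (unif_rand() < p_birth) ++n; else --n;
      if (n == 0) break;
    }
    if (n > 0) { *attempts_used += a + 1; return n; }
  }
  return -1; // rejection guard tripped
}

// Crown-conditioned clade sizes: two basal lineages, each conditioned on
// survival to time t (equivalent, by independence, to rejecting whole
// crown trees until both basal lineages survive). Returns reps sizes;
// attr "attempts" carries the total number of single-lineage attempts,
// from which the acceptance probability can be estimated.
// [[Rcpp::export]]
IntegerVector bd_crown_sizes_cpp(int reps, double lambda, double mu, double t,
                                 double max_attempts) {
  if (reps < 1) stop("reps must be >= 1");
  if (lambda <= 0 || mu < 0 || mu >= lambda)
    stop("need lambda > 0 and 0 <= mu < lambda");
  if (t <= 0) stop("t must be > 0");
  IntegerVector out(reps);
  long attempts = 0;
  const long cap = (long)max_attempts;
  RNGScope scope;
  for (int i = 0; i < reps; ++i) {
    long n1 = survive_size(lambda, mu, t, cap, &attempts);
    long n2 = (n1 < 0) ? -1 : survive_size(lambda, mu, t, cap, &attempts);
    if (n1 < 0 || n2 < 0) {
      double acc = attempts > 0 ? (double)(2 * i) / (double)attempts : 0.0;
      stop("rejection guard: no surviving lineage within %d attempts "
           "(estimated acceptance probability %.3g)", (int)cap, acc);
    }
    double s = (double)n1 + (double)n2;
    if (s > INT_MAX) stop("simulated clade size overflows integer range");
    out[i] = (int)s;
    if (i % 4096 == 0) checkUserInterrupt();
  }
  out.attr("attempts") = (double)attempts;
  return out;
}

// Extant descendant counts of a single unconditioned lineage after time t
// (zeros retained): oracle for the geometric-with-zero-class law.
// [[Rcpp::export]]
IntegerVector bd_single_sizes_cpp(int reps, double lambda, double mu, double t) {
  if (reps < 1) stop("reps must be >= 1");
  if (lambda <= 0 || mu < 0 || mu >= lambda)
    stop("need lambda > 0 and 0 <= mu < lambda");
  if (t <= 0) stop("t must be > 0");
  const double total = lambda + mu;
  const double p_birth = lambda / total;
  IntegerVector out(reps);
  RNGScope scope;
  for (int i = 0; i < reps; ++i) {
    long n = 1;
    double tau = 0.0;
    for (;;) {
      tau += R::exp_rand() / (total * n);
      if (tau > t) break;
      if (unif_rand() < p_birth) ++n; else --n;
      if (n == 0) break;
    }
    if (n > INT_MAX) stop("simulated size overflows integer range");
    out[i] = (int)n;
    if (i % 4096 == 0) checkUserInterrupt();
  }
  return out;
}
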