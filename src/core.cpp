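#include <Rcpp.h>
using namespace Rcpp;

// Population arrays are R arrays: code dims (64, 21, n) and reading
// dims (21, 3, n); element (c, l, k) of the code sits at c + 64*(l + 21*k).
// All randomness goes through R's RNG (unif_rand / R::rgamma), so a single
// set.seed() in R makes whole runs reproducible.

static const int NC = 64, NL = 21, NM = 3;

// Evaluate log-fitness for every individual. mode 0 = sampled (one reading
// mechanism drawn per label from the individual's reading row; the draw
// probability enters the factor linearly), mode 1 = expected (factor summed
// over mechanisms with weight r^2 / |N_j|). A per-label factor of 0 gives
// log-fitness -Inf. RNG consumption in sampled mode is exactly NL uniforms
// per individual, independent of the matrix contents.
// [[Rcpp::export]]
NumericVector eval_population_cpp(NumericVector code, NumericVector reading,
                                  int n, IntegerMatrix nb1, IntegerMatrix nb2,
                                  IntegerMatrix nb3, int mode) {
  NumericVector logf(n);
  const IntegerMatrix *nbs[3] = {&nb1, &nb2, &nb3};
  const double sizes[3] = {4.0, 7.0, 10.0};
  for (int k = 0; k < n; ++k) {
    const double *P = &code[0] + (R_xlen_t)k * NC * NL;
    const double *R_ = &reading[0] + (R_xlen_t)k * NL * NM;
    double lf = 0.0;
    for (int l = 0; l < NL; ++l) {
      // Bayes codon: column argmax, lowest index on ties
      const double *col = P + (R_xlen_t)l * NC;
      int cbest = 0;
      double best = col[0];
      for (int c = 1; c < NC; ++c) {
        if (col[c] > best) { best = col[c]; cbest = c; }
      }
      double term;
      if (mode == 0) {
        double u = unif_rand();
        double r1 = R_[l], r2 = R_[l + NL];
        int j = (u <= r1) ? 0 : (u <= r1 + r2 ? 1 : 2);
        const IntegerMatrix &nb = *nbs[j];
        double s = 0.0;
        for (int i = 0; i < nb.ncol(); ++i) s += col[nb(cbest, i) - 1];
        term = R_[l + (R_xlen_t)j * NL] / sizes[j] * s;
      } else {
        term = 0.0;
        for (int j = 0; j < NM; ++j) {
          const IntegerMatrix &nb = *nbs[j];
          double s = 0.0;
          for (int i = 0; i < nb.ncol(); ++i) s += col[nb(cbest, i) - 1];
          double r = R_[l + (R_xlen_t)j * NL];
          term += r * r / sizes[j] * s;
        }
      }
      lf += log(term);
    }
    logf[k] = lf;
  }
  return logf;
}

static void mutate_rows(double *mat, int nrow, int ncol, double row_prob,
                        double kappa, double eps) {
  std::vector<double> g(ncol);
  for (int r = 0; r < nrow; ++r) {
    double u = unif_rand();
    if (u >= row_prob) continue;
    double s = 0.0;
    for (int c = 0; c < ncol; ++c) {
      double alpha = kappa * mat[r + (R_xlen_t)c * nrow] + eps;
      g[c] = R::rgamma(alpha, 1.0);
      s += g[c];
    }
    if (s <= 0.0) {  // all gammas underflowed; keep the row on the simplex
      for (int c = 0; c < ncol; ++c) g[c] = 1.0;
      s = ncol;
    }
    for (int c = 0; c < ncol; ++c) mat[r + (R_xlen_t)c * nrow] = g[c] / s;
  }
}

// Build the next generation in one pass: gather individuals idx (1-based,
// elites first) from the current arrays, then Dirichlet-mutate everyone past
// skip_first. Fuses the selection copy and the mutation so each generation
// allocates and copies the population exactly once.
// [[Rcpp::export]]
List next_generation_cpp(NumericVector code, NumericVector reading, int n,
                         IntegerVector idx, double row_prob,
                         double reading_prob, double kappa, double eps,
                         int skip_first) {
  NumericVector code2((R_xlen_t)NC * NL * n), reading2((R_xlen_t)NL * NM * n);
  for (int k = 0; k < n; ++k) {
    int src = idx[k] - 1;
    std::copy(&code[0] + (R_xlen_t)src * NC * NL,
              &code[0] + (R_xlen_t)(src + 1) * NC * NL,
              &code2[0] + (R_xlen_t)k * NC * NL);
    std::copy(&reading[0] + (R_xlen_t)src * NL * NM,
              &reading[0] + (R_xlen_t)(src + 1) * NL * NM,
              &reading2[0] + (R_xlen_t)k * NL * NM);
  }
  for (int k = skip_first; k < n; ++k) {
    mutate_rows(&code2[0] + (R_xlen_t)k * NC * NL, NC, NL, row_prob, kappa, eps);
    mutate_rows(&reading2[0] + (R_xlen_t)k * NL * NM, NL, NM, reading_prob,
                kappa, eps);
  }
  code2.attr("dim") = IntegerVector::create(NC, NL, n);
  reading2.attr("dim") = IntegerVector::create(NL, NM, n);
  return List::create(_["code"] = code2, _["reading"] = reading2);
}

// Dirichlet row mutation. Each code row is hit with probability row_prob and
// each reading row with probability reading_prob; a hit row is resampled
// from Dirichlet(kappa * row + eps). The first skip_first individuals
// (elites) are left untouched and consume no RNG draws. Returns fresh
// arrays; inputs are not modified.
// [[Rcpp::export]]
List mutate_population_cpp(NumericVector code, NumericVector reading, int n,
                           double row_prob, double reading_prob, double kappa,
                           double eps, int skip_first) {
  NumericVector code2 = clone(code), reading2 = clone(reading);
  for (int k = skip_first; k < n; ++k) {
    mutate_rows(&code2[0] + (R_xlen_t)k * NC * NL, NC, NL, row_prob, kappa, eps);
    mutate_rows(&reading2[0] + (R_xlen_t)k * NL * NM, NL, NM, reading_prob,
                kappa, eps);
  }
  code2.attr("dim") = code.attr("dim");
  reading2.attr("dim") = reading.attr("dim");
  return List::create(_["code"] = code2, _["reading"] = reading2);
}
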