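#include <Rcpp.h>
using namespace Rcpp;

// Per-site log10 likelihood-ratio IBD scan over all individual pairs.
//
// For each pair of diploid genotypes (g1, g2) at a site with sample alt
// frequency p, the score is log10 P(g1, g2 | one haplotype shared IBD) -
// log10 P(g1) P(g2) under Hardy-Weinberg, with a small genotype error rate
// folded into the emission so opposite homozygotes score strongly negative
// but finite. Maximal positive-sum runs are extracted per pair; runs with
// cumulative score >= lod and genetic length >= minCm are reported.
//
// geno: sites x individuals, values 0/1/2, NA allowed (scores 0).
// Returns a data.frame of 1-based site indices per segment.

// [[Rcpp::export(name = ".ibdScanCpp")]]
DataFrame ibdScanCpp(IntegerMatrix geno, NumericVector p, NumericVector cm,
                     double err, double lod, double minCm) {
  const int S = geno.nrow(), N = geno.ncol();
  // emission P(obs | true) with the hom<->het error model
  double E[3][3] = {
    {1.0 - err, err, 0.0},
    {err / 2.0, 1.0 - err, err / 2.0},
    {0.0, err, 1.0 - err}
  };
  // per-site 3x3 score lookup (flattened 9 per site)
  std::vector<double> lut(static_cast<size_t>(S) * 9);
  for (int s = 0; s < S; ++s) {
    double ps = p[s], qs = 1.0 - ps;
    double hwe[3] = {qs * qs, 2.0 * ps * qs, ps * ps};
    double p0[3], fref[3], falt[3];
    for (int g = 0; g < 3; ++g) {
      p0[g] = hwe[0] * E[0][g] + hwe[1] * E[1][g] + hwe[2] * E[2][g];
      // true genotype given one shared allele: ref -> (q, p, 0), alt -> (0, q, p)
      fref[g] = qs * E[0][g] + ps * E[1][g];
      falt[g] = qs * E[1][g] + ps * E[2][g];
    }
    for (int g1 = 0; g1 < 3; ++g1)
      for (int g2 = 0; g2 < 3; ++g2) {
        double p1 = qs * fref[g1] * fref[g2] + ps * falt[g1] * falt[g2];
        double den = p0[g1] * p0[g2];
        double sc = (p1 <= 0.0 || den <= 0.0) ? -12.0
                                              : std::log10(p1 / den);
        lut[static_cast<size_t>(s) * 9 + g1 * 3 + g2] = sc;
      }
  }

  std::vector<int> outI, outJ, outStart, outEnd;
  std::vector<double> outScore;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      int s = 0;
      while (s < S) {
        double cur = 0.0, best = R_NegInf;
        int start = s, bestIdx = -1, t = s;
        for (; t < S; ++t) {
          int g1 = geno(t, i), g2 = geno(t, j);
          double sc = (g1 == NA_INTEGER || g2 == NA_INTEGER)
                          ? 0.0
                          : lut[static_cast<size_t>(t) * 9 + g1 * 3 + g2];
          cur += sc;
          if (cur > best) { best = cur; bestIdx = t; }
          if (cur <= 0.0) break;
        }
        if (bestIdx >= start && best >= lod &&
            cm[bestIdx] - cm[start] >= minCm) {
          outI.push_back(i + 1);
          outJ.push_back(j + 1);
          outStart.push_back(start + 1);
          outEnd.push_back(bestIdx + 1);
          outScore.push_back(best);
          s = bestIdx + 1;
        } else {
          s = t + 1;
        }
      }
    }
  }
  return DataFrame::create(_["id1"] = outI, _["id2"] = outJ,
                           _["startIdx"] = outStart, _["endIdx"] = outEnd,
                           _["score"] = outScore);
}
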