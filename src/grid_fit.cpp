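#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive inner grid of the sediment-influx depositional model for one
// (e1, e2) pair: cl runs over (0, 1] from gridStep, dxloc and id over
// [0, 2] inclusive, all at gridStep (0.01 -> 100 x 201 x 201 = 4,040,100
// evaluations).  The fit score is the sum of squared prediction errors on
// (d1, d2) plus the squared difference of the d2/d1 ratios; the ratio term
// is omitted (and flagged) when either denominator is zero.  Ties keep the
// first point visited (cl, then dxloc, then id, each ascending).
// [[Rcpp::export]]
List gridBestFitCpp(double e1, double e2, double obs1, double obs2,
                    double gridStep, bool fraction) {
  const int nCl = (int)std::lround(1.0 / gridStep);
  const int nD  = (int)std::lround(2.0 / gridStep) + 1;
  const bool useRatio = obs1 > 0.0;
  const double ro = useRatio ? obs2 / obs1 : 0.0;

  double bestFit = R_PosInf;
  double bCl = 0, bDx = 0, bId = 0, bD1 = 0, bD2 = 0;
  bool bOmit = false;

  for (int ic = 1; ic <= nCl; ++ic) {
    const double cl = ic * gridStep;
    const double cs = 1.0 - cl;
    const double f1 = fraction ? 1.0 + (cs / cl) * (1.0 + e1)
                               : 1.0 + cl * cs * (1.0 + e1);
    const double g = cs * (1.0 + e2);
    for (int ix = 0; ix < nD; ++ix) {
      const double dx = ix * gridStep;
      const double d1 = dx * f1;
      const double t1 = d1 - obs1;
      const double t1sq = t1 * t1;
      const bool ratioHere = useRatio && d1 > 0.0;
      for (int ii = 0; ii < nD; ++ii) {
        const double id = ii * gridStep;
        const double d2 = dx + id * g;
        const double t2 = d2 - obs2;
        double fit = t1sq + t2 * t2;
        if (ratioHere) {
          const double tr = d2 / d1 - ro;
          fit += tr * tr;
        }
        if (fit < bestFit) {
          bestFit = fit;
          bCl = cl; bDx = dx; bId = id; bD1 = d1; bD2 = d2;
          bOmit = !ratioHere;
        }
      }
    }
  }
  return List::create(_["fit"] = bestFit, _["cl"] = bCl, _["dxloc"] = bDx,
                      _["id"] = bId, _["d1"] = bD1, _["d2"] = bD2,
                      _["nEvaluations"] = (double)nCl * nD * nD,
                      _["ratioOmitted"] = bOmit);
}
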