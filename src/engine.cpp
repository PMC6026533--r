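#include <Rcpp.h>
using namespace Rcpp;

// Forward Wright-Fisher loop for one parameter cell.
//
// Haplotype order: 1=AB, 2=Ab, 3=aB, 4=ab. Each generation applies the
// deterministic selection+recombination recursion to the current gamete
// frequencies and draws the next 2N gametes from a multinomial. Fixation at
// a locus (allele count 0 or 2N after sampling) is absorbing; a replicate
// stops once both loci are fixed. Generations are counted from 1 (the first
// sampled generation). Uses R's RNG, so results are governed by set.seed().
//
// W: 4x4 genotype fitness matrix; r: recombination fraction in [0, 0.5];
// init_counts: replicates x 4 integer matrix of starting gamete counts.
// [[Rcpp::export]]
List run_cell_cpp(NumericMatrix W, double r, int N, int G,
                  IntegerMatrix init_counts, bool record_traj) {
  const int reps = init_counts.nrow();
  const int twoN = 2 * N;
  const double inv2N = 1.0 / twoN;
  const double w14 = W(0, 3), w23 = W(1, 2);

  IntegerVector fix1(reps, NA_INTEGER), fix2(reps, NA_INTEGER);
  IntegerMatrix finals(reps, 4);
  std::vector<double> traj; // packed rows: replicate, generation, p, q

  double x[4], w[4], xp[4];
  int counts[4];

  for (int rep = 0; rep < reps; ++rep) {
    for (int h = 0; h < 4; ++h) counts[h] = init_counts(rep, h);
    int f1 = NA_INTEGER, f2 = NA_INTEGER;

    for (int gen = 1; gen <= G; ++gen) {
      for (int h = 0; h < 4; ++h) x[h] = counts[h] * inv2N;

      double wbar = 0.0;
      for (int i = 0; i < 4; ++i) {
        double wi = 0.0;
        for (int j = 0; j < 4; ++j) wi += W(i, j) * x[j];
        w[i] = wi;
        wbar += x[i] * wi;
      }
      const double adj = r * (w14 * x[0] * x[3] - w23 * x[1] * x[2]);
      xp[0] = (x[0] * w[0] - adj) / wbar;
      xp[1] = (x[1] * w[1] + adj) / wbar;
      xp[2] = (x[2] * w[2] + adj) / wbar;
      xp[3] = (x[3] * w[3] - adj) / wbar;
      for (int h = 0; h < 4; ++h) if (xp[h] < 0.0) xp[h] = 0.0;

      rmultinom(twoN, xp, 4, counts);

      const int cA = counts[0] + counts[1];
      const int cB = counts[0] + counts[2];
      if (f1 == NA_INTEGER && (cA == 0 || cA == twoN)) f1 = gen;
      if (f2 == NA_INTEGER && (cB == 0 || cB == twoN)) f2 = gen;

      if (record_traj) {
        traj.push_back(rep + 1);
        traj.push_back(gen);
        traj.push_back(cA * inv2N);
        traj.push_back(cB * inv2N);
      }
      if (f1 != NA_INTEGER && f2 != NA_INTEGER) break;
    }

    fix1[rep] = f1;
    fix2[rep] = f2;
    for (int h = 0; h < 4; ++h) finals(rep, h) = counts[h];
    if (rep % 16 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["fix_gen_locus1"] = fix1,
                          _["fix_gen_locus2"] = fix2,
                          _["final_counts"] = finals);
  if (record_traj) {
    const int nrow = traj.size() / 4;
    NumericMatrix tm(nrow, 4);
    for (int i = 0; i < nrow; ++i)
      for (int k = 0; k < 4; ++k) tm(i, k) = traj[4 * i + k];
    out["trajectories"] = tm;
  }
  return out;
}
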