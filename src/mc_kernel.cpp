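#include <Rcpp.h>
using namespace Rcpp;

// Metropolis block on a fixed lattice.
//
// spins:  +/-1 per site; nbr: sites x z matrix of 0-based neighbour indices
// (a neighbour slot list: on side-2 periodic lattices opposite slots repeat,
// which is the convention matched by the bond list used for energies).
// Energy: H = -(J/2) sum_i sum_{j in nbr(i)} s_i s_j - h sum_i s_i,
// temperature and energies in Kelvin.  One sweep = N attempted flips at
// uniformly random sites; acceptance min(1, exp(-dE/T)).  Uses R's RNG so
// set.seed() in R fully determines the trajectory.
//
// Returns the updated spins, per-sweep magnetization, block means of
// magnetization and energy per site, and the acceptance rate.
// [[Rcpp::export]]
List mc_block(IntegerVector spins, IntegerMatrix nbr, double J, double h,
              double T, int nsweeps) {
  int N = spins.size();
  int z = nbr.ncol();
  IntegerVector s = clone(spins);

  // initial energy and magnetization
  double E = 0.0;
  long sumS = 0;
  for (int i = 0; i < N; ++i) {
    double nb = 0.0;
    for (int k = 0; k < z; ++k) nb += s[nbr(i, k)];
    E += -0.5 * J * s[i] * nb - h * s[i];
    sumS += s[i];
  }

  NumericVector m_sweep(nsweeps);
  double m_acc = 0.0, e_acc = 0.0;
  long accepted = 0;
  RNGScope scope;
  for (int sw = 0; sw < nsweeps; ++sw) {
    for (int a = 0; a < N; ++a) {
      int i = (int)(unif_rand() * N);
      if (i == N) i = N - 1;
      double nb = 0.0;
      for (int k = 0; k < z; ++k) nb += s[nbr(i, k)];
      double dE = 2.0 * s[i] * (J * nb + h);
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / T)) {
        sumS -= 2L * s[i];
        E += dE;
        s[i] = -s[i];
        ++accepted;
      }
    }
    double m = (double)sumS / N;
    m_sweep[sw] = m;
    m_acc += m;
    e_acc += E / N;
  }
  return List::create(
    _["spins"] = s,
    _["m_sweep"] = m_sweep,
    _["m_mean"] = m_acc / nsweeps,
    _["e_mean"] = e_acc / nsweeps,
    _["acc_rate"] = (double)accepted / ((double)N * nsweeps));
}
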