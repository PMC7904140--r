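#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact continuous-time simulation of the two-type birth-death-mutation
// process under the infinite-sites model.
//
// Cells are aggregated implicitly: we keep one integer per cell giving its
// genotype, and genotypes form a tree where each node adds exactly one new
// mutation to its parent.  Per-cell event rates are constant within a type,
// so an event is drawn by (i) choosing the event channel from the aggregate
// rates and (ii) choosing a uniform cell of the relevant type; both are O(1).
// Carrier counts are recovered at the end by one pass up the genotype tree.
//
// Uses R's RNG, so results are reproducible via set.seed() on the R side.

// [[Rcpp::export]]
List gillespie_two_type(double a0, double b0, double a1, double b1,
                        double u1, double nu,
                        double t_max, double n_max, double cell_cap,
                        int record_every) {
  // genotype tree; genotype 0 is the mutation-free root
  std::vector<int> g_parent(1, -1);
  std::vector<double> g_time(1, 0.0);
  std::vector<int> g_class(1, -1);     // 0 = type-0 neutral, 1 = driver (1A),
                                       // 2 = type-1 neutral, -1 = root
  std::vector<int> cells0(1, 0);       // genotype of each type-0 cell
  std::vector<int> cells1;             // genotype of each type-1 cell

  double t = 0.0;
  bool aborted = false;
  long long n_events = 0;

  std::vector<double> traj_t, traj_z0, traj_z1;

  const double r0 = a0 + b0 + u1 + nu; // per type-0 cell
  const double r1 = a1 + b1 + nu;      // per type-1 cell

  while (true) {
    const double z0 = (double)cells0.size();
    const double z1 = (double)cells1.size();
    if (z0 + z1 <= 0.0) break;                     // extinct
    if (n_max > 0 && z0 + z1 >= n_max) break;      // reached target size
    if (z0 + z1 >= cell_cap ||
        (double)g_parent.size() >= cell_cap * 16) {
      aborted = true;                              // memory guard
      break;
    }
    const double total = z0 * r0 + z1 * r1;
    t += R::rexp(1.0 / total);
    if (t_max > 0 && t > t_max) { t = t_max; break; }
    ++n_events;
    if (record_every > 0 && n_events % record_every == 0) {
      traj_t.push_back(t);
      traj_z0.push_back(z0);
      traj_z1.push_back(z1);
    }

    double u = R::unif_rand() * total;
    if (u < z0 * r0) {
      // event on a uniform type-0 cell
      int idx = (int)(R::unif_rand() * z0);
      if (idx >= (int)cells0.size()) idx = (int)cells0.size() - 1;
      double v = R::unif_rand() * r0;
      if (v < a0) {                                 // birth
        cells0.push_back(cells0[idx]);
      } else if (v < a0 + b0) {                     // death: swap-remove
        cells0[idx] = cells0.back();
        cells0.pop_back();
      } else if (v < a0 + b0 + u1) {                // driver mutation -> type 1
        g_parent.push_back(cells0[idx]);
        g_time.push_back(t);
        g_class.push_back(1);
        cells1.push_back((int)g_parent.size() - 1);
        cells0[idx] = cells0.back();
        cells0.pop_back();
      } else {                                      // neutral mutation
        g_parent.push_back(cells0[idx]);
        g_time.push_back(t);
        g_class.push_back(0);
        cells0[idx] = (int)g_parent.size() - 1;
      }
    } else {
      // event on a uniform type-1 cell
      int idx = (int)(R::unif_rand() * z1);
      if (idx >= (int)cells1.size()) idx = (int)cells1.size() - 1;
      double v = R::unif_rand() * r1;
      if (v < a1) {
        cells1.push_back(cells1[idx]);
      } else if (v < a1 + b1) {
        cells1[idx] = cells1.back();
        cells1.pop_back();
      } else {
        g_parent.push_back(cells1[idx]);
        g_time.push_back(t);
        g_class.push_back(2);
        cells1[idx] = (int)g_parent.size() - 1;
      }
    }
  }

  // carrier counts: tally cells per genotype, then push counts up the tree
  const int n_g = (int)g_parent.size();
  std::vector<double> acc(n_g, 0.0);
  for (size_t i = 0; i < cells0.size(); ++i) acc[cells0[i]] += 1.0;
  for (size_t i = 0; i < cells1.size(); ++i) acc[cells1[i]] += 1.0;
  for (int g = n_g - 1; g >= 1; --g) acc[g_parent[g]] += acc[g];

  // mutation table (genotype g >= 1 corresponds to mutation id g)
  const int n_mut = n_g - 1;
  IntegerVector m_id(n_mut), m_class(n_mut);
  NumericVector m_time(n_mut), m_carriers(n_mut);
  for (int g = 1; g < n_g; ++g) {
    m_id[g - 1] = g;
    m_class[g - 1] = g_class[g];
    m_time[g - 1] = g_time[g];
    m_carriers[g - 1] = acc[g];
  }

  return List::create(
      _["t_end"] = t,
      _["z0"] = (double)cells0.size(),
      _["z1"] = (double)cells1.size(),
      _["n_events"] = (double)n_events,
      _["aborted"] = aborted,
      _["mut_id"] = m_id,
      _["mut_class"] = m_class,
      _["mut_time"] = m_time,
      _["mut_carriers"] = m_carriers,
      _["traj_t"] = traj_t,
      _["traj_z0"] = traj_z0,
      _["traj_z1"] = traj_z1);
}
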