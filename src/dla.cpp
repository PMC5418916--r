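#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

namespace {

inline long long key_of(int x, int y) {
  return (static_cast<long long>(x) << 32) ^ (static_cast<unsigned int>(y));
}

}

// Lattice diffusion-limited aggregation in 2D. Walkers are launched on a
// circle of radius (cluster radius + launch_margin), take unit steps on the
// 4-connected lattice, are discarded beyond kill_factor * launch radius, and
// stick at the first position face-adjacent to the cluster. Uses R's RNG so
// set.seed() makes growth reproducible.
// [[Rcpp::export]]
IntegerMatrix cpp_grow_dla(int n_particles, double launch_margin,
                           double kill_factor, double max_attempts_per_particle) {
  std::unordered_set<long long> cluster;
  std::vector<int> xs, ys;
  xs.reserve(n_particles + 1);
  ys.reserve(n_particles + 1);
  cluster.insert(key_of(0, 0));
  xs.push_back(0); ys.push_back(0);

  const int dx[4] = {1, -1, 0, 0};
  const int dy[4] = {0, 0, 1, -1};
  double r_agg = 0.0;
  double attempts = 0.0;
  const double budget = max_attempts_per_particle * std::max(1, n_particles);

  for (int p = 0; p < n_particles; ++p) {
    bool stuck = false;
    while (!stuck) {
      attempts += 1.0;
      if (attempts > budget)
        stop("walker budget exhausted after attaching %d of %d particles",
             p, n_particles);
      double r_launch = r_agg + launch_margin;
      double ang = 2.0 * M_PI * unif_rand();
      int x = (int)std::lround(r_launch * std::cos(ang));
      int y = (int)std::lround(r_launch * std::sin(ang));
      if (cluster.count(key_of(x, y))) continue;
      double r_kill = kill_factor * r_launch;
      double r_kill2 = r_kill * r_kill;
      while (true) {
        bool adjacent = false;
        for (int d = 0; d < 4; ++d) {
          if (cluster.count(key_of(x + dx[d], y + dy[d]))) { adjacent = true; break; }
        }
        if (adjacent) {
          cluster.insert(key_of(x, y));
          xs.push_back(x); ys.push_back(y);
          double rr = std::sqrt((double)x * x + (double)y * y);
          if (rr > r_agg) r_agg = rr;
          stuck = true;
          break;
        }
        int step = (int)(unif_rand() * 4.0);
        if (step > 3) step = 3;
        x += dx[step];
        y += dy[step];
        if ((double)x * x + (double)y * y > r_kill2) break; // killed, relaunch
      }
    }
  }

  IntegerMatrix out(xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i];
    out(i, 1) = ys[i];
  }
  return out;
}
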