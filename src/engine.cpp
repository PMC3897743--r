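// Per-iteration engine for the energy-allocation aging model.
//
// The iteration schedule, arithmetic expressions and RNG draw order are
// mirrored exactly by the pure-R reference stepper in R/step.R; a test pins
// bit-identical trajectories between the two. All randomness comes from R's
// generator (unif_rand), so runs are reproducible under set.seed().
//
// Draw order per iteration:
//   1. pool generation (no draws)
//   2. foraging permutation (Fisher-Yates, n-1 draws), then one uniform per
//      individual in permuted order (costs deducted first, then foraging)
//   3. starvation removals (no draws)
//   4. predation: one uniform per alive individual in storage order
//   5. intrinsic-death removals (no draws)
//   6. mating: permutation of eligible females, then per attempt one uniform
//      for male choice and one for the pregnancy outcome
//   7. births: per litter one uniform (declining mode), per offspring two
//      uniforms per trait (+ redraws for ordering) and one for sex
//   8. age increment, newborns appended
//   9. statistics

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pop {
  std::vector<double> energy, age, tmat, tdie, fa_tmat, fa_tdie;
  std::vector<int> female, gest, mated_iter;

  size_t size() const { return energy.size(); }

  void reserve(size_t n) {
    energy.reserve(n); age.reserve(n); tmat.reserve(n); tdie.reserve(n);
    fa_tmat.reserve(n); fa_tdie.reserve(n);
    female.reserve(n); gest.reserve(n); mated_iter.reserve(n);
  }

  void push(double e, double a, int fem, double tm, double td) {
    energy.push_back(e); age.push_back(a); female.push_back(fem);
    tmat.push_back(tm); tdie.push_back(td);
    gest.push_back(0); mated_iter.push_back(0);
    fa_tmat.push_back(0.0); fa_tdie.push_back(0.0);
  }

  // stable in-place removal of flagged individuals
  size_t remove(const std::vector<char>& dead) {
    size_t kept = 0, n = size(), removed = 0;
    for (size_t i = 0; i < n; ++i) {
      if (dead[i]) { ++removed; continue; }
      if (kept != i) {
        energy[kept] = energy[i]; age[kept] = age[i];
        tmat[kept] = tmat[i]; tdie[kept] = tdie[i];
        fa_tmat[kept] = fa_tmat[i]; fa_tdie[kept] = fa_tdie[i];
        female[kept] = female[i]; gest[kept] = gest[i];
        mated_iter[kept] = mated_iter[i];
      }
      ++kept;
    }
    energy.resize(kept); age.resize(kept); tmat.resize(kept);
    tdie.resize(kept); fa_tmat.resize(kept); fa_tdie.resize(kept);
    female.resize(kept); gest.resize(kept); mated_iter.resize(kept);
    return removed;
  }
};

struct Par {
  double n_modifier, c_adult, x, pred_density_exp, ev_mat, ev_die,
    size_ratio, storage_factor,
    forage_rate, forage_size_exp, pool_cap, gen_rate, growth_eff, e_mate,
    mate_threshold, e_init, e_mature;
  int gestation, d_type, fec_increasing, pred_on_start, max_redraw;
  double d_scale, d_lin_tref, d_asym_half, d_sig_mid, d_sig_width,
    d_high_factor;
};

double frac_size(double age, double tmat, const Par& p) {
  return std::min(1.0, std::pow(p.size_ratio, age / tmat - 1.0));
}

double repair_base(double tdie, const Par& p) {
  double level = (p.d_type >= 3) ? p.d_high_factor : 1.0;
  int shape = p.d_type % 3;  // 0 sigmoidal, 1 linear, 2 asymptotic
  double base;
  if (shape == 1)
    base = p.d_scale * tdie / p.d_lin_tref;
  else if (shape == 2)
    base = p.d_scale * tdie / (tdie + p.d_asym_half);
  else
    base = p.d_scale / (1.0 + std::exp(-(tdie - p.d_sig_mid) / p.d_sig_width));
  return level * base;
}

// Fisher-Yates with floor(u * i), matching the R reference exactly.
void permute(std::vector<int>& perm) {
  size_t n = perm.size();
  if (n < 2) return;
  for (size_t i = n; i > 1; --i) {
    double u = unif_rand();
    size_t j = (size_t)std::floor(u * (double)i);
    if (j >= i) j = i - 1;
    std::swap(perm[i - 1], perm[j]);
  }
}

Par read_par(const List& par) {
  Par p;
  p.n_modifier = as<double>(par["n_modifier"]);
  p.c_adult = as<double>(par["c_adult"]);
  p.x = as<double>(par["x"]);
  p.pred_density_exp = as<double>(par["pred_density_exp"]);
  p.ev_mat = as<double>(par["evolvability_mat"]);
  p.ev_die = as<double>(par["evolvability_die"]);
  p.size_ratio = as<double>(par["size_ratio"]);
  p.storage_factor = as<double>(par["storage_factor"]);
  p.forage_rate = as<double>(par["forage_rate"]);
  p.forage_size_exp = as<double>(par["forage_size_exp"]);
  p.pool_cap = as<double>(par["pool_cap"]);
  p.gen_rate = as<double>(par["gen_rate"]);
  p.growth_eff = as<double>(par["growth_eff"]);
  p.e_mate = as<double>(par["e_mate"]);
  p.mate_threshold = as<double>(par["mate_threshold"]);
  p.e_init = as<double>(par["e_init"]);
  p.e_mature = as<double>(par["e_mature"]);
  p.gestation = as<int>(par["gestation"]);
  p.d_type = as<int>(par["d_type"]);
  p.fec_increasing = as<int>(par["fec_increasing"]);
  p.pred_on_start = as<int>(par["pred_on_start"]);
  p.max_redraw = as<int>(par["max_redraw"]);
  p.d_scale = as<double>(par["d_scale"]);
  p.d_lin_tref = as<double>(par["d_lin_tref"]);
  p.d_asym_half = as<double>(par["d_asym_half"]);
  p.d_sig_mid = as<double>(par["d_sig_mid"]);
  p.d_sig_width = as<double>(par["d_sig_width"]);
  p.d_high_factor = as<double>(par["d_high_factor"]);
  return p;
}

const int NSTAT = 21;

}  // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List par, NumericVector energy0, NumericVector age0,
                IntegerVector female0, NumericVector tmat0,
                NumericVector tdie0, double pool0, int duration,
                int record_every) {
  Par p = read_par(par);

  Pop pop;
  size_t n0 = energy0.size();
  pop.reserve(std::max((size_t)256, 4 * n0));
  for (size_t i = 0; i < n0; ++i)
    pop.push(energy0[i], age0[i], female0[i], tmat0[i], tdie0[i]);

  double pool = pool0;
  bool extinct = (pop.size() == 0);
  int extinct_iter = extinct ? 0 : NA_INTEGER;

  int n_rec_max = (record_every > 0 ? duration / record_every : 0) + 2;
  NumericMatrix stats(n_rec_max, NSTAT);
  int n_rec = 0;

  std::vector<int> perm;
  std::vector<char> dead;
  Pop born;

  // per-death log: cause 1 = starved, 2 = eaten, 3 = aged
  std::vector<double> d_iter, d_cause, d_age, d_tdie, d_tmat;

  for (int t = 1; t <= duration && !extinct; ++t) {
    // 1. pool generation, clamped at capacity
    double pool_before = pool;
    pool = std::min(pool + p.gen_rate, p.pool_cap);
    double generated = pool - pool_before;

    size_t n = pop.size();
    size_t n_start = n;

    // 2. costs then foraging, individuals in fresh random order
    perm.resize(n);
    for (size_t i = 0; i < n; ++i) perm[i] = (int)i;
    permute(perm);

    double juv_rep = 0, juv_mat = 0, juv_met = 0;
    double mat_rep = 0, mat_met = 0, mat_repro = 0;
    double foraged_total = 0, cost_total = 0;

    for (size_t k = 0; k < n; ++k) {
      size_t i = (size_t)perm[k];
      double a = pop.age[i], tm = pop.tmat[i], td = pop.tdie[i];
      double s = frac_size(a, tm, p);
      double rep_c = s * repair_base(td, p);
      double mat_c;
      if (a >= tm) {
        mat_c = 0.0;
      } else {
        double s_next = frac_size(a + 1.0, tm, p);
        mat_c = p.e_mature * (s_next - s) / p.growth_eff;
      }
      double met_c = p.c_adult * s;
      double total = rep_c + mat_c + met_c;
      if (a < tm) { juv_rep += rep_c; juv_mat += mat_c; juv_met += met_c; }
      else { mat_rep += rep_c; mat_met += met_c; }
      pop.energy[i] -= total;
      cost_total += total;

      double u = unif_rand();
      double sal = std::pow(s, p.forage_size_exp);
      double capacity = sal * (p.forage_rate + u);
      double headroom = p.storage_factor * sal * (p.forage_rate + 1.0) -
        pop.energy[i];
      double gained = std::max(0.0, std::min(capacity,
                                             std::min(pool, headroom)));
      pop.energy[i] += gained;
      pool -= gained;
      foraged_total += gained;
    }

    // 3. starvation: stored energy strictly below zero
    dead.assign(pop.size(), 0);
    for (size_t i = 0; i < pop.size(); ++i)
      if (pop.energy[i] < 0.0) dead[i] = 1;
    for (size_t i = 0; i < pop.size(); ++i)
      if (dead[i]) {
        d_iter.push_back(t); d_cause.push_back(1.0);
        d_age.push_back(pop.age[i]); d_tdie.push_back(pop.tdie[i]);
        d_tmat.push_back(pop.tmat[i]);
      }
    size_t starved = pop.remove(dead);

    // 4. density-dependent predation (one draw per alive individual)
    size_t n2 = pop.size();
    double dens_count = p.pred_on_start ? (double)n_start : (double)n2;
    double pprob = std::min(
      1.0, p.x * std::pow(dens_count / p.n_modifier, p.pred_density_exp));
    dead.assign(n2, 0);
    for (size_t i = 0; i < n2; ++i) {
      double u = unif_rand();
      if (u < pprob) dead[i] = 1;
    }
    for (size_t i = 0; i < pop.size(); ++i)
      if (dead[i]) {
        d_iter.push_back(t); d_cause.push_back(2.0);
        d_age.push_back(pop.age[i]); d_tdie.push_back(pop.tdie[i]);
        d_tmat.push_back(pop.tmat[i]);
      }
    size_t eaten = pop.remove(dead);
    double pred_frac = n2 > 0 ? (double)eaten / (double)n2 : NA_REAL;

    // 5. intrinsic aging death: age reached or surpassed t_die
    dead.assign(pop.size(), 0);
    for (size_t i = 0; i < pop.size(); ++i)
      if (pop.age[i] >= pop.tdie[i]) dead[i] = 1;
    for (size_t i = 0; i < pop.size(); ++i)
      if (dead[i]) {
        d_iter.push_back(t); d_cause.push_back(3.0);
        d_age.push_back(pop.age[i]); d_tdie.push_back(pop.tdie[i]);
        d_tmat.push_back(pop.tmat[i]);
      }
    size_t aged = pop.remove(dead);

    // 6. mating: each eligible female, in random order, attempts eligible
    //    males sampled without replacement until pregnant, out of energy,
    //    or out of bachelors; both sides pay e_mate per attempt
    std::vector<int> F, M;
    for (size_t i = 0; i < pop.size(); ++i) {
      if (pop.age[i] >= pop.tmat[i]) {
        if (pop.female[i]) {
          if (pop.energy[i] > p.mate_threshold && !pop.gest[i])
            F.push_back((int)i);
        } else {
          M.push_back((int)i);
        }
      }
    }
    permute(F);
    double mating_total = 0;
    std::vector<char> tried;
    std::vector<int> avail;
    for (size_t kf = 0; kf < F.size(); ++kf) {
      size_t f = (size_t)F[kf];
      tried.assign(M.size(), 0);
      while (pop.energy[f] > p.mate_threshold && !pop.gest[f]) {
        avail.clear();
        for (size_t km = 0; km < M.size(); ++km)
          if (!tried[km] && pop.energy[(size_t)M[km]] > p.mate_threshold)
            avail.push_back((int)km);
        if (avail.empty()) break;
        double u = unif_rand();
        size_t j = (size_t)std::floor(u * (double)avail.size());
        if (j >= avail.size()) j = avail.size() - 1;
        size_t km = (size_t)avail[j];
        size_t m = (size_t)M[km];
        tried[km] = 1;
        pop.energy[f] -= p.e_mate;
        pop.energy[m] -= p.e_mate;
        mat_repro += 2.0 * p.e_mate;
        mating_total += 2.0 * p.e_mate;
        double pp;
        if (p.fec_increasing) {
          pp = 0.5;
        } else {
          pp = (pop.tdie[f] - pop.age[f]) / (pop.tdie[f] - pop.tmat[f]);
          pp = std::min(1.0, std::max(0.0, pp));
        }
        double u2 = unif_rand();
        if (u2 < pp) {
          pop.gest[f] = 1;
          pop.mated_iter[f] = t;
          pop.fa_tmat[f] = pop.tmat[m];
          pop.fa_tdie[f] = pop.tdie[m];
        }
      }
    }

    // 7. births from females that finished gestating
    born.energy.clear(); born.age.clear(); born.tmat.clear();
    born.tdie.clear(); born.fa_tmat.clear(); born.fa_tdie.clear();
    born.female.clear(); born.gest.clear(); born.mated_iter.clear();
    int births = 0;
    for (size_t i = 0; i < pop.size(); ++i) {
      if (!(pop.female[i] && pop.gest[i] &&
            t - pop.mated_iter[i] >= p.gestation))
        continue;
      int litter;
      if (p.fec_increasing) {
        double raw = std::floor(
          1.0 + 8.0 * (pop.age[i] - pop.tmat[i]) /
                (pop.tdie[i] - pop.tmat[i]));
        litter = (int)std::min(8.0, std::max(1.0, raw));
      } else {
        double u = unif_rand();
        litter = u < 0.5 ? 1 : 2;
      }
      for (int z = 0; z < litter; ++z) {
        double u = unif_rand(), v = unif_rand();
        double tm = (u * pop.tmat[i] + (1.0 - u) * pop.fa_tmat[i]) *
          (1.0 + p.ev_mat * (2.0 * v - 1.0));
        double td;
        int tries = 0;
        do {
          double u2 = unif_rand(), v2 = unif_rand();
          td = (u2 * pop.tdie[i] + (1.0 - u2) * pop.fa_tdie[i]) *
            (1.0 + p.ev_die * (2.0 * v2 - 1.0));
          ++tries;
        } while (td <= tm && tries <= p.max_redraw);
        if (td <= tm) td = tm + 1.0;
        double u3 = unif_rand();
        born.push(p.e_init, 0.0, u3 < 0.5 ? 1 : 0, tm, td);
      }
      pop.gest[i] = 0;
      births += litter;
    }

    // 8. ages advance for pre-existing individuals; newborns join at age 0
    for (size_t i = 0; i < pop.size(); ++i) pop.age[i] += 1.0;
    for (size_t i = 0; i < born.size(); ++i)
      pop.push(born.energy[i], born.age[i], born.female[i], born.tmat[i],
               born.tdie[i]);

    size_t np = pop.size();
    if (np == 0) { extinct = true; extinct_iter = t; }

    // 9. statistics
    bool rec = extinct || (record_every > 0 && t % record_every == 0);
    if (rec && n_rec < n_rec_max) {
      double sum_tm = 0, sum_td = 0, sum_em = 0;
      size_t n_mature = 0;
      for (size_t i = 0; i < np; ++i) {
        sum_tm += pop.tmat[i];
        sum_td += pop.tdie[i];
        if (pop.age[i] >= pop.tmat[i]) { sum_em += pop.energy[i]; ++n_mature; }
      }
      double juv_tot = juv_rep + juv_mat + juv_met;
      double mat_tot = mat_rep + mat_repro + mat_met;
      int r = n_rec++;
      stats(r, 0) = t;
      stats(r, 1) = (double)np;
      stats(r, 2) = pool;
      stats(r, 3) = births;
      stats(r, 4) = (double)starved;
      stats(r, 5) = (double)eaten;
      stats(r, 6) = (double)aged;
      stats(r, 7) = np > 0 ? sum_tm / (double)np : NA_REAL;
      stats(r, 8) = np > 0 ? sum_td / (double)np : NA_REAL;
      stats(r, 9) = n_mature > 0 ? sum_em / (double)n_mature : NA_REAL;
      stats(r, 10) = juv_tot > 0 ? juv_rep / juv_tot : NA_REAL;
      stats(r, 11) = juv_tot > 0 ? juv_mat / juv_tot : NA_REAL;
      stats(r, 12) = juv_tot > 0 ? juv_met / juv_tot : NA_REAL;
      stats(r, 13) = mat_tot > 0 ? mat_rep / mat_tot : NA_REAL;
      stats(r, 14) = mat_tot > 0 ? mat_repro / mat_tot : NA_REAL;
      stats(r, 15) = mat_tot > 0 ? mat_met / mat_tot : NA_REAL;
      stats(r, 16) = pred_frac;
      stats(r, 17) = generated;
      stats(r, 18) = foraged_total;
      stats(r, 19) = cost_total;
      stats(r, 20) = mating_total;
    }
  }

  NumericMatrix out_stats(n_rec, NSTAT);
  for (int r = 0; r < n_rec; ++r)
    for (int c = 0; c < NSTAT; ++c) out_stats(r, c) = stats(r, c);

  size_t np = pop.size();
  NumericVector f_tmat(np), f_tdie(np), f_energy(np), f_age(np);
  IntegerVector f_female(np);
  for (size_t i = 0; i < np; ++i) {
    f_tmat[i] = pop.tmat[i]; f_tdie[i] = pop.tdie[i];
    f_energy[i] = pop.energy[i]; f_age[i] = pop.age[i];
    f_female[i] = pop.female[i];
  }

  return List::create(
    _["stats"] = out_stats, _["pool"] = pool,
    _["t_mat"] = f_tmat, _["t_die"] = f_tdie,
    _["energy"] = f_energy, _["age"] = f_age, _["female"] = f_female,
    _["extinct"] = extinct, _["extinct_iter"] = extinct_iter,
    _["death_iter"] = wrap(d_iter), _["death_cause"] = wrap(d_cause),
    _["death_age"] = wrap(d_age), _["death_tdie"] = wrap(d_tdie),
    _["death_tmat"] = wrap(d_tmat));
}
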