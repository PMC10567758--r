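#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Discrete-event tau-leaping kernel. One step:
//   dt = P_events / max(beta*T/s, c, nE/tauE, nI/tauI)
//   E_out[i] ~ Binomial(E[i], dt*nE/tauE)         i = 1..nE
//   I_out[j] ~ Binomial(I[j], dt*nI/tauI)         j = 1..nI
//   V_prod  ~ Poisson(dt * p * sum(I))
//   (V_decay, V_enter) ~ Trinomial(V, dt*c, dt*beta*T/s), realized exactly as
//       V_decay ~ Binomial(V, p1); V_enter ~ Binomial(V - V_decay, p2/(1-p1))
//   V_suc   ~ Binomial(V_enter, gamma)
//   N_inf   = #distinct cells among V_suc uniform draws on {1..T}
// The draw order above is part of the reproducibility contract: the pure-R
// engine makes the identical sequence of R RNG calls, so both engines give
// bit-identical runs from the same seed.

static inline int count_unique_draws(int T, int V_suc) {
  if (T <= 0 || V_suc <= 0) return 0;
  if (T == 1) return 1;
  std::vector<int> idx(V_suc);
  for (int k = 0; k < V_suc; ++k) {
    idx[k] = (int)std::floor(unif_rand() * (double)T);
  }
  std::sort(idx.begin(), idx.end());
  int n = 1;
  for (int k = 1; k < V_suc; ++k) if (idx[k] != idx[k - 1]) ++n;
  return n;
}

// [[Rcpp::export]]
List cpp_sm_run(double beta, double p, double c, double gamma,
                int nE, int nI, double tauE, double tauI,
                double Ncells, double s, int V0, int I0,
                double P_events, double max_time, bool record) {
  double T = Ncells;
  std::vector<double> E(nE, 0.0), I(nI, 0.0);
  double V = V0;
  I[0] = I0;
  double t = 0.0;
  double cum_inf = 0.0, cum_prod = 0.0;
  long steps = 0;
  bool censored = false;

  const double rE = nE / tauE, rI = nI / tauI;
  std::vector<double> traj;
  const int ncol = 3 + nE + nI;
  std::vector<double> Eout(nE), Iout(nI);

  auto push_row = [&]() {
    traj.push_back(t);
    traj.push_back(T);
    for (int i = 0; i < nE; ++i) traj.push_back(E[i]);
    for (int j = 0; j < nI; ++j) traj.push_back(I[j]);
    traj.push_back(V);
  };
  if (record) push_row();

  for (;;) {
    double sumE = 0.0, sumI = 0.0;
    for (int i = 0; i < nE; ++i) sumE += E[i];
    for (int j = 0; j < nI; ++j) sumI += I[j];
    if (V <= 0.0 && sumE <= 0.0 && sumI <= 0.0) break;
    if (t >= max_time) { censored = true; break; }

    double rmax = std::max(std::max(beta * T / s, c), std::max(rE, rI));
    double dt = P_events / rmax;
    double pE = dt * rE, pI = dt * rI;
    double p1 = dt * c, p2 = dt * beta * T / s;

    for (int i = 0; i < nE; ++i) Eout[i] = R::rbinom(E[i], pE);
    for (int j = 0; j < nI; ++j) Iout[j] = R::rbinom(I[j], pI);
    double Vprod = R::rpois(dt * p * sumI);
    double Vdecay = R::rbinom(V, p1);
    double Venter = R::rbinom(V - Vdecay, p2 / (1.0 - p1));
    double Vsuc = R::rbinom(Venter, gamma);
    int Ninf = count_unique_draws((int)T, (int)Vsuc);

    T -= Ninf;
    E[0] += Ninf - Eout[0];
    for (int i = 1; i < nE; ++i) E[i] += Eout[i - 1] - Eout[i];
    I[0] += Eout[nE - 1] - Iout[0];
    for (int j = 1; j < nI; ++j) I[j] += Iout[j - 1] - Iout[j];
    V += Vprod - Vdecay - Venter;
    cum_inf += Ninf;
    cum_prod += Vprod;
    t += dt;
    ++steps;
    if (record) push_row();
  }

  List out = List::create(
    _["t"] = t,
    _["T"] = T,
    _["E"] = NumericVector(E.begin(), E.end()),
    _["I"] = NumericVector(I.begin(), I.end()),
    _["V"] = V,
    _["cells_consumed"] = Ncells - T,
    _["cumulative_infected"] = cum_inf,
    _["cumulative_virions_produced"] = cum_prod,
    _["steps"] = (double)steps,
    _["censored"] = censored
  );
  if (record) {
    int nrow = traj.size() / ncol;
    NumericMatrix m(nrow, ncol);
    for (int r = 0; r < nrow; ++r)
      for (int ccol = 0; ccol < ncol; ++ccol)
        m(r, ccol) = traj[(size_t)r * ncol + ccol];
    out["trajectory"] = m;
  }
  return out;
}

// Burst sizes of single infectious cells at the time step `dt` of the full
// simulator. The residence of a cell in each of the nI compartments lasts
// 1 + Geometric(pI) steps (the exact law of repeated Bernoulli(pI) exit
// draws); over K total steps production is Poisson(K * dt * p). Both
// shortcuts are distributionally identical to stepping the cell one dt at a
// time while retaining the finite-dt discretization of the kernel.
// [[Rcpp::export]]
IntegerVector cpp_sample_bursts(int n, double p, int nI, double tauI,
                                double dt) {
  double pI = dt * nI / tauI;
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    double K = 0.0;
    for (int j = 0; j < nI; ++j) K += 1.0 + R::rgeom(pI);
    out[k] = (int)R::rpois(K * dt * p);
  }
  return out;
}

// Fate of single virions in a fully susceptible population held at T=Ncells:
// per step the virion decays (p1), enters a cell (p2) and then succeeds with
// probability gamma, or persists. Returns 1 for each virion that caused a
// productive infection, 0 otherwise.
// [[Rcpp::export]]
IntegerVector cpp_virion_success(int n, double beta, double c, double gamma,
                                 double Ncells, double s,
                                 double rE, double rI, double P_events) {
  double rmax = std::max(std::max(beta * Ncells / s, c), std::max(rE, rI));
  double dt = P_events / rmax;
  double p1 = dt * c, p2 = dt * beta * Ncells / s;
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    int res = 0;
    for (;;) {
      if (R::rbinom(1.0, p1) > 0) { res = 0; break; }
      if (R::rbinom(1.0, p2 / (1.0 - p1)) > 0) {
        res = (R::rbinom(1.0, gamma) > 0) ? 1 : 0;
        break;
      }
    }
    out[k] = res;
  }
  return out;
}
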