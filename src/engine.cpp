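// Exact stochastic simulation (Gillespie) core for host-plasmid community
// dynamics. State is the integer abundance table H[i, p] over (host i,
// plasmid profile p); five event channels: death, growth, segregation,
// competition, infection (conjugation). Cells are flattened as
// c = i * M + p with M = 2^n_p profiles; profile 0 is plasmid-free.
//
// Channel totals are maintained incrementally; exact integer quantities
// (abundances, recipient sums) stay exact in doubles, while floating
// accumulators are refreshed from scratch periodically to bound drift.
// Uses R's RNG stream (unif_rand / exp_rand) so set.seed() governs runs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_gillespie(IntegerMatrix H0,          // n_b x M initial abundances
                   NumericMatrix eta_ip,      // realized growth rates
                   NumericVector mu,
                   NumericVector eseg,
                   NumericVector gam,
                   NumericMatrix bmat,        // competition kernel b_ij
                   double K,
                   IntegerVector rec_ptr,     // length M+1 (0-based, per donor profile)
                   IntegerVector rec_cells,   // recipient cell ids k*M+q
                   IntegerVector tc_ptr,      // per rec_cells entry -> transconjugant run
                   IntegerVector tc_r,        // transconjugant profile (0-based)
                   NumericVector tc_w,        // normalized column weights
                   IntegerVector rev_ptr,     // length n_b*M+1, per cell
                   IntegerVector rev_p,       // donor profiles whose list holds the cell
                   double t_max,
                   double record_interval,
                   bool stop_single_host,
                   bool record_events,
                   double max_events) {
  const int nb = H0.nrow();
  const int M = H0.ncol();
  const int ncell = nb * M;

  std::vector<double> H(ncell);
  for (int i = 0; i < nb; ++i)
    for (int p = 0; p < M; ++p) H[i * M + p] = H0(i, p);

  std::vector<double> Htot(nb), sumEta(nb), sumOm(nb), W(nb), Lsum(M), press(nb);

  auto refresh = [&]() {
    for (int p = 0; p < M; ++p) {
      double s = 0.0;
      for (int j = rec_ptr[p]; j < rec_ptr[p + 1]; ++j) s += H[rec_cells[j]];
      Lsum[p] = s;
    }
    for (int i = 0; i < nb; ++i) {
      double ht = 0.0, se = 0.0, so = 0.0, w = 0.0;
      for (int p = 0; p < M; ++p) {
        const double h = H[i * M + p];
        ht += h;
        se += eta_ip(i, p) * h;
        if (p > 0) {
          so += eseg[i] * eta_ip(i, p) * h;
          w += h * Lsum[p];
        }
      }
      Htot[i] = ht; sumEta[i] = se; sumOm[i] = so; W[i] = w;
    }
  };

  auto applyDelta = [&](int c, int d) {
    const int i = c / M, p = c % M;
    H[c] += d;
    Htot[i] += d;
    const double e = eta_ip(i, p);
    sumEta[i] += d * e;
    if (p > 0) {
      sumOm[i] += d * eseg[i] * e;
      W[i] += d * Lsum[p];
    }
    for (int j = rev_ptr[c]; j < rev_ptr[c + 1]; ++j) {
      const int pp = rev_p[j];
      Lsum[pp] += d;
      for (int h = 0; h < nb; ++h) W[h] += H[h * M + pp] * d;
    }
  };

  refresh();

  // snapshot storage (sparse: nonzero cells per snapshot)
  std::vector<double> snap_t;
  std::vector<int> snap_cell, snap_ab, snap_len;
  auto record_state = [&](double tt) {
    if (!snap_t.empty() && snap_t.back() == tt) return;
    snap_t.push_back(tt);
    int len = 0;
    for (int c = 0; c < ncell; ++c) {
      if (H[c] > 0) { snap_cell.push_back(c); snap_ab.push_back((int)H[c]); ++len; }
    }
    snap_len.push_back(len);
  };

  std::vector<int> ev_ch, ev_a, ev_b, ev_c;
  std::vector<double> ev_dt, ev_R;

  double t = 0.0;
  double next_rec = record_interval;
  record_state(0.0);
  std::string termination = "t_max";
  double n_events = 0.0;
  const double eps = 1e-12;

  // pick index from weights via linear cascade; fallback = last positive
  auto pick = [&](const double* w, int n, double u) {
    int last = -1;
    for (int i = 0; i < n; ++i) {
      if (w[i] <= 0) continue;
      last = i;
      if (u < w[i]) return i;
      u -= w[i];
    }
    return last;
  };

  std::vector<double> wbuf(std::max(ncell, M));

  while (true) {
    if (((long long)n_events & 0xFFFFF) == 0xFFFFF) Rcpp::checkUserInterrupt();
    if (((long long)n_events & 0x3FFFFF) == 0x3FFFFF) refresh();

    // channel totals
    double R_D = 0.0, R_G = 0.0, R_S = 0.0, R_C = 0.0, R_I = 0.0;
    for (int i = 0; i < nb; ++i) {
      R_D += mu[i] * Htot[i];
      R_G += sumEta[i];
      R_S += sumOm[i];
      double pr = 0.0;
      for (int j = 0; j < nb; ++j) pr += bmat(i, j) * Htot[j];
      press[i] = pr / K;
      R_C += sumEta[i] * press[i];
      R_I += gam[i] * W[i];
    }
    if (R_S < 0) R_S = 0;
    if (R_I < 0) R_I = 0;
    const double R = R_D + R_G + R_S + R_C + R_I;
    if (R <= eps) { termination = "collapse"; record_state(t); break; }

    const double dt = exp_rand() / R;
    const double tnew = t + dt;
    if (tnew >= t_max) {
      while (next_rec <= t_max + 1e-9) { record_state(next_rec); next_rec += record_interval; }
      t = t_max;
      termination = "t_max";
      record_state(t_max);
      break;
    }

    // channel
    double u = unif_rand() * R;
    int channel;
    if (u < R_D) channel = 0;
    else if ((u -= R_D) < R_G) channel = 1;
    else if ((u -= R_G) < R_S) channel = 2;
    else if ((u -= R_S) < R_C) channel = 3;
    else channel = 4;

    int cell_a = -1, cell_b = -1, cell_c = -1;

    if (channel == 0) { // death: host ~ mu_i Htot_i, cell ~ H
      for (int i = 0; i < nb; ++i) wbuf[i] = mu[i] * Htot[i];
      const int i = pick(wbuf.data(), nb, unif_rand() * R_D);
      for (int p = 0; p < M; ++p) wbuf[p] = H[i * M + p];
      const int p = pick(wbuf.data(), M, unif_rand() * Htot[i]);
      cell_a = i * M + p;
      applyDelta(cell_a, -1);
    } else if (channel == 1) { // growth: host ~ sumEta, cell ~ eta H
      const int i = pick(sumEta.data(), nb, unif_rand() * R_G);
      for (int p = 0; p < M; ++p) wbuf[p] = eta_ip(i, p) * H[i * M + p];
      const int p = pick(wbuf.data(), M, unif_rand() * sumEta[i]);
      cell_a = i * M + p;
      applyDelta(cell_a, +1);
    } else if (channel == 2) { // segregation: plasmid-free daughter
      const int i = pick(sumOm.data(), nb, unif_rand() * R_S);
      wbuf[0] = 0.0;
      for (int p = 1; p < M; ++p) wbuf[p] = eta_ip(i, p) * H[i * M + p];
      double tot = 0.0; for (int p = 1; p < M; ++p) tot += wbuf[p];
      const int p = pick(wbuf.data(), M, unif_rand() * tot);
      cell_a = i * M + p;           // actor (unchanged)
      applyDelta(i * M, +1);        // H[i, 0] gains the daughter
    } else if (channel == 3) { // competition
      for (int i = 0; i < nb; ++i) wbuf[i] = sumEta[i] * press[i];
      const int i = pick(wbuf.data(), nb, unif_rand() * R_C);
      for (int p = 0; p < M; ++p) wbuf[p] = eta_ip(i, p) * H[i * M + p];
      const int p = pick(wbuf.data(), M, unif_rand() * sumEta[i]);
      cell_a = i * M + p;
      applyDelta(cell_a, -1);
    } else { // infection
      for (int i = 0; i < nb; ++i) wbuf[i] = gam[i] * W[i];
      const int i = pick(wbuf.data(), nb, unif_rand() * R_I);
      wbuf[0] = 0.0;
      for (int p = 1; p < M; ++p) wbuf[p] = H[i * M + p] * Lsum[p];
      const int p = pick(wbuf.data(), M, unif_rand() * (W[i] > 0 ? W[i] : 0));
      cell_a = i * M + p; // donor (unchanged)
      // recipient ~ abundance within the donor-profile list
      const int lo = rec_ptr[p], hi = rec_ptr[p + 1];
      double u2 = unif_rand() * Lsum[p];
      int jsel = -1;
      for (int j = lo; j < hi; ++j) {
        const double w = H[rec_cells[j]];
        if (w <= 0) continue;
        jsel = j;
        if (u2 < w) break;
        u2 -= w;
      }
      if (jsel < 0) { n_events += 1.0; t = tnew; continue; } // numeric corner: no recipient mass
      cell_b = rec_cells[jsel];
      const int k = cell_b / M;
      // transconjugant ~ normalized tensor column
      double u3 = unif_rand();
      int r = -1;
      for (int j = tc_ptr[jsel]; j < tc_ptr[jsel + 1]; ++j) {
        r = tc_r[j];
        if (u3 < tc_w[j]) break;
        u3 -= tc_w[j];
      }
      cell_c = k * M + r;
      applyDelta(cell_b, -1);
      applyDelta(cell_c, +1);
    }

    n_events += 1.0;
    t = tnew;
    if (record_events) {
      ev_ch.push_back(channel); ev_a.push_back(cell_a);
      ev_b.push_back(cell_b); ev_c.push_back(cell_c);
      ev_dt.push_back(dt); ev_R.push_back(R);
      if (ev_ch.size() > 5000000) { termination = "event_limit"; record_state(t); break; }
    }

    while (next_rec <= t + 1e-9 && next_rec <= t_max + 1e-9) {
      record_state(next_rec);
      next_rec += record_interval;
    }

    double ntot = 0.0;
    int alive = 0;
    for (int i = 0; i < nb; ++i) { ntot += Htot[i]; if (Htot[i] > 0) ++alive; }
    if (ntot <= 0) { termination = "collapse"; record_state(t); break; }
    if (stop_single_host && alive <= 1) { termination = "single_host"; record_state(t); break; }
    if (n_events >= max_events) { termination = "event_limit"; record_state(t); break; }
  }

  IntegerMatrix Hfin(nb, M);
  for (int i = 0; i < nb; ++i)
    for (int p = 0; p < M; ++p) Hfin(i, p) = (int)H[i * M + p];

  List out = List::create(
    _["snap_t"] = snap_t, _["snap_cell"] = snap_cell,
    _["snap_ab"] = snap_ab, _["snap_len"] = snap_len,
    _["final_state"] = Hfin, _["t_end"] = t,
    _["termination"] = termination, _["n_events"] = n_events);
  if (record_events) {
    out["events"] = List::create(
      _["channel"] = ev_ch, _["cell_actor"] = ev_a,
      _["cell_recipient"] = ev_b, _["cell_transconjugant"] = ev_c,
      _["dt"] = ev_dt, _["total_rate"] = ev_R);
  }
  return out;
}
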