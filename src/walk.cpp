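#include <Rcpp.h>
using namespace Rcpp;

// Continuous-time 1D sliding walk for one DNA-binding event.
//
// The walker occupies integer bp positions.  Off a motif it hops to an
// enterable neighbour at rate k_hop per direction (k_hop = D1 in bp^2/s,
// giving MSD = 2*D1*t) and dissociates at rate k_off_ns.  On a motif
// footprint it is trapped: the only event is escape at the site's escape
// rate, after which it steps to a bp just outside the footprint (or is
// released into solution if both flanks are blocked).  Events are recorded
// only when the render label changes; occupancy time per bp is accumulated
// exactly.
//
// All positions are 0-based.  trap_id/label use 0 = none, k = site k.
// [[Rcpp::export]]
List walk_cpp(int start, double t0, double t_end,
              double k_hop, double k_off_ns,
              LogicalVector enterable,
              IntegerVector trap_id,
              IntegerVector trap_start,
              IntegerVector trap_end,
              NumericVector k_escape,
              IntegerVector label_map) {
  const int L = enterable.size();
  double t = t0;
  int p = start;
  std::vector<double> ev_t;
  std::vector<int> ev_p, ev_lab;
  NumericVector occ(L);
  int pmin = p, pmax = p;
  int cur = -999;
  bool dissoc = false;

  if (p < 0 || p >= L) stop("start position outside template");

  // record label change
  ev_t.push_back(t); ev_p.push_back(p); ev_lab.push_back(label_map[p]);
  cur = label_map[p];

  while (t < t_end) {
    int sid = trap_id[p];
    if (sid > 0) {
      double ke = k_escape[sid - 1];
      if (ke <= 0.0) { occ[p] += t_end - t; t = t_end; break; }
      double dt = R::exp_rand() / ke;
      if (t + dt >= t_end) { occ[p] += t_end - t; t = t_end; break; }
      occ[p] += dt; t += dt;
      int lo = trap_start[sid - 1] - 1;
      int hi = trap_end[sid - 1];
      bool okl = lo >= 0 && enterable[lo];
      bool okr = hi < L && enterable[hi];
      if (okl && okr) p = (unif_rand() < 0.5) ? lo : hi;
      else if (okl) p = lo;
      else if (okr) p = hi;
      else { dissoc = true; break; }  // landlocked site: release to solution
    } else {
      bool okl = p - 1 >= 0 && enterable[p - 1];
      bool okr = p + 1 < L && enterable[p + 1];
      double rl = okl ? k_hop : 0.0;
      double rr = okr ? k_hop : 0.0;
      double tot = rl + rr + k_off_ns;
      if (tot <= 0.0) { occ[p] += t_end - t; t = t_end; break; }
      double dt = R::exp_rand() / tot;
      if (t + dt >= t_end) { occ[p] += t_end - t; t = t_end; break; }
      occ[p] += dt; t += dt;
      double u = unif_rand() * tot;
      if (u < rl) p -= 1;
      else if (u < rl + rr) p += 1;
      else { dissoc = true; break; }
    }
    if (p < pmin) pmin = p;
    if (p > pmax) pmax = p;
    if (label_map[p] != cur) {
      ev_t.push_back(t); ev_p.push_back(p); ev_lab.push_back(label_map[p]);
      cur = label_map[p];
    }
  }

  return List::create(_["t"] = ev_t, _["pos"] = ev_p, _["label"] = ev_lab,
                      _["occupancy"] = occ, _["pmin"] = pmin, _["pmax"] = pmax,
                      _["t_end"] = t, _["dissociated"] = dissoc);
}
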