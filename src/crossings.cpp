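#include <Rcpp.h>
using namespace Rcpp;

// Per-particle 3-state (below | inside | above) crossing counter with
// hysteresis.  A particle last seen definitively below z_low - delta
// that is later seen above z_high + delta completes an outward event
// (and symmetrically inward).  A consecutive-frame |dz| > lz/2 is a
// periodic wrap: the tracking state is reset without an event.  With
// the radial check enabled, a crossing that showed any frames strictly
// between the bounds must have passed within r_cut of the pore axis in
// at least one of them; a direct below->above jump with no observed
// inside frame still counts (sparse output sampling).
//
// z:      frames x particles z coordinates (nm)
// r:      frames x particles radial distance from the pore axis, or a
//         0x0 matrix when radial_check is off
// z_low, z_high, lz: per-frame boundaries and box length (nm)
// Returns a list: events (particle, direction, entry_frame,
// completion_frame; 1-based frames) and per-particle first/last
// definitive side (-1 below, +1 above, 0 never definitive).
// [[Rcpp::export(name = ".count_crossings_core")]]
List count_crossings_core(NumericMatrix z, NumericMatrix r,
                          NumericVector z_low, NumericVector z_high,
                          NumericVector lz, double delta, double r_cut,
                          bool radial_check) {
  const int nf = z.nrow(), np = z.ncol();
  std::vector<int> ev_particle, ev_dir, ev_entry, ev_done;
  IntegerVector first_side(np, 0), last_side(np, 0);

  for (int p = 0; p < np; ++p) {
    int side = 0, last_def_frame = -1;
    bool seen_inside = false;
    double min_r = R_PosInf;
    double zprev = 0.0;
    for (int t = 0; t < nf; ++t) {
      const double zt = z(t, p);
      if (t > 0 && lz[t] > 0 && std::abs(zt - zprev) > lz[t] / 2.0) {
        // periodic wrap: reset, never a crossing
        int def = (zt > z_high[t] + delta) ? 1 :
                  (zt < z_low[t] - delta) ? -1 : 0;
        side = def;
        last_def_frame = (def != 0) ? t : -1;
        seen_inside = false;
        min_r = R_PosInf;
        if (def != 0 && first_side[p] == 0) first_side[p] = def;
        if (def != 0) last_side[p] = def;
        zprev = zt;
        continue;
      }
      const int def = (zt > z_high[t] + delta) ? 1 :
                      (zt < z_low[t] - delta) ? -1 : 0;
      if (def != 0 && first_side[p] == 0) first_side[p] = def;
      if (def != 0) last_side[p] = def;
      if (def != 0 && def == side) {
        last_def_frame = t;      // still parked on the same side
        seen_inside = false;
        min_r = R_PosInf;
      } else if (def != 0 && def != side) {
        if (side != 0) {
          bool ok = true;
          if (radial_check && seen_inside && !(min_r < r_cut)) ok = false;
          if (ok) {
            ev_particle.push_back(p + 1);
            ev_dir.push_back(def);  // +1 outward, -1 inward
            ev_entry.push_back(last_def_frame + 1);
            ev_done.push_back(t + 1);
          }
        }
        side = def;
        last_def_frame = t;
        seen_inside = false;
        min_r = R_PosInf;
      } else {  // def == 0: in or near the filter region
        if (zt > z_low[t] && zt < z_high[t]) {
          seen_inside = true;
          if (radial_check && r.nrow() == nf) {
            const double rt = r(t, p);
            if (rt < min_r) min_r = rt;
          }
        }
      }
      zprev = zt;
    }
  }
  return List::create(
      _["particle"] = wrap(ev_particle), _["direction"] = wrap(ev_dir),
      _["entry_frame"] = wrap(ev_entry), _["completion_frame"] = wrap(ev_done),
      _["first_side"] = first_side, _["last_side"] = last_side);
}
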