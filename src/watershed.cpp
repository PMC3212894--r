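#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
using namespace Rcpp;

// Seeded watershed flood of a (smoothed) canopy height model.
// Seeds are the 8-neighbour local maxima at or above min_height; ties between
// equal-height neighbours are broken toward the lower linear pixel id so the
// labelling is deterministic. Pixels below min_height (or NA) stay 0.
// [[Rcpp::export]]
IntegerMatrix watershed_labels_cpp(NumericMatrix z, double min_height) {
  const int nr = z.nrow(), nc = z.ncol(), n = nr * nc;
  IntegerMatrix lab(nr, nc);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  auto lin = [&](int r, int c) { return r + c * nr; };

  std::vector<int> seeds;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double z0 = z(r, c);
      if (NumericMatrix::is_na(z0) || z0 < min_height) continue;
      bool ismax = true;
      int id0 = lin(r, c);
      for (int k = 0; k < 8 && ismax; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double zn = z(rr, cc);
        if (NumericMatrix::is_na(zn)) continue;
        if (zn > z0 || (zn == z0 && lin(rr, cc) < id0)) ismax = false;
      }
      if (ismax) seeds.push_back(id0);
    }
  }
  int nlab = 0;
  for (int s : seeds) lab[s] = ++nlab;

  // Priority flood: always extend the current labelling at the highest
  // unprocessed pixel, so each pixel joins the crown it drains toward.
  typedef std::pair<double, int> E;  // (height, -id): max height, then min id
  std::priority_queue<E> pq;
  std::vector<char> inq(n, 0);
  for (int s : seeds) {
    pq.push(E(z[s], -s));
    inq[s] = 1;
  }
  while (!pq.empty()) {
    int id = -pq.top().second;
    pq.pop();
    int r = id % nr, c = id / nr;
    if (lab[id] == 0) {
      double best = -1.0;
      int bl = 0, bid = n + 1;
      for (int k = 0; k < 8; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int nid = lin(rr, cc);
        if (lab[nid] == 0) continue;
        double zn = z(rr, cc);
        if (zn > best || (zn == best && nid < bid)) {
          best = zn;
          bl = lab[nid];
          bid = nid;
        }
      }
      lab[id] = bl;  // bl > 0: popped pixels were queued by a labelled pixel
    }
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int nid = lin(rr, cc);
      double zn = z(rr, cc);
      if (inq[nid] || lab[nid] != 0) continue;
      if (NumericMatrix::is_na(zn) || zn < min_height) continue;
      pq.push(E(zn, -nid));
      inq[nid] = 1;
    }
  }
  return lab;
}
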