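#include <Rcpp.h>
using namespace Rcpp;

static inline int iunif2(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// One walk campaign over a graph in CSR form (0-based indptr/indices).
// From every node, `walks_per_start` blind random walks are launched; at each
// arrival the node's class is sampled (red with probability p_red, drawn only
// when 0 < p_red < 1 so that pure patterns consume no class randomness) and
// the first passage step count to each requested class is recorded.  The
// start node itself is excluded, so all first passage times are >= 1.  Walks
// that exceed `max_steps` before reaching a requested class are discarded
// and counted as truncated for that class.
// [[Rcpp::export]]
List walk_campaign_cpp(IntegerVector indptr, IntegerVector indices,
                       NumericVector p_red, int walks_per_start,
                       double max_steps, bool need_red, bool need_yellow) {
  int n = p_red.size();
  NumericVector sum_r(n), ssq_r(n), sum_y(n), ssq_y(n);
  IntegerVector cnt_r(n), cnt_y(n), trunc_r(n), trunc_y(n);

  for (int i = 0; i < n; ++i) {
    if (indptr[i + 1] - indptr[i] == 0) continue;  // isolated node: no walks
    for (int w = 0; w < walks_per_start; ++w) {
      int pos = i;
      double steps = 0, fr = -1, fy = -1;
      bool got_r = !need_red, got_y = !need_yellow;
      while (!(got_r && got_y) && steps < max_steps) {
        int off = indptr[pos];
        int deg = indptr[pos + 1] - off;
        pos = indices[off + iunif2(deg)];
        steps += 1;
        double p = p_red[pos];
        bool is_red;
        if (p <= 0) is_red = false;
        else if (p >= 1) is_red = true;
        else is_red = unif_rand() < p;
        if (is_red) { if (!got_r) { got_r = true; fr = steps; } }
        else        { if (!got_y) { got_y = true; fy = steps; } }
      }
      if (need_red) {
        if (fr > 0) { sum_r[i] += fr; ssq_r[i] += fr * fr; cnt_r[i]++; }
        else trunc_r[i]++;
      }
      if (need_yellow) {
        if (fy > 0) { sum_y[i] += fy; ssq_y[i] += fy * fy; cnt_y[i]++; }
        else trunc_y[i]++;
      }
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["sum_r"] = sum_r, _["ssq_r"] = ssq_r, _["cnt_r"] = cnt_r,
      _["trunc_r"] = trunc_r,
      _["sum_y"] = sum_y, _["ssq_y"] = ssq_y, _["cnt_y"] = cnt_y,
      _["trunc_y"] = trunc_y);
}
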