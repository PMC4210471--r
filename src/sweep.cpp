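#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Sweep-line (sort-merge) joins over one chromosome. Coordinates are 0-based
// half-open. Event types share one priority scale so that coordinate ties
// resolve the half-open convention:
//   0 region_end < 1 window_end < 2 region_start < 3 variant point / window start
// A region ending at c therefore never annotates a point/window starting at c,
// and a region starting at c always annotates a variant point at c.

namespace {

struct Event {
  long long coord;
  int type;
  int idx;
};

inline bool event_lt(const Event &a, const Event &b) {
  if (a.coord != b.coord) return a.coord < b.coord;
  return a.type < b.type;
}

// identity-keyed active set with O(1) insert/remove-by-identity
struct ActiveSet {
  std::vector<int> members;
  std::vector<int> slot; // idx -> position in members, -1 if absent
  long long insertions = 0, removals = 0;
  explicit ActiveSet(int n) : slot(n, -1) {}
  void insert(int i) {
    slot[i] = (int)members.size();
    members.push_back(i);
    ++insertions;
  }
  void remove(int i) {
    int s = slot[i];
    int last = members.back();
    members[s] = last;
    slot[last] = s;
    members.pop_back();
    slot[i] = -1;
    ++removals;
  }
};

void check_sorted(const IntegerVector &x, const char *what) {
  for (R_xlen_t i = 1; i < x.size(); ++i)
    if (x[i] < x[i - 1])
      stop("unsorted input detected during scan: %s", what);
}

} // namespace

// [[Rcpp::export(name = ".point_join_cpp")]]
List point_join_cpp(IntegerVector vpoint, IntegerVector rstart,
                    IntegerVector rend) {
  const int nv = (int)vpoint.size(), nr = (int)rstart.size();
  check_sorted(vpoint, "variant points");
  check_sorted(rstart, "region starts");

  std::vector<Event> ev;
  ev.reserve((size_t)nv + 2 * (size_t)nr);
  for (int j = 0; j < nr; ++j) {
    ev.push_back({(long long)rstart[j], 2, j});
    ev.push_back({(long long)rend[j], 0, j});
  }
  for (int i = 0; i < nv; ++i) ev.push_back({(long long)vpoint[i], 3, i});
  std::stable_sort(ev.begin(), ev.end(), event_lt);

  ActiveSet regions(nr);
  std::vector<int> out_v, out_r;
  for (const Event &e : ev) {
    switch (e.type) {
    case 2: regions.insert(e.idx); break;
    case 0: regions.remove(e.idx); break;
    case 3:
      for (int j : regions.members) {
        out_v.push_back(e.idx + 1);
        out_r.push_back(j + 1);
      }
      break;
    }
  }
  return List::create(
      _["variant"] = IntegerVector(out_v.begin(), out_v.end()),
      _["region"] = IntegerVector(out_r.begin(), out_r.end()),
      _["insertions"] = (double)regions.insertions,
      _["removals"] = (double)regions.removals);
}

// [[Rcpp::export(name = ".window_join_cpp")]]
List window_join_cpp(IntegerVector vpoint, IntegerVector rstart,
                     IntegerVector rend, int w) {
  const int nv = (int)vpoint.size(), nr = (int)rstart.size();
  if (w < 0) stop("flank size must be non-negative");
  check_sorted(vpoint, "variant points");
  check_sorted(rstart, "region starts");

  std::vector<Event> ev;
  ev.reserve(2 * ((size_t)nv + (size_t)nr));
  for (int j = 0; j < nr; ++j) {
    ev.push_back({(long long)rstart[j], 2, j});
    ev.push_back({(long long)rend[j], 0, j});
  }
  for (int i = 0; i < nv; ++i) {
    long long ws = (long long)vpoint[i] - w;
    if (ws < 0) ws = 0;
    ev.push_back({ws, 3, i});
    ev.push_back({(long long)vpoint[i] + w + 1, 1, i});
  }
  std::stable_sort(ev.begin(), ev.end(), event_lt);

  ActiveSet regions(nr), variants(nv);
  std::vector<int> out_v, out_r;
  for (const Event &e : ev) {
    switch (e.type) {
    case 2: // region opens: annotate every open window
      regions.insert(e.idx);
      for (int i : variants.members) {
        out_v.push_back(i + 1);
        out_r.push_back(e.idx + 1);
      }
      break;
    case 0: regions.remove(e.idx); break;
    case 3: // window opens: annotate with every open region
      variants.insert(e.idx);
      for (int j : regions.members) {
        out_v.push_back(e.idx + 1);
        out_r.push_back(j + 1);
      }
      break;
    case 1: variants.remove(e.idx); break;
    }
  }
  return List::create(
      _["variant"] = IntegerVector(out_v.begin(), out_v.end()),
      _["region"] = IntegerVector(out_r.begin(), out_r.end()),
      _["insertions"] = (double)(regions.insertions + variants.insertions),
      _["removals"] = (double)(regions.removals + variants.removals));
}
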