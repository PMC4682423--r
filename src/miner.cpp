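// Depth-first closed subsequential pattern miner.
//
// Items are integers in -3..3; a pattern is a sequence of pair-items
// represented by lower items (lo in -3..2). A (gene, offset) window
// matches positively when every item is in {lo, lo+1}, and negatively
// (weak) when every item is negatively similar to at least one end of
// the pair (strict: both ends). Match sets only shrink under
// extension, so infrequent prefixes prune whole subtrees.
//
// Match sets are bitsets over (gene, offset): each gene owns a 32-bit
// block (offsets 0..30), four per 128 bits, packed into 64-bit words.
// A one-pair extension is then a blockwise shift plus AND against a
// precomputed per-pair mask, and because extension match sets are
// always subsets of the parent's (offset-shifted for left extensions),
// the closedness test "some extension preserves both reported sets"
// reduces to popcount comparisons.

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;

namespace {

constexpr int kBlock = 32;          // bits per gene block
constexpr int kPerWord = 2;         // gene blocks per 64-bit word

inline bool pos_match(int e, int lo) { return e == lo || e == lo + 1; }

inline bool neg_match(int e, int lo, bool weak) {
  const bool a = std::abs(e + lo) <= 1;
  const bool b = std::abs(e + lo + 1) <= 1;
  return weak ? (a || b) : (a && b);
}

typedef std::vector<uint64_t> Bits;

inline int popcount_all(const Bits& v) {
  int k = 0;
  for (uint64_t w : v) k += __builtin_popcountll(w);
  return k;
}

class Miner {
 public:
  Miner(const IntegerMatrix& S, int sup, int min_len, double max0, bool weak)
      : nv_(S.nrow()), nt_(S.ncol()), sup_(sup), min_len_(min_len),
        max0_(max0), nw_((S.nrow() + kPerWord - 1) / kPerWord) {
    // per-pair-item masks: bit (g, t) set when item S(g, t) matches
    for (int pi = 0; pi < 6; ++pi) {
      const int lo = pi - 3;
      pos_mask_[pi].assign(nw_, 0);
      neg_mask_[pi].assign(nw_, 0);
      for (int g = 0; g < nv_; ++g) {
        for (int t = 0; t < nt_; ++t) {
          const int e = S(g, t);
          const size_t w = g / kPerWord;
          const int bit = (g % kPerWord) * kBlock + t;
          if (pos_match(e, lo)) pos_mask_[pi][w] |= 1ULL << bit;
          if (neg_match(e, lo, weak)) neg_mask_[pi][w] |= 1ULL << bit;
        }
      }
    }
  }

  void run() {
    std::vector<int> lov(1);
    for (int pi = 0; pi < 6; ++pi) {
      lov[0] = pi - 3;
      dfs(lov, pos_mask_[pi], neg_mask_[pi]);
    }
  }

  List results(const IntegerMatrix& /*S*/) {
    List out(emitted_.size());
    for (size_t i = 0; i < emitted_.size(); ++i) {
      const Emitted& e = emitted_[i];
      out[i] = List::create(Named("pairs") = IntegerVector(e.lov.begin(), e.lov.end()),
                            Named("p") = decode(e.P),
                            Named("n") = decode(e.nbits));
    }
    return out;
  }

 private:
  struct Emitted {
    std::vector<int> lov;
    Bits P;       // reported p bits
    Bits nbits;   // reported n bits (genes without positive matches)
  };

  const int nv_, nt_, sup_, min_len_;
  const double max0_;
  const size_t nw_;
  Bits pos_mask_[6], neg_mask_[6];
  std::vector<Emitted> emitted_;
  std::map<std::string, size_t> seen_;

  // blockwise right shift by s: offset o+s -> o within each gene block
  inline void block_shift(const Bits& v, int s, Bits* out) const {
    const uint64_t mask_one = (s >= kBlock) ? 0 : (0xFFFFFFFFULL >> s);
    const uint64_t m = mask_one | (mask_one << kBlock);
    for (size_t w = 0; w < nw_; ++w) (*out)[w] = (v[w] >> s) & m;
  }

  inline void and_into(const Bits& a, const Bits& b, Bits* out) const {
    for (size_t w = 0; w < nw_; ++w) (*out)[w] = a[w] & b[w];
  }

  // genes with at least one bit in P or N
  int distinct_genes(const Bits& P, const Bits& N) const {
    int k = 0;
    for (size_t w = 0; w < nw_; ++w) {
      const uint64_t u = P[w] | N[w];
      if (static_cast<uint32_t>(u)) ++k;
      if (static_cast<uint32_t>(u >> kBlock)) ++k;
    }
    return k;
  }

  // reported-n bits: N bits of genes with empty P block
  void n_report(const Bits& P, const Bits& N, Bits* out) const {
    for (size_t w = 0; w < nw_; ++w) {
      const uint32_t plo = static_cast<uint32_t>(P[w]);
      const uint32_t phi = static_cast<uint32_t>(P[w] >> kBlock);
      uint64_t keep = 0;
      if (!plo) keep |= 0xFFFFFFFFULL;
      if (!phi) keep |= 0xFFFFFFFFULL << kBlock;
      (*out)[w] = N[w] & keep;
    }
  }

  int n_report_count(const Bits& P, const Bits& N) const {
    int k = 0;
    for (size_t w = 0; w < nw_; ++w) {
      const uint64_t pw = P[w], nwrd = N[w];
      if (!static_cast<uint32_t>(pw))
        k += __builtin_popcountll(nwrd & 0xFFFFFFFFULL);
      if (!static_cast<uint32_t>(pw >> kBlock))
        k += __builtin_popcountll(nwrd >> kBlock);
    }
    return k;
  }

  // extension match sets; right: parent bit (g,o) survives when the
  // mask has (g, o+l); left: parent (g,o) moves to (g, o-1) when the
  // mask has (g, o-1)
  void extend(const Bits& P, const Bits& N, int l, int pi, bool left,
              Bits* P2, Bits* N2, Bits* scratch) const {
    if (left) {
      block_shift(P, 1, scratch);
      and_into(*scratch, pos_mask_[pi], P2);
      block_shift(N, 1, scratch);
      and_into(*scratch, neg_mask_[pi], N2);
    } else {
      block_shift(pos_mask_[pi], l, scratch);
      and_into(P, *scratch, P2);
      block_shift(neg_mask_[pi], l, scratch);
      and_into(N, *scratch, N2);
    }
  }

  bool is_closed(const Bits& P, const Bits& N, int l) const {
    if (l >= nt_) return true;
    const int pP = popcount_all(P);
    const int pn = n_report_count(P, N);
    Bits P2(nw_), N2(nw_), scratch(nw_);
    for (int side = 0; side < 2; ++side) {
      for (int pi = 0; pi < 6; ++pi) {
        extend(P, N, l, pi, side == 1, &P2, &N2, &scratch);
        if (popcount_all(P2) == pP && n_report_count(P2, N2) == pn)
          return false;
      }
    }
    return true;
  }

  IntegerMatrix decode(const Bits& v) const {
    std::vector<int> gs, os;
    for (size_t w = 0; w < nw_; ++w) {
      uint64_t u = v[w];
      while (u) {
        const int bit = __builtin_ctzll(u);
        u &= u - 1;
        gs.push_back(static_cast<int>(w) * kPerWord + bit / kBlock + 1);
        os.push_back(bit % kBlock);
      }
    }
    IntegerMatrix m(gs.size(), 2);
    for (size_t i = 0; i < gs.size(); ++i) {
      m(i, 0) = gs[i];
      m(i, 1) = os[i];
    }
    return m;
  }

  void emit(const std::vector<int>& lov, const Bits& P, const Bits& N) {
    Bits nb(nw_);
    n_report(P, N, &nb);
    std::string key;
    key.reserve(nw_ * 32 + 1);
    char buf[17];
    for (size_t w = 0; w < nw_; ++w) {
      snprintf(buf, sizeof buf, "%016llx",
               static_cast<unsigned long long>(P[w]));
      key += buf;
    }
    key += '|';
    for (size_t w = 0; w < nw_; ++w) {
      snprintf(buf, sizeof buf, "%016llx",
               static_cast<unsigned long long>(nb[w]));
      key += buf;
    }
    auto it = seen_.find(key);
    if (it == seen_.end()) {
      seen_[key] = emitted_.size();
      emitted_.push_back({lov, P, nb});
      return;
    }
    std::vector<int>& cur = emitted_[it->second].lov;
    if (lov.size() < cur.size() ||
        (lov.size() == cur.size() &&
         std::lexicographical_compare(lov.begin(), lov.end(),
                                      cur.begin(), cur.end())))
      cur = lov;
  }

  void dfs(std::vector<int>& lov, const Bits& P, const Bits& N) {
    const int l = static_cast<int>(lov.size());
    if (distinct_genes(P, N) < sup_) return;
    int cnt0 = 0;
    for (int lo : lov)
      if (lo == -1 || lo == 0) ++cnt0;
    // even diluted to the maximum possible length the insignificant
    // fraction cannot drop below cnt0 / nt_
    if (cnt0 > max0_ * nt_ + 1e-9) return;
    if (l >= min_len_ && cnt0 <= max0_ * l + 1e-9 && is_closed(P, N, l))
      emit(lov, P, N);
    if (l >= nt_) return;
    Bits P2(nw_), N2(nw_), scratch(nw_);
    for (int pi = 0; pi < 6; ++pi) {
      extend(P, N, l, pi, false, &P2, &N2, &scratch);
      bool any = false;
      for (size_t w = 0; w < nw_; ++w)
        if (P2[w] | N2[w]) { any = true; break; }
      if (!any) continue;
      lov.push_back(pi - 3);
      dfs(lov, P2, N2);
      lov.pop_back();
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_mine(IntegerMatrix S, int sup, int min_len, double max0, bool weak) {
  if (S.ncol() > 31)
    stop("the miner supports at most 31 time points; split longer series into cycles first");
  Miner m(S, sup, min_len, max0, weak);
  m.run();
  return m.results(S);
}
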