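#include <Rcpp.h>
using namespace Rcpp;

// Unsigned LEB128 varint block codec for one chromosome's sorted positions:
// first value absolute, the rest non-negative deltas.

// [[Rcpp::export(name = ".encode_positions_cpp")]]
RawVector encode_positions_cpp(IntegerVector pos) {
  const R_xlen_t n = pos.size();
  // worst case 5 bytes per value (positions < 2^31)
  std::vector<unsigned char> out;
  out.reserve(static_cast<size_t>(n) * 2 + 8);
  long long prev = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (pos[i] == NA_INTEGER || pos[i] < 0)
      stop("positions must be non-negative and non-missing");
    long long v = (i == 0) ? (long long)pos[i] : (long long)pos[i] - prev;
    if (v < 0) stop("positions must be sorted in non-decreasing order");
    prev = pos[i];
    unsigned long long u = (unsigned long long)v;
    do {
      unsigned char byte = u & 0x7f;
      u >>= 7;
      if (u) byte |= 0x80;
      out.push_back(byte);
    } while (u);
  }
  RawVector res(out.size());
  if (!out.empty()) std::copy(out.begin(), out.end(), res.begin());
  return res;
}

// Decode `count` varints from `payload` starting at 0-based byte `start`.
// Returns list(positions, bytes_consumed). Errors name the absolute byte
// offset at which the payload ran out or overflowed.

// [[Rcpp::export(name = ".decode_positions_cpp")]]
List decode_positions_cpp(RawVector payload, double start, double count) {
  const R_xlen_t len = payload.size();
  R_xlen_t at = (R_xlen_t)start;
  const R_xlen_t n = (R_xlen_t)count;
  IntegerVector pos(n);
  long long acc = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    unsigned long long u = 0;
    int shift = 0;
    for (;;) {
      if (at >= len)
        stop("corrupt payload: truncated varint at byte offset %d", (int)at);
      unsigned char byte = payload[at++];
      u |= (unsigned long long)(byte & 0x7f) << shift;
      if (!(byte & 0x80)) break;
      shift += 7;
      if (shift > 63)
        stop("corrupt payload: varint overflow at byte offset %d", (int)at);
    }
    acc = (i == 0) ? (long long)u : acc + (long long)u;
    if (acc > INT_MAX)
      stop("corrupt payload: position exceeds integer range at byte offset %d",
           (int)at);
    pos[i] = (int)acc;
  }
  return List::create(_["positions"] = pos,
                      _["bytes_consumed"] = (double)(at - (R_xlen_t)start));
}
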