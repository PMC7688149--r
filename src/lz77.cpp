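// Sliding-window LZ77 coder used as the second compression phase.
//
// Greedy longest-match parsing with a hash-chain search over 3-byte
// prefixes (plain windowed scan when min_match < 3). Serialized stream:
//
//   bytes 0-2   magic "DLZ"
//   byte  3     version (1)
//   bytes 4-19  four little-endian uint32: window, min_match, max_match,
//               uncompressed length
//   then a bitstream, most-significant-bit first:
//     literal: flag 0, 8 bits of the byte
//     match:   flag 1, ceil(log2(window)) bits of (offset - 1),
//              ceil(log2(max_match - min_match + 1)) bits of
//              (length - min_match)
//   padded to a byte boundary with zero bits.
//
// Overlapping matches (offset < length) are allowed, so a run of one byte
// codes as a literal plus a single long match.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

const int HASH_BITS = 15;
const int HASH_SIZE = 1 << HASH_BITS;
const int MAX_CHAIN = 1024;

inline int bits_for(uint32_t n_values) {
  // width needed to store values 0 .. n_values-1
  int b = 0;
  while ((uint32_t(1) << b) < n_values) ++b;
  return b;
}

inline int hash3(const uint8_t* p) {
  uint32_t h = (uint32_t(p[0]) << 16) | (uint32_t(p[1]) << 8) | p[2];
  return int((h * 2654435761u) >> (32 - HASH_BITS));
}

struct BitWriter {
  std::vector<uint8_t> out;
  uint32_t acc = 0;
  int nbits = 0;
  void put(uint32_t value, int width) {
    for (int i = width - 1; i >= 0; --i) {
      acc = (acc << 1) | ((value >> i) & 1u);
      if (++nbits == 8) {
        out.push_back(uint8_t(acc & 0xffu));
        acc = 0;
        nbits = 0;
      }
    }
  }
  void flush() {
    if (nbits > 0) {
      out.push_back(uint8_t((acc << (8 - nbits)) & 0xffu));
      acc = 0;
      nbits = 0;
    }
  }
};

struct BitReader {
  const uint8_t* p;
  size_t n;
  size_t pos = 0;
  int bit = 0;
  BitReader(const uint8_t* p_, size_t n_) : p(p_), n(n_) {}
  uint32_t get(int width) {
    uint32_t v = 0;
    for (int i = 0; i < width; ++i) {
      if (pos >= n) stop("truncated LZ77 stream");
      v = (v << 1) | ((p[pos] >> (7 - bit)) & 1u);
      if (++bit == 8) { bit = 0; ++pos; }
    }
    return v;
  }
};

struct Token {
  bool is_match;
  uint8_t lit;
  uint32_t offset;
  uint32_t length;
};

// Greedy tokenizer shared by the compressor and the token-inspection API.
std::vector<Token> tokenize(const uint8_t* data, size_t n,
                            uint32_t window, uint32_t min_match,
                            uint32_t max_match) {
  std::vector<Token> tokens;
  if (n == 0) return tokens;

  bool use_hash = min_match >= 3 && n >= 3;
  std::vector<int64_t> head, prev;
  if (use_hash) {
    head.assign(HASH_SIZE, -1);
    prev.assign(n, -1);
  }

  size_t i = 0;
  while (i < n) {
    uint32_t best_len = 0, best_off = 0;
    size_t limit = std::min<size_t>(max_match, n - i);

    if (limit >= min_match) {
      if (use_hash) {
        if (i + 2 < n) {
          int64_t cand = head[hash3(data + i)];
          int chain = 0;
          while (cand >= 0 && i - size_t(cand) <= window &&
                 chain < MAX_CHAIN) {
            const uint8_t* a = data + cand;
            const uint8_t* b = data + i;
            uint32_t len = 0;
            while (len < limit && a[len] == b[len]) ++len;
            if (len > best_len) {
              best_len = len;
              best_off = uint32_t(i - size_t(cand));
              if (best_len >= limit) break;
            }
            cand = prev[cand];
            ++chain;
          }
        }
      } else {
        size_t start = (i > window) ? i - window : 0;
        for (size_t cand = i; cand-- > start;) {
          const uint8_t* a = data + cand;
          const uint8_t* b = data + i;
          uint32_t len = 0;
          while (len < limit && a[len] == b[len]) ++len;
          if (len > best_len) {
            best_len = len;
            best_off = uint32_t(i - cand);
            if (best_len >= limit) break;
          }
        }
      }
    }

    size_t step;
    if (best_len >= min_match) {
      Token t; t.is_match = true; t.lit = 0;
      t.offset = best_off; t.length = best_len;
      tokens.push_back(t);
      step = best_len;
    } else {
      Token t; t.is_match = false; t.lit = data[i];
      t.offset = 0; t.length = 0;
      tokens.push_back(t);
      step = 1;
    }
    if (use_hash) {
      size_t end = std::min(i + step, n >= 2 ? n - 2 : size_t(0));
      for (size_t j = i; j < end; ++j) {
        int h = hash3(data + j);
        prev[j] = head[h];
        head[h] = int64_t(j);
      }
    }
    i += step;
  }
  return tokens;
}

void put_u32(std::vector<uint8_t>& v, uint32_t x) {
  v.push_back(x & 0xffu);
  v.push_back((x >> 8) & 0xffu);
  v.push_back((x >> 16) & 0xffu);
  v.push_back((x >> 24) & 0xffu);
}

uint32_t get_u32(const uint8_t* p) {
  return uint32_t(p[0]) | (uint32_t(p[1]) << 8) |
         (uint32_t(p[2]) << 16) | (uint32_t(p[3]) << 24);
}

}  // namespace

// [[Rcpp::export(name = ".lz77_compress_raw")]]
RawVector lz77_compress_raw(RawVector data, int window, int min_match,
                            int max_match) {
  if (window < 1 || min_match < 1 || max_match < min_match)
    stop("invalid LZ77 parameters");
  size_t n = data.size();
  const uint8_t* p = n ? (const uint8_t*)RAW(data) : nullptr;

  std::vector<Token> tokens =
      tokenize(p, n, uint32_t(window), uint32_t(min_match),
               uint32_t(max_match));

  std::vector<uint8_t> out;
  out.push_back('D'); out.push_back('L'); out.push_back('Z');
  out.push_back(1);  // version
  put_u32(out, uint32_t(window));
  put_u32(out, uint32_t(min_match));
  put_u32(out, uint32_t(max_match));
  put_u32(out, uint32_t(n));

  int off_bits = bits_for(uint32_t(window));
  int len_bits = bits_for(uint32_t(max_match - min_match + 1));

  BitWriter bw;
  for (const Token& t : tokens) {
    if (t.is_match) {
      bw.put(1, 1);
      bw.put(t.offset - 1, off_bits);
      bw.put(t.length - uint32_t(min_match), len_bits);
    } else {
      bw.put(0, 1);
      bw.put(t.lit, 8);
    }
  }
  bw.flush();
  out.insert(out.end(), bw.out.begin(), bw.out.end());

  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".lz77_decompress_raw")]]
RawVector lz77_decompress_raw(RawVector serialized) {
  size_t n = serialized.size();
  const uint8_t* p = n ? (const uint8_t*)RAW(serialized) : nullptr;
  if (n < 20 || p[0] != 'D' || p[1] != 'L' || p[2] != 'Z')
    stop("not an LZ77 stream (bad magic)");
  if (p[3] != 1) stop("unsupported LZ77 stream version");
  uint32_t window = get_u32(p + 4);
  uint32_t min_match = get_u32(p + 8);
  uint32_t max_match = get_u32(p + 12);
  uint32_t out_len = get_u32(p + 16);
  if (window < 1 || min_match < 1 || max_match < min_match)
    stop("corrupt LZ77 header");

  int off_bits = bits_for(window);
  int len_bits = bits_for(max_match - min_match + 1);

  BitReader br(p + 20, n - 20);
  std::vector<uint8_t> out;
  out.reserve(out_len);
  while (out.size() < out_len) {
    uint32_t flag = br.get(1);
    if (flag == 0) {
      out.push_back(uint8_t(br.get(8)));
    } else {
      uint32_t offset = br.get(off_bits) + 1;
      uint32_t length = br.get(len_bits) + min_match;
      if (offset > out.size())
        stop("match offset references beyond decoded prefix");
      if (out.size() + length > out_len)
        stop("match overruns declared uncompressed length");
      size_t from = out.size() - offset;
      for (uint32_t k = 0; k < length; ++k)
        out.push_back(out[from + k]);  // overlapping matches supported
    }
  }
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".lz77_tokens_raw")]]
List lz77_tokens_raw(RawVector data, int window, int min_match,
                     int max_match) {
  if (window < 1 || min_match < 1 || max_match < min_match)
    stop("invalid LZ77 parameters");
  size_t n = data.size();
  const uint8_t* p = n ? (const uint8_t*)RAW(data) : nullptr;
  std::vector<Token> tokens =
      tokenize(p, n, uint32_t(window), uint32_t(min_match),
               uint32_t(max_match));
  size_t m = tokens.size();
  CharacterVector kind(m);
  IntegerVector lit(m), off(m), len(m);
  for (size_t i = 0; i < m; ++i) {
    if (tokens[i].is_match) {
      kind[i] = "match";
      lit[i] = NA_INTEGER;
      off[i] = int(tokens[i].offset);
      len[i] = int(tokens[i].length);
    } else {
      kind[i] = "literal";
      lit[i] = int(tokens[i].lit);
      off[i] = NA_INTEGER;
      len[i] = NA_INTEGER;
    }
  }
  return List::create(_["kind"] = kind, _["literal"] = lit,
                      _["offset"] = off, _["length"] = len);
}
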