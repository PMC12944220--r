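#include <Rcpp.h>
using namespace Rcpp;

// CRC-32 (IEEE 802.3) and Adler-32, needed by the PNG chunk / zlib stream
// writer. Table computed once at load.

static uint32_t crc_table[256];
static bool crc_ready = false;

static void make_crc_table() {
  for (uint32_t n = 0; n < 256; n++) {
    uint32_t c = n;
    for (int k = 0; k < 8; k++)
      c = (c & 1) ? 0xedb88320UL ^ (c >> 1) : c >> 1;
    crc_table[n] = c;
  }
  crc_ready = true;
}

// [[Rcpp::export]]
double crc32_raw(RawVector data) {
  if (!crc_ready) make_crc_table();
  uint32_t c = 0xffffffffUL;
  for (R_xlen_t i = 0; i < data.size(); i++)
    c = crc_table[(c ^ data[i]) & 0xff] ^ (c >> 8);
  return (double)(c ^ 0xffffffffUL);
}

// [[Rcpp::export]]
double adler32_raw(RawVector data) {
  const uint32_t MOD = 65521;
  uint32_t a = 1, b = 0;
  for (R_xlen_t i = 0; i < data.size(); i++) {
    a = (a + data[i]) % MOD;
    b = (b + a) % MOD;
  }
  return (double)((b << 16) | a);
}
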