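#include <Rcpp.h>
#include <cstdio>
#include <cstdint>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Minimal multi-page 32-bit float grayscale TIFF writer (little-endian,
// uncompressed, SampleFormat = IEEE float). The CRAN tiff package reads
// such files but cannot write float samples (it quantizes to [0,1] fixed
// point), so analysis maps in physical units (degrees, pixels) are written
// here and read back with tiff::readTIFF.

static void put16(std::vector<uint8_t>& b, uint16_t v) {
  b.push_back(v & 0xff); b.push_back(v >> 8);
}
static void put32(std::vector<uint8_t>& b, uint32_t v) {
  b.push_back(v & 0xff); b.push_back((v >> 8) & 0xff);
  b.push_back((v >> 16) & 0xff); b.push_back((v >> 24) & 0xff);
}
static void tag(std::vector<uint8_t>& b, uint16_t id, uint16_t type,
                uint32_t count, uint32_t value) {
  put16(b, id); put16(b, type); put32(b, count); put32(b, value);
}

// pages: list of numeric matrices (ny x nx), written in list order.
// [[Rcpp::export]]
void cpp_write_tiff_f32(List pages, std::string path) {
  const int npage = pages.size();
  std::vector<uint8_t> buf;
  buf.reserve(1024);
  // header
  buf.push_back('I'); buf.push_back('I'); put16(buf, 42);
  put32(buf, 0); // first IFD offset, patched later
  size_t ifd_ptr_pos = 4;

  for (int p = 0; p < npage; ++p) {
    NumericMatrix m = pages[p];
    const uint32_t ny = m.nrow(), nx = m.ncol();
    const uint32_t nbytes = ny * nx * 4;

    // pixel data (row-major strips)
    const uint32_t data_off = (uint32_t)buf.size();
    for (uint32_t y = 0; y < ny; ++y) {
      for (uint32_t x = 0; x < nx; ++x) {
        const float f = (float)m(y, x);
        uint32_t bits;
        std::memcpy(&bits, &f, 4);
        put32(buf, bits);
      }
    }
    if (buf.size() % 2) buf.push_back(0); // word-align IFD

    const uint32_t ifd_off = (uint32_t)buf.size();
    // patch previous pointer to this IFD
    buf[ifd_ptr_pos]     = ifd_off & 0xff;
    buf[ifd_ptr_pos + 1] = (ifd_off >> 8) & 0xff;
    buf[ifd_ptr_pos + 2] = (ifd_off >> 16) & 0xff;
    buf[ifd_ptr_pos + 3] = (ifd_off >> 24) & 0xff;

    const uint16_t ntags = 11;
    put16(buf, ntags);
    tag(buf, 256, 3, 1, nx);            // ImageWidth
    tag(buf, 257, 3, 1, ny);            // ImageLength
    tag(buf, 258, 3, 1, 32);            // BitsPerSample
    tag(buf, 259, 3, 1, 1);             // Compression: none
    tag(buf, 262, 3, 1, 1);             // Photometric: BlackIsZero
    tag(buf, 273, 4, 1, data_off);      // StripOffsets
    tag(buf, 277, 3, 1, 1);             // SamplesPerPixel
    tag(buf, 278, 3, 1, ny);            // RowsPerStrip
    tag(buf, 279, 4, 1, nbytes);        // StripByteCounts
    tag(buf, 284, 3, 1, 1);             // PlanarConfig
    tag(buf, 339, 3, 1, 3);             // SampleFormat: IEEE float
    ifd_ptr_pos = buf.size();
    put32(buf, 0);                      // next IFD (patched or stays 0)
  }

  FILE* fh = std::fopen(path.c_str(), "wb");
  if (!fh) stop("cannot open '%s' for writing", path);
  const size_t nw = std::fwrite(buf.data(), 1, buf.size(), fh);
  std::fclose(fh);
  if (nw != buf.size()) stop("short write to '%s'", path);
}
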