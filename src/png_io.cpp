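// Minimal PNG codec for 8-bit greyscale (masks) and RGB (scenes).
//
// No pre-installed R package reads or writes PNG in this toolchain, so the
// package carries its own codec against zlib.  Scope is deliberately
// narrow: bit depth 8, colour types 0 (grey) and 2 (RGB), no interlacing,
// no palette.  The writer emits filter type 0 scanlines; the reader
// understands all five standard scanline filters so externally produced
// files of the supported colour types load too.

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <cstring>
#include <vector>
using namespace Rcpp;

static const unsigned char PNG_SIG[8] = {137, 80, 78, 71, 13, 10, 26, 10};

static void put_be32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static uint32_t get_be32(const unsigned char* p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) |
         ((uint32_t)p[2] << 8) | (uint32_t)p[3];
}

static void write_chunk(FILE* f, const char type[4],
                        const unsigned char* data, uint32_t len) {
  unsigned char hdr[8];
  hdr[0] = (len >> 24) & 0xff; hdr[1] = (len >> 16) & 0xff;
  hdr[2] = (len >> 8) & 0xff;  hdr[3] = len & 0xff;
  std::memcpy(hdr + 4, type, 4);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, (const Bytef*)type, 4);
  if (len) crc = crc32(crc, data, len);
  unsigned char tail[4] = {
    (unsigned char)((crc >> 24) & 0xff), (unsigned char)((crc >> 16) & 0xff),
    (unsigned char)((crc >> 8) & 0xff), (unsigned char)(crc & 0xff)};
  if (fwrite(hdr, 1, 8, f) != 8 || (len && fwrite(data, 1, len, f) != len) ||
      fwrite(tail, 1, 4, f) != 4)
    stop("png: write failed");
}

// data: integers 0..255 in column-major (H, W[, C]) order.
// [[Rcpp::export]]
void cpp_write_png(std::string path, IntegerVector data, int height,
                   int width, int channels) {
  if (channels != 1 && channels != 3)
    stop("png: only 1 (grey) or 3 (RGB) channels supported");
  if ((R_xlen_t)height * width * channels != data.size())
    stop("png: data length does not match dimensions");

  size_t stride = (size_t)width * channels;
  std::vector<unsigned char> raw(((size_t)height) * (stride + 1));
  size_t plane = (size_t)height * width;
  for (int h = 0; h < height; ++h) {
    unsigned char* row = &raw[(size_t)h * (stride + 1)];
    row[0] = 0;  // filter: None
    for (int w = 0; w < width; ++w)
      for (int c = 0; c < channels; ++c) {
        int v = data[h + (size_t)height * w + plane * c];
        if (v < 0) v = 0;
        if (v > 255) v = 255;
        row[1 + (size_t)w * channels + c] = (unsigned char)v;
      }
  }

  uLongf bound = compressBound(raw.size());
  std::vector<unsigned char> comp(bound);
  if (compress2(comp.data(), &bound, raw.data(), raw.size(), 6) != Z_OK)
    stop("png: deflate failed");

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("png: cannot open '%s' for writing", path.c_str());
  std::fwrite(PNG_SIG, 1, 8, f);
  std::vector<unsigned char> ihdr;
  put_be32(ihdr, (uint32_t)width);
  put_be32(ihdr, (uint32_t)height);
  ihdr.push_back(8);                                // bit depth
  ihdr.push_back(channels == 1 ? 0 : 2);            // colour type
  ihdr.push_back(0); ihdr.push_back(0); ihdr.push_back(0);
  write_chunk(f, "IHDR", ihdr.data(), (uint32_t)ihdr.size());
  write_chunk(f, "IDAT", comp.data(), (uint32_t)bound);
  write_chunk(f, "IEND", NULL, 0);
  std::fclose(f);
}

static unsigned char paeth(int a, int b, int c) {
  int p = a + b - c;
  int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return (unsigned char)a;
  if (pb <= pc) return (unsigned char)b;
  return (unsigned char)c;
}

// [[Rcpp::export]]
List cpp_read_png(std::string path) {
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("png: cannot open '%s'", path.c_str());
  unsigned char sig[8];
  if (std::fread(sig, 1, 8, f) != 8 || std::memcmp(sig, PNG_SIG, 8) != 0) {
    std::fclose(f);
    stop("png: '%s' is not a PNG file", path.c_str());
  }
  int width = 0, height = 0, channels = 0;
  bool have_ihdr = false;
  std::vector<unsigned char> idat;
  for (;;) {
    unsigned char hdr[8];
    if (std::fread(hdr, 1, 8, f) != 8) { std::fclose(f); stop("png: truncated file"); }
    uint32_t len = get_be32(hdr);
    char type[5] = {0};
    std::memcpy(type, hdr + 4, 4);
    std::vector<unsigned char> data(len);
    if (len && std::fread(data.data(), 1, len, f) != len) {
      std::fclose(f); stop("png: truncated chunk %s", type);
    }
    std::fseek(f, 4, SEEK_CUR);  // skip CRC
    if (std::strcmp(type, "IHDR") == 0) {
      width = (int)get_be32(&data[0]);
      height = (int)get_be32(&data[4]);
      int depth = data[8], ctype = data[9], interlace = data[12];
      if (depth != 8) { std::fclose(f); stop("png: only bit depth 8 supported"); }
      if (interlace != 0) { std::fclose(f); stop("png: interlaced files not supported"); }
      if (ctype == 0) channels = 1;
      else if (ctype == 2) channels = 3;
      else { std::fclose(f); stop("png: unsupported colour type %d", ctype); }
      have_ihdr = true;
    } else if (std::strcmp(type, "IDAT") == 0) {
      idat.insert(idat.end(), data.begin(), data.end());
    } else if (std::strcmp(type, "IEND") == 0) {
      break;
    }
  }
  std::fclose(f);
  if (!have_ihdr || idat.empty()) stop("png: missing IHDR or IDAT");

  size_t stride = (size_t)width * channels;
  uLongf rawlen = (uLongf)(((size_t)height) * (stride + 1));
  std::vector<unsigned char> raw(rawlen);
  if (uncompress(raw.data(), &rawlen, idat.data(), idat.size()) != Z_OK ||
      rawlen != ((uLongf)height) * (stride + 1))
    stop("png: inflate failed");

  int bpp = channels;  // bytes per pixel at depth 8
  std::vector<unsigned char> prev(stride, 0), cur(stride);
  IntegerVector out((R_xlen_t)height * width * channels);
  size_t plane = (size_t)height * width;
  for (int h = 0; h < height; ++h) {
    const unsigned char* row = &raw[(size_t)h * (stride + 1)];
    int filt = row[0];
    const unsigned char* src = row + 1;
    for (size_t i = 0; i < stride; ++i) {
      int a = i >= (size_t)bpp ? cur[i - bpp] : 0;
      int b = prev[i];
      int c = i >= (size_t)bpp ? prev[i - bpp] : 0;
      unsigned char v;
      switch (filt) {
        case 0: v = src[i]; break;
        case 1: v = (unsigned char)(src[i] + a); break;
        case 2: v = (unsigned char)(src[i] + b); break;
        case 3: v = (unsigned char)(src[i] + ((a + b) >> 1)); break;
        case 4: v = (unsigned char)(src[i] + paeth(a, b, c)); break;
        default: stop("png: bad filter type %d", filt);
      }
      cur[i] = v;
    }
    for (int w = 0; w < width; ++w)
      for (int ch = 0; ch < channels; ++ch)
        out[h + (size_t)height * w + plane * ch] = cur[(size_t)w * channels + ch];
    prev.swap(cur);
  }
  return List::create(_["height"] = height, _["width"] = width,
                      _["channels"] = channels, _["data"] = out);
}
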