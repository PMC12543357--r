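// Minimal PNG codec (8-bit grey / grey+alpha / RGB / RGBA, non-interlaced).
// The stack this package targets has no image-reading R package, so the
// pipeline carries its own reader/writer backed by zlib.
#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <cstring>
#include <vector>

using namespace Rcpp;

namespace {

const unsigned char PNG_SIG[8] = {137, 80, 78, 71, 13, 10, 26, 10};

void put_u32(std::vector<unsigned char> &v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

uint32_t get_u32(const unsigned char *p) {
  return (uint32_t(p[0]) << 24) | (uint32_t(p[1]) << 16) |
         (uint32_t(p[2]) << 8) | uint32_t(p[3]);
}

void write_chunk(std::vector<unsigned char> &out, const char *type,
                 const unsigned char *data, size_t len) {
  put_u32(out, (uint32_t)len);
  size_t start = out.size();
  out.insert(out.end(), type, type + 4);
  if (len) out.insert(out.end(), data, data + len);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, (uInt)(len + 4));
  put_u32(out, (uint32_t)crc);
}

int paeth(int a, int b, int c) {
  int p = a + b - c, pa = std::abs(p - a), pb = std::abs(p - b),
      pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

} // namespace

// [[Rcpp::export(name = ".png_write_cpp")]]
void png_write_cpp(std::string path, NumericVector data, int width,
                   int height, int channels) {
  if (channels != 1 && channels != 3)
    stop("png write supports 1 (grey) or 3 (RGB) channels");
  if ((int)data.size() != width * height * channels)
    stop("pixel buffer size does not match width*height*channels");
  int color_type = (channels == 1) ? 0 : 2;
  size_t stride = (size_t)width * channels;
  std::vector<unsigned char> raw((stride + 1) * height);
  // data is column-major per channel: value(y, x, ch) = data[ch*w*h + x*h + y]
  for (int y = 0; y < height; ++y) {
    unsigned char *row = raw.data() + (size_t)y * (stride + 1);
    row[0] = 0; // filter: None
    for (int x = 0; x < width; ++x)
      for (int c = 0; c < channels; ++c) {
        double v = data[(size_t)c * width * height + (size_t)x * height + y];
        if (v < 0) v = 0;
        if (v > 255) v = 255;
        row[1 + x * channels + c] = (unsigned char)(v + 0.5);
      }
  }
  uLongf comp_len = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(comp_len);
  if (compress2(comp.data(), &comp_len, raw.data(), (uLong)raw.size(), 6) !=
      Z_OK)
    stop("zlib compression failed");

  std::vector<unsigned char> out;
  out.insert(out.end(), PNG_SIG, PNG_SIG + 8);
  unsigned char ihdr[13];
  ihdr[0] = (width >> 24) & 0xff; ihdr[1] = (width >> 16) & 0xff;
  ihdr[2] = (width >> 8) & 0xff;  ihdr[3] = width & 0xff;
  ihdr[4] = (height >> 24) & 0xff; ihdr[5] = (height >> 16) & 0xff;
  ihdr[6] = (height >> 8) & 0xff;  ihdr[7] = height & 0xff;
  ihdr[8] = 8;               // bit depth
  ihdr[9] = (unsigned char)color_type;
  ihdr[10] = ihdr[11] = ihdr[12] = 0;
  write_chunk(out, "IHDR", ihdr, 13);
  write_chunk(out, "IDAT", comp.data(), comp_len);
  write_chunk(out, "IEND", nullptr, 0);

  FILE *f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  size_t n = std::fwrite(out.data(), 1, out.size(), f);
  std::fclose(f);
  if (n != out.size()) stop("short write to '%s'", path.c_str());
}

// [[Rcpp::export(name = ".png_read_cpp")]]
List png_read_cpp(std::string path) {
  FILE *f = std::fopen(path.c_str(), "rb");
  if (!f) stop("cannot open '%s'", path.c_str());
  std::fseek(f, 0, SEEK_END);
  long fsize = std::ftell(f);
  std::fseek(f, 0, SEEK_SET);
  std::vector<unsigned char> buf((size_t)std::max(fsize, 0L));
  size_t nread = buf.empty() ? 0 : std::fread(buf.data(), 1, buf.size(), f);
  std::fclose(f);
  if (nread != buf.size() || buf.size() < 8 ||
      std::memcmp(buf.data(), PNG_SIG, 8) != 0)
    stop("'%s' is not a PNG file", path.c_str());

  int width = 0, height = 0, bit_depth = 0, color_type = 0, interlace = 0;
  std::vector<unsigned char> idat;
  size_t pos = 8;
  while (pos + 8 <= buf.size()) {
    uint32_t len = get_u32(buf.data() + pos);
    const char *type = (const char *)buf.data() + pos + 4;
    if (pos + 12 + len > buf.size()) stop("truncated PNG chunk in '%s'", path.c_str());
    const unsigned char *cdata = buf.data() + pos + 8;
    if (std::memcmp(type, "IHDR", 4) == 0) {
      width = (int)get_u32(cdata);
      height = (int)get_u32(cdata + 4);
      bit_depth = cdata[8];
      color_type = cdata[9];
      interlace = cdata[12];
    } else if (std::memcmp(type, "IDAT", 4) == 0) {
      idat.insert(idat.end(), cdata, cdata + len);
    } else if (std::memcmp(type, "IEND", 4) == 0) {
      break;
    }
    pos += 12 + len;
  }
  if (width <= 0 || height <= 0) stop("bad PNG header in '%s'", path.c_str());
  if (bit_depth != 8) stop("only 8-bit PNGs are supported ('%s')", path.c_str());
  if (interlace != 0) stop("interlaced PNGs are not supported ('%s')", path.c_str());
  int channels;
  switch (color_type) {
  case 0: channels = 1; break;
  case 2: channels = 3; break;
  case 4: channels = 2; break;
  case 6: channels = 4; break;
  default: stop("unsupported PNG colour type %d in '%s'", color_type, path.c_str());
  }

  size_t stride = (size_t)width * channels;
  std::vector<unsigned char> raw((stride + 1) * height);
  uLongf raw_len = (uLongf)raw.size();
  int zrc = uncompress(raw.data(), &raw_len, idat.data(), (uLong)idat.size());
  if (zrc != Z_OK || raw_len != raw.size())
    stop("corrupt PNG pixel data in '%s'", path.c_str());

  // undo per-row filters in place
  std::vector<unsigned char> prev(stride, 0);
  for (int y = 0; y < height; ++y) {
    unsigned char *row = raw.data() + (size_t)y * (stride + 1);
    int filter = row[0];
    unsigned char *cur = row + 1;
    for (size_t i = 0; i < stride; ++i) {
      int a = (i >= (size_t)channels) ? cur[i - channels] : 0;
      int b = prev[i];
      int c = (i >= (size_t)channels) ? prev[i - channels] : 0;
      int x = cur[i];
      switch (filter) {
      case 0: break;
      case 1: x += a; break;
      case 2: x += b; break;
      case 3: x += (a + b) / 2; break;
      case 4: x += paeth(a, b, c); break;
      default: stop("bad PNG filter type %d", filter);
      }
      cur[i] = (unsigned char)(x & 0xff);
    }
    std::memcpy(prev.data(), cur, stride);
  }

  NumericVector out((size_t)width * height * channels);
  for (int y = 0; y < height; ++y) {
    const unsigned char *cur = raw.data() + (size_t)y * (stride + 1) + 1;
    for (int x = 0; x < width; ++x)
      for (int c = 0; c < channels; ++c)
        out[(size_t)c * width * height + (size_t)x * height + y] =
            cur[x * channels + c];
  }
  return List::create(_["data"] = out, _["width"] = width,
                      _["height"] = height, _["channels"] = channels);
}
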