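#include <Rcpp.h>
using namespace Rcpp;

// SLIC superpixels on the CPU. Distance between pixel p and cluster center k:
//   D^2 = ||rgb_p - rgb_k||^2 + C^2 * ||xy_p - xy_k||^2 / S^2
// with color channels on [0,1], so the compactness C is image-independent.
// After N assignment/update iterations, connectivity is enforced by merging
// components smaller than S*S/4 into an adjacent, already-finalized region.
// Returns an H x W integer matrix of dense, 0-based region ids.
// [[Rcpp::export(name = ".cpp_slic", rng = false)]]
IntegerMatrix cpp_slic(NumericVector img, int H, int W,
                       int S, double compactness, int iters) {
  const double *px = img.begin(); // (H, W, 3) column-major
  const R_xlen_t plane = (R_xlen_t)H * W;

  int ny = std::max(1, (int)std::lround((double)H / S));
  int nx = std::max(1, (int)std::lround((double)W / S));
  const int K = ny * nx;
  std::vector<double> cr(K), cc(K), cR(K), cG(K), cB(K);
  {
    const double sy = (double)H / ny, sx = (double)W / nx;
    int k = 0;
    for (int gy = 0; gy < ny; ++gy) {
      for (int gx = 0; gx < nx; ++gx, ++k) {
        int r = std::min(H - 1, (int)((gy + 0.5) * sy));
        int c = std::min(W - 1, (int)((gx + 0.5) * sx));
        cr[k] = r; cc[k] = c;
        cR[k] = px[r + (R_xlen_t)c * H];
        cG[k] = px[r + (R_xlen_t)c * H + plane];
        cB[k] = px[r + (R_xlen_t)c * H + 2 * plane];
      }
    }
  }

  std::vector<int> label((size_t)plane, 0);
  std::vector<double> dist((size_t)plane);
  const double spw = (compactness * compactness) / ((double)S * S);

  for (int it = 0; it < iters; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int k = 0; k < K; ++k) {
      const int r0 = std::max(0, (int)cr[k] - S), r1 = std::min(H - 1, (int)cr[k] + S);
      const int c0 = std::max(0, (int)cc[k] - S), c1 = std::min(W - 1, (int)cc[k] + S);
      for (int c = c0; c <= c1; ++c) {
        const double dc2 = (c - cc[k]) * (c - cc[k]);
        const double *colR = px + (R_xlen_t)c * H;
        for (int r = r0; r <= r1; ++r) {
          const R_xlen_t p = r + (R_xlen_t)c * H;
          const double dR = colR[r] - cR[k];
          const double dG = px[p + plane] - cG[k];
          const double dB = px[p + 2 * plane] - cB[k];
          const double d = dR * dR + dG * dG + dB * dB +
                           spw * ((r - cr[k]) * (r - cr[k]) + dc2);
          if (d < dist[p]) { dist[p] = d; label[p] = k; }
        }
      }
    }
    std::vector<double> sr(K, 0), sc(K, 0), sR(K, 0), sG(K, 0), sB(K, 0);
    std::vector<int> n(K, 0);
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        const R_xlen_t p = r + (R_xlen_t)c * H;
        const int k = label[p];
        sr[k] += r; sc[k] += c;
        sR[k] += px[p]; sG[k] += px[p + plane]; sB[k] += px[p + 2 * plane];
        ++n[k];
      }
    }
    for (int k = 0; k < K; ++k) {
      if (n[k] == 0) continue;
      cr[k] = sr[k] / n[k]; cc[k] = sc[k] / n[k];
      cR[k] = sR[k] / n[k]; cG[k] = sG[k] / n[k]; cB[k] = sB[k] / n[k];
    }
  }

  // connectivity enforcement: flood-fill 4-connected components in scan
  // order; orphans below min_size adopt the label of the previously
  // finalized neighboring region.
  const int min_size = std::max(1, (S * S) / 4);
  IntegerMatrix out(H, W);
  std::fill(out.begin(), out.end(), -1);
  std::vector<R_xlen_t> stack;
  const int dr[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  int next_label = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const R_xlen_t p = r + (R_xlen_t)c * H;
      if (out[p] >= 0) continue;
      int adjacent = -1; // a finalized neighbor's label, for orphan merging
      stack.clear();
      stack.push_back(p);
      out[p] = next_label;
      size_t head = 0;
      while (head < stack.size()) {
        const R_xlen_t q = stack[head++];
        const int qr = (int)(q % H), qc = (int)(q / H);
        for (int d = 0; d < 4; ++d) {
          const int nr = qr + dr[d], nc = qc + dc4[d];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          const R_xlen_t np = nr + (R_xlen_t)nc * H;
          if (out[np] < 0 && label[np] == label[p]) {
            out[np] = next_label;
            stack.push_back(np);
          } else if (out[np] >= 0 && out[np] != next_label) {
            adjacent = out[np];
          }
        }
      }
      if ((int)stack.size() < min_size && adjacent >= 0) {
        for (R_xlen_t q : stack) out[q] = adjacent;
      } else {
        ++next_label;
      }
    }
  }
  out.attr("n_regions") = next_label;
  return out;
}
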