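// Per-point surface normals from neighborhood covariance eigen-structure.
// Neighborhoods are closed balls of a fixed metric radius, found with a
// uniform grid whose cell edge equals the radius (27-cell stencil).

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

inline int64_t cell_key(int ix, int iy, int iz) {
  // pack three 21-bit signed cell coordinates into one key
  const int64_t B = 1 << 20;
  return ((int64_t)(ix + B) << 42) | ((int64_t)(iy + B) << 21) | (int64_t)(iz + B);
}

} // namespace

// [[Rcpp::export(name = ".estimate_normals_cpp")]]
List estimate_normals_cpp(const arma::mat& pts, double radius, double tie_tol) {
  const arma::uword n = pts.n_rows;
  if (pts.n_cols != 3) stop("points must be an n x 3 matrix");
  if (!(radius > 0)) stop("radius must be positive");

  std::unordered_map<int64_t, std::vector<arma::uword>> grid;
  grid.reserve(n * 2);
  const double inv_r = 1.0 / radius;
  std::vector<int> cix(n), ciy(n), ciz(n);
  for (arma::uword i = 0; i < n; ++i) {
    cix[i] = (int)std::floor(pts(i, 0) * inv_r);
    ciy[i] = (int)std::floor(pts(i, 1) * inv_r);
    ciz[i] = (int)std::floor(pts(i, 2) * inv_r);
    grid[cell_key(cix[i], ciy[i], ciz[i])].push_back(i);
  }

  arma::mat normals(n, 3, arma::fill::zeros);
  LogicalVector valid(n);
  const double r2 = radius * radius;

  const double* px = pts.colptr(0);
  const double* py = pts.colptr(1);
  const double* pz = pts.colptr(2);

  for (arma::uword i = 0; i < n; ++i) {
    // single pass: moments of offsets from the query point (well
    // conditioned, |d| <= radius), then population covariance
    double s1[3] = {0, 0, 0};
    double s2[6] = {0, 0, 0, 0, 0, 0};  // xx, xy, xz, yy, yz, zz
    int cnt = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cell_key(cix[i] + dx, ciy[i] + dy, ciz[i] + dz));
          if (it == grid.end()) continue;
          for (arma::uword j : it->second) {
            const double ddx = px[j] - px[i];
            const double ddy = py[j] - py[i];
            const double ddz = pz[j] - pz[i];
            if (ddx * ddx + ddy * ddy + ddz * ddz > r2) continue;
            ++cnt;
            s1[0] += ddx; s1[1] += ddy; s1[2] += ddz;
            s2[0] += ddx * ddx; s2[1] += ddx * ddy; s2[2] += ddx * ddz;
            s2[3] += ddy * ddy; s2[4] += ddy * ddz; s2[5] += ddz * ddz;
          }
        }
    if (cnt < 3) { valid[i] = false; continue; }

    const double m = (double)cnt;
    arma::mat33 C;
    C(0, 0) = s2[0] / m - (s1[0] / m) * (s1[0] / m);
    C(0, 1) = C(1, 0) = s2[1] / m - (s1[0] / m) * (s1[1] / m);
    C(0, 2) = C(2, 0) = s2[2] / m - (s1[0] / m) * (s1[2] / m);
    C(1, 1) = s2[3] / m - (s1[1] / m) * (s1[1] / m);
    C(1, 2) = C(2, 1) = s2[4] / m - (s1[1] / m) * (s1[2] / m);
    C(2, 2) = s2[5] / m - (s1[2] / m) * (s1[2] / m);

    arma::vec3 eval;
    arma::mat33 evec;
    if (!arma::eig_sym(eval, evec, C)) { valid[i] = false; continue; }
    // ambiguous normal: two smallest eigenvalues numerically equal
    const double scale = std::max(eval(2), 1e-300);
    if ((eval(1) - eval(0)) < tie_tol * scale) { valid[i] = false; continue; }

    arma::vec3 nvec = evec.col(0);
    if (nvec(2) > 0) nvec = -nvec; // orient toward the camera (z <= 0)
    normals.row(i) = nvec.t();
    valid[i] = true;
  }

  return List::create(_["normals"] = normals, _["valid"] = valid);
}

// CRC-32 (IEEE 802.3, as used by PNG chunks), table-driven.
// [[Rcpp::export(name = ".crc32_cpp")]]
double crc32_cpp(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t k = 0; k < 256; ++k) {
      uint32_t c = k;
      for (int b = 0; b < 8; ++b)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[k] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
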