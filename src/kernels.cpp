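#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Trilinear gather at a (0-based) voxel coordinate. Returns false when the
// 2x2x2 support leaves the grid entirely; partial support uses `oob` for the
// missing corners when use_oob is true, otherwise fails.
static inline bool trilinear(const double *v, const int *d,
                             double x, double y, double z,
                             bool use_oob, double oob, double &out) {
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0.0;
    for (int dz = 0; dz < 2; ++dz) {
        for (int dy = 0; dy < 2; ++dy) {
            for (int dx = 0; dx < 2; ++dx) {
                double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                if (w == 0.0) continue;
                int xi = x0 + dx, yi = y0 + dy, zi = z0 + dz;
                double val;
                if (xi < 0 || yi < 0 || zi < 0 || xi >= d[0] || yi >= d[1] || zi >= d[2]) {
                    if (!use_oob) return false;
                    val = oob;
                } else {
                    val = v[xi + (R_xlen_t)d[0] * (yi + (R_xlen_t)d[1] * zi)];
                }
                acc += w * val;
            }
        }
    }
    out = acc;
    return true;
}

// Resample a source volume onto a destination grid. M is a 4x4 matrix mapping
// 0-based destination voxel indices to 0-based source voxel indices.
// method: 0 = trilinear, 1 = nearest neighbour. Out-of-grid samples get
// `fill` (may be NA).
// [[Rcpp::export]]
NumericVector c_resample_affine(NumericVector src, IntegerVector sdim,
                                NumericMatrix M, IntegerVector ddim,
                                int method, double fill) {
    const double *v = src.begin();
    int d[3] = { sdim[0], sdim[1], sdim[2] };
    int nx = ddim[0], ny = ddim[1], nz = ddim[2];
    NumericVector out((R_xlen_t)nx * ny * nz);
    double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
    double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
    double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
            double bx = m01 * j + m02 * k + m03;
            double by = m11 * j + m12 * k + m13;
            double bz = m21 * j + m22 * k + m23;
            for (int i = 0; i < nx; ++i, ++idx) {
                double x = m00 * i + bx, y = m10 * i + by, z = m20 * i + bz;
                if (method == 1) {
                    int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
                    if (xi < 0 || yi < 0 || zi < 0 || xi >= d[0] || yi >= d[1] || zi >= d[2])
                        out[idx] = fill;
                    else
                        out[idx] = v[xi + (R_xlen_t)d[0] * (yi + (R_xlen_t)d[1] * zi)];
                } else {
                    double val;
                    if (x < -1 || y < -1 || z < -1 || x > d[0] || y > d[1] || z > d[2]) {
                        out[idx] = fill;
                    } else if (trilinear(v, d, x, y, z, !ISNA(fill), fill, val)) {
                        out[idx] = val;
                    } else {
                        out[idx] = fill;
                    }
                }
            }
        }
    }
    out.attr("dim") = ddim;
    return out;
}

// 26-connected component labelling of a binary mask (column-major 3D array).
// Labels are assigned in first-encounter scan order, so the output is
// deterministic for a given mask.
// [[Rcpp::export]]
IntegerVector c_label_components(LogicalVector mask, IntegerVector dim) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector lab(n, 0);
    int next = 0;
    std::queue<R_xlen_t> q;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || lab[s]) continue;
        lab[s] = ++next;
        q.push(s);
        while (!q.empty()) {
            R_xlen_t c = q.front(); q.pop();
            int ci = (int)(c % nx), cj = (int)((c / nx) % ny), ck = (int)(c / ((R_xlen_t)nx * ny));
            for (int dk = -1; dk <= 1; ++dk) {
                int zk = ck + dk; if (zk < 0 || zk >= nz) continue;
                for (int dj = -1; dj <= 1; ++dj) {
                    int yj = cj + dj; if (yj < 0 || yj >= ny) continue;
                    for (int di = -1; di <= 1; ++di) {
                        int xi = ci + di; if (xi < 0 || xi >= nx) continue;
                        if (!di && !dj && !dk) continue;
                        R_xlen_t t = xi + (R_xlen_t)nx * (yj + (R_xlen_t)ny * zk);
                        if (mask[t] && !lab[t]) { lab[t] = next; q.push(t); }
                    }
                }
            }
        }
    }
    lab.attr("dim") = dim;
    return lab;
}

// Forward-project a volume into a set of 2D slices through a sampled PSF.
// maps:    list of 4x4 matrices, slice pixel (i,j,0,1) -> 0-based volume voxel
// offsets: list of 3xK matrices, PSF sample offsets in volume voxel units
// weights: length-K PSF weights (sum to 1)
// Out-of-grid samples contribute `oob`, keeping the operator linear in the
// volume when oob = 0.
// [[Rcpp::export]]
List c_project_slices(NumericVector vol, IntegerVector vdim,
                      List maps, List offsets, NumericVector weights,
                      int nx, int ny, double oob) {
    const double *v = vol.begin();
    int d[3] = { vdim[0], vdim[1], vdim[2] };
    int ns = maps.size();
    int K = weights.size();
    List out(ns);
    for (int s = 0; s < ns; ++s) {
        NumericMatrix M = maps[s];
        NumericMatrix off = offsets[s];
        NumericMatrix sl(nx, ny);
        for (int j = 0; j < ny; ++j) {
            for (int i = 0; i < nx; ++i) {
                double bx = M(0,0) * i + M(0,1) * j + M(0,3);
                double by = M(1,0) * i + M(1,1) * j + M(1,3);
                double bz = M(2,0) * i + M(2,1) * j + M(2,3);
                double acc = 0.0;
                for (int m = 0; m < K; ++m) {
                    double x = bx + off(0,m), y = by + off(1,m), z = bz + off(2,m);
                    double val;
                    if (trilinear(v, d, x, y, z, true, oob, val))
                        acc += weights[m] * val;
                    else
                        acc += weights[m] * oob;
                }
                sl(i, j) = acc;
            }
        }
        out[s] = sl;
    }
    return out;
}

// Adjoint of c_project_slices with per-slice scalar weights: scatters
// sw[s] * weights[m] * resid(i,j) through the trilinear coefficients.
// Returns the accumulated volume and the accumulated coefficient mass
// (used as a diagonal preconditioner). NA residual pixels are skipped.
// [[Rcpp::export]]
List c_backproject_slices(List resid, List maps, List offsets,
                          NumericVector weights, NumericVector sw,
                          IntegerVector vdim) {
    int d[3] = { vdim[0], vdim[1], vdim[2] };
    R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
    NumericVector num(n), mass(n);
    int ns = resid.size();
    int K = weights.size();
    for (int s = 0; s < ns; ++s) {
        double w_s = sw[s];
        if (w_s == 0.0) continue;
        NumericMatrix r = resid[s];
        NumericMatrix M = maps[s];
        NumericMatrix off = offsets[s];
        int nx = r.nrow(), ny = r.ncol();
        for (int j = 0; j < ny; ++j) {
            for (int i = 0; i < nx; ++i) {
                double rv = r(i, j);
                if (ISNA(rv)) continue;
                double bx = M(0,0) * i + M(0,1) * j + M(0,3);
                double by = M(1,0) * i + M(1,1) * j + M(1,3);
                double bz = M(2,0) * i + M(2,1) * j + M(2,3);
                for (int m = 0; m < K; ++m) {
                    double x = bx + off(0,m), y = by + off(1,m), z = bz + off(2,m);
                    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
                    double fx = x - x0, fy = y - y0, fz = z - z0;
                    double wm = w_s * weights[m];
                    for (int dz = 0; dz < 2; ++dz) {
                        int zi = z0 + dz; if (zi < 0 || zi >= d[2]) continue;
                        for (int dy = 0; dy < 2; ++dy) {
                            int yi = y0 + dy; if (yi < 0 || yi >= d[1]) continue;
                            for (int dx = 0; dx < 2; ++dx) {
                                int xi = x0 + dx; if (xi < 0 || xi >= d[0]) continue;
                                double c = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                                if (c == 0.0) continue;
                                R_xlen_t t = xi + (R_xlen_t)d[0] * (yi + (R_xlen_t)d[1] * zi);
                                num[t] += wm * c * rv;
                                mass[t] += wm * c;
                            }
                        }
                    }
                }
            }
        }
    }
    num.attr("dim") = vdim;
    mass.attr("dim") = vdim;
    return List::create(_["num"] = num, _["mass"] = mass);
}

// Separable 3D convolution with one odd-length kernel applied along each axis
// (zero padding at the boundaries).
// [[Rcpp::export]]
NumericVector c_separable_conv(NumericVector vol, IntegerVector dim,
                               NumericVector kernel) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    int K = kernel.size(), h = K / 2;
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector a = clone(vol), b(n);
    int dims[3] = { nx, ny, nz };
    R_xlen_t strides[3] = { 1, nx, (R_xlen_t)nx * ny };
    for (int ax = 0; ax < 3; ++ax) {
        int len = dims[ax];
        R_xlen_t st = strides[ax];
        // iterate over all lines along axis `ax`
        int o1 = (ax == 0) ? 1 : 0;
        int o2 = (ax == 2) ? 1 : 2;
        for (int j2 = 0; j2 < dims[o2]; ++j2) {
            for (int j1 = 0; j1 < dims[o1]; ++j1) {
                R_xlen_t base = strides[o1] * j1 + strides[o2] * j2;
                for (int i = 0; i < len; ++i) {
                    double acc = 0.0;
                    for (int m = 0; m < K; ++m) {
                        int p = i + m - h;
                        if (p < 0 || p >= len) continue;
                        acc += kernel[m] * a[base + st * p];
                    }
                    b[base + st * i] = acc;
                }
            }
        }
        std::swap(a, b);
    }
    a.attr("dim") = dim;
    return a;
}

// Block-mean downsampling by integer factor f along each axis (trailing
// partial blocks are averaged over their actual extent).
// [[Rcpp::export]]
NumericVector c_block_mean(NumericVector vol, IntegerVector dim, int f) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    int mx = (nx + f - 1) / f, my = (ny + f - 1) / f, mz = (nz + f - 1) / f;
    NumericVector out((R_xlen_t)mx * my * mz);
    for (int k = 0; k < mz; ++k) {
        for (int j = 0; j < my; ++j) {
            for (int i = 0; i < mx; ++i) {
                double acc = 0.0; int cnt = 0;
                for (int dz = 0; dz < f; ++dz) {
                    int z = k * f + dz; if (z >= nz) break;
                    for (int dy = 0; dy < f; ++dy) {
                        int y = j * f + dy; if (y >= ny) break;
                        for (int dx = 0; dx < f; ++dx) {
                            int x = i * f + dx; if (x >= nx) break;
                            acc += vol[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
                            ++cnt;
                        }
                    }
                }
                out[i + (R_xlen_t)mx * (j + (R_xlen_t)my * k)] = acc / cnt;
            }
        }
    }
    out.attr("dim") = IntegerVector::create(mx, my, mz);
    return out;
}

// Row-wise median of a matrix, ignoring NA entries; rows with no finite
// entries give NA.
// [[Rcpp::export]]
NumericVector c_row_median(NumericMatrix m) {
    int n = m.nrow(), k = m.ncol();
    NumericVector out(n);
    std::vector<double> buf;
    buf.reserve(k);
    for (int i = 0; i < n; ++i) {
        buf.clear();
        for (int j = 0; j < k; ++j) {
            double v = m(i, j);
            if (!ISNA(v) && !ISNAN(v)) buf.push_back(v);
        }
        int c = (int)buf.size();
        if (c == 0) { out[i] = NA_REAL; continue; }
        std::sort(buf.begin(), buf.end());
        out[i] = (c % 2) ? buf[c / 2] : 0.5 * (buf[c / 2 - 1] + buf[c / 2]);
    }
    return out;
}
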