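// 3-D image primitives: anisotropic squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher separable lower-envelope algorithm),
// 26-connected component labeling, grayscale reconstruction by dilation
// (Vincent's hybrid raster/FIFO algorithm), marker-based priority-flood
// watershed, separable Gaussian smoothing and axis-aligned box dilation.
//
// Arrays are R arrays with dim = c(d0, d1, d2) = (z, y, x); index
// i = i0 + d0*(i1 + d1*i2), i0 fastest-varying.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

static const double BIG = 1e20;

// ---- distance transform -------------------------------------------------

// 1-D squared-distance lower envelope on a line of n samples with grid
// spacing a; f holds squared distances so far, d receives the update.
static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& z,
                  int n, double a) {
    const double a2 = a * a;
    const double INF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        double s = 0.0;
        while (true) {
            int p = v[k];
            s = ((f[q] + a2 * q * q) - (f[p] + a2 * p * p)) /
                (2.0 * a2 * (q - p));
            if (s <= z[k]) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        int p = v[k];
        d[q] = a2 * (q - p) * (q - p) + f[p];
    }
}

// Squared Euclidean distance from every voxel to the nearest feature voxel,
// with per-axis spacings (physical units per step along d0, d1, d2).
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector feature, IntegerVector dim,
                         NumericVector spacing) {
    const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
    const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = feature[i] ? 0.0 : BIG;

    int nmax = std::max(d0, std::max(d1, d2));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along axis 0 (stride 1)
    for (int i2 = 0; i2 < d2; ++i2)
        for (int i1 = 0; i1 < d1; ++i1) {
            R_xlen_t base = (R_xlen_t)d0 * (i1 + (R_xlen_t)d1 * i2);
            for (int i0 = 0; i0 < d0; ++i0) f[i0] = out[base + i0];
            edt1d(f, d, v, z, d0, spacing[0]);
            for (int i0 = 0; i0 < d0; ++i0) out[base + i0] = d[i0];
        }
    // axis 1 (stride d0)
    for (int i2 = 0; i2 < d2; ++i2)
        for (int i0 = 0; i0 < d0; ++i0) {
            R_xlen_t base = i0 + (R_xlen_t)d0 * d1 * i2;
            for (int i1 = 0; i1 < d1; ++i1) f[i1] = out[base + (R_xlen_t)d0 * i1];
            edt1d(f, d, v, z, d1, spacing[1]);
            for (int i1 = 0; i1 < d1; ++i1) out[base + (R_xlen_t)d0 * i1] = d[i1];
        }
    // axis 2 (stride d0*d1)
    const R_xlen_t s2 = (R_xlen_t)d0 * d1;
    for (int i1 = 0; i1 < d1; ++i1)
        for (int i0 = 0; i0 < d0; ++i0) {
            R_xlen_t base = i0 + (R_xlen_t)d0 * i1;
            for (int i2 = 0; i2 < d2; ++i2) f[i2] = out[base + s2 * i2];
            edt1d(f, d, v, z, d2, spacing[2]);
            for (int i2 = 0; i2 < d2; ++i2) out[base + s2 * i2] = d[i2];
        }
    for (R_xlen_t i = 0; i < n; ++i)
        if (out[i] >= BIG / 2) out[i] = R_PosInf;
    return out;
}

// ---- 26-connected labeling ----------------------------------------------

// [[Rcpp::export]]
IntegerVector label26_cpp(LogicalVector mask, IntegerVector dim) {
    const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
    const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
    IntegerVector lab(n, 0);
    std::vector<R_xlen_t> stack;
    int next = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i] || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        stack.push_back(i);
        while (!stack.empty()) {
            R_xlen_t p = stack.back();
            stack.pop_back();
            int p0 = (int)(p % d0);
            int p1 = (int)((p / d0) % d1);
            int p2 = (int)(p / ((R_xlen_t)d0 * d1));
            for (int o2 = -1; o2 <= 1; ++o2)
                for (int o1 = -1; o1 <= 1; ++o1)
                    for (int o0 = -1; o0 <= 1; ++o0) {
                        if (o0 == 0 && o1 == 0 && o2 == 0) continue;
                        int q0 = p0 + o0, q1 = p1 + o1, q2 = p2 + o2;
                        if (q0 < 0 || q0 >= d0 || q1 < 0 || q1 >= d1 ||
                            q2 < 0 || q2 >= d2)
                            continue;
                        R_xlen_t q = q0 + (R_xlen_t)d0 * (q1 + (R_xlen_t)d1 * q2);
                        if (mask[q] && lab[q] == 0) {
                            lab[q] = next;
                            stack.push_back(q);
                        }
                    }
        }
    }
    lab.attr("n_labels") = next;
    return lab;
}

// ---- grayscale reconstruction by dilation (26-conn) ----------------------

// Vincent (1993) hybrid algorithm on integer images; marker <= mask required.
// [[Rcpp::export]]
IntegerVector reconstruct_cpp(IntegerVector marker, IntegerVector mask,
                              IntegerVector dim) {
    const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
    const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
    IntegerVector J(n);
    for (R_xlen_t i = 0; i < n; ++i)
        J[i] = std::min(marker[i], mask[i]);

    // raster (forward) pass: neighbors that precede p in scan order
    for (R_xlen_t p = 0; p < n; ++p) {
        int p0 = (int)(p % d0);
        int p1 = (int)((p / d0) % d1);
        int p2 = (int)(p / ((R_xlen_t)d0 * d1));
        int m = J[p];
        for (int o2 = -1; o2 <= 1; ++o2)
            for (int o1 = -1; o1 <= 1; ++o1)
                for (int o0 = -1; o0 <= 1; ++o0) {
                    if (o2 > 0 || (o2 == 0 && (o1 > 0 || (o1 == 0 && o0 >= 0))))
                        continue;  // keep only preceding neighbors
                    int q0 = p0 + o0, q1 = p1 + o1, q2 = p2 + o2;
                    if (q0 < 0 || q0 >= d0 || q1 < 0 || q1 >= d1 ||
                        q2 < 0 || q2 >= d2)
                        continue;
                    R_xlen_t q = q0 + (R_xlen_t)d0 * (q1 + (R_xlen_t)d1 * q2);
                    if (J[q] > m) m = J[q];
                }
        J[p] = std::min(m, mask[p]);
    }
    // anti-raster pass + queue seeding
    std::queue<R_xlen_t> fifo;
    for (R_xlen_t p = n - 1; p >= 0; --p) {
        int p0 = (int)(p % d0);
        int p1 = (int)((p / d0) % d1);
        int p2 = (int)(p / ((R_xlen_t)d0 * d1));
        int m = J[p];
        bool enqueue = false;
        for (int o2 = -1; o2 <= 1; ++o2)
            for (int o1 = -1; o1 <= 1; ++o1)
                for (int o0 = -1; o0 <= 1; ++o0) {
                    if (o2 < 0 || (o2 == 0 && (o1 < 0 || (o1 == 0 && o0 <= 0))))
                        continue;  // keep only following neighbors
                    int q0 = p0 + o0, q1 = p1 + o1, q2 = p2 + o2;
                    if (q0 < 0 || q0 >= d0 || q1 < 0 || q1 >= d1 ||
                        q2 < 0 || q2 >= d2)
                        continue;
                    R_xlen_t q = q0 + (R_xlen_t)d0 * (q1 + (R_xlen_t)d1 * q2);
                    if (J[q] > m) m = J[q];
                }
        J[p] = std::min(m, mask[p]);
        for (int o2 = -1; o2 <= 1 && !enqueue; ++o2)
            for (int o1 = -1; o1 <= 1 && !enqueue; ++o1)
                for (int o0 = -1; o0 <= 1 && !enqueue; ++o0) {
                    if (o2 < 0 || (o2 == 0 && (o1 < 0 || (o1 == 0 && o0 <= 0))))
                        continue;
                    int q0 = p0 + o0, q1 = p1 + o1, q2 = p2 + o2;
                    if (q0 < 0 || q0 >= d0 || q1 < 0 || q1 >= d1 ||
                        q2 < 0 || q2 >= d2)
                        continue;
                    R_xlen_t q = q0 + (R_xlen_t)d0 * (q1 + (R_xlen_t)d1 * q2);
                    if (J[q] < J[p] && J[q] < mask[q]) enqueue = true;
                }
        if (enqueue) fifo.push(p);
        if (p == 0) break;
    }
    // FIFO propagation
    while (!fifo.empty()) {
        R_xlen_t p = fifo.front();
        fifo.pop();
        int p0 = (int)(p % d0);
        int p1 = (int)((p / d0) % d1);
        int p2 = (int)(p / ((R_xlen_t)d0 * d1));
        for (int o2 = -1; o2 <= 1; ++o2)
            for (int o1 = -1; o1 <= 1; ++o1)
                for (int o0 = -1; o0 <= 1; ++o0) {
                    if (o0 == 0 && o1 == 0 && o2 == 0) continue;
                    int q0 = p0 + o0, q1 = p1 + o1, q2 = p2 + o2;
                    if (q0 < 0 || q0 >= d0 || q1 < 0 || q1 >= d1 ||
                        q2 < 0 || q2 >= d2)
                        continue;
                    R_xlen_t q = q0 + (R_xlen_t)d0 * (q1 + (R_xlen_t)d1 * q2);
                    if (J[q] < J[p] && mask[q] != J[q]) {
                        J[q] = std::min(J[p], mask[q]);
                        fifo.push(q);
                    }
                }
    }
    return J;
}

// ---- marker-based watershed (priority flood) -----------------------------

struct WsEntry {
    double prio;
    uint64_t ord;
    R_xlen_t idx;
};
struct WsCmp {
    bool operator()(const WsEntry& a, const WsEntry& b) const {
        if (a.prio != b.prio) return a.prio < b.prio;  // higher priority first
        return a.ord > b.ord;                          // FIFO among ties
    }
};

// Floods `mask` from labeled markers in decreasing order of `height`
// (the distance map); every mask voxel reachable from a marker gets the
// marker's label. 26-connectivity.
// [[Rcpp::export]]
IntegerVector watershed_flood_cpp(NumericVector height, IntegerVector markers,
                                  LogicalVector mask, IntegerVector dim) {
    const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
    const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
    IntegerVector lab(n, 0);
    std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
    uint64_t ord = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (markers[i] > 0 && mask[i]) {
            lab[i] = markers[i];
            pq.push({height[i], ord++, i});
        }
    }
    while (!pq.empty()) {
        WsEntry e = pq.top();
        pq.pop();
        R_xlen_t p = e.idx;
        int p0 = (int)(p % d0);
        int p1 = (int)((p / d0) % d1);
        int p2 = (int)(p / ((R_xlen_t)d0 * d1));
        for (int o2 = -1; o2 <= 1; ++o2)
            for (int o1 = -1; o1 <= 1; ++o1)
                for (int o0 = -1; o0 <= 1; ++o0) {
                    if (o0 == 0 && o1 == 0 && o2 == 0) continue;
                    int q0 = p0 + o0, q1 = p1 + o1, q2 = p2 + o2;
                    if (q0 < 0 || q0 >= d0 || q1 < 0 || q1 >= d1 ||
                        q2 < 0 || q2 >= d2)
                        continue;
                    R_xlen_t q = q0 + (R_xlen_t)d0 * (q1 + (R_xlen_t)d1 * q2);
                    if (mask[q] && lab[q] == 0) {
                        lab[q] = lab[p];
                        pq.push({height[q], ord++, q});
                    }
                }
    }
    return lab;
}

// ---- separable Gaussian smoothing ----------------------------------------

static void gauss_axis(std::vector<double>& buf, const std::vector<double>& w,
                       int r, std::vector<double>& line, int n) {
    for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int k = -r; k <= r; ++k) {
            int j = i + k;
            if (j < 0) j = -j - 1;            // reflect
            if (j >= n) j = 2 * n - j - 1;
            acc += w[k + r] * line[j];
        }
        buf[i] = acc;
    }
}

// [[Rcpp::export]]
NumericVector gauss3d_cpp(NumericVector img, IntegerVector dim,
                          NumericVector sigma) {
    const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
    const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
    NumericVector out = clone(img);
    int nmax = std::max(d0, std::max(d1, d2));
    std::vector<double> line(nmax), buf(nmax);

    for (int ax = 0; ax < 3; ++ax) {
        double s = sigma[ax];
        if (s <= 0) continue;
        int r = std::max(1, (int)std::ceil(3.0 * s));
        std::vector<double> w(2 * r + 1);
        double tot = 0.0;
        for (int k = -r; k <= r; ++k) {
            w[k + r] = std::exp(-0.5 * k * k / (s * s));
            tot += w[k + r];
        }
        for (auto& x : w) x /= tot;

        if (ax == 0) {
            for (int i2 = 0; i2 < d2; ++i2)
                for (int i1 = 0; i1 < d1; ++i1) {
                    R_xlen_t base = (R_xlen_t)d0 * (i1 + (R_xlen_t)d1 * i2);
                    for (int i = 0; i < d0; ++i) line[i] = out[base + i];
                    gauss_axis(buf, w, r, line, d0);
                    for (int i = 0; i < d0; ++i) out[base + i] = buf[i];
                }
        } else if (ax == 1) {
            for (int i2 = 0; i2 < d2; ++i2)
                for (int i0 = 0; i0 < d0; ++i0) {
                    R_xlen_t base = i0 + (R_xlen_t)d0 * d1 * i2;
                    for (int i = 0; i < d1; ++i)
                        line[i] = out[base + (R_xlen_t)d0 * i];
                    gauss_axis(buf, w, r, line, d1);
                    for (int i = 0; i < d1; ++i)
                        out[base + (R_xlen_t)d0 * i] = buf[i];
                }
        } else {
            const R_xlen_t s2 = (R_xlen_t)d0 * d1;
            for (int i1 = 0; i1 < d1; ++i1)
                for (int i0 = 0; i0 < d0; ++i0) {
                    R_xlen_t base = i0 + (R_xlen_t)d0 * i1;
                    for (int i = 0; i < d2; ++i) line[i] = out[base + s2 * i];
                    gauss_axis(buf, w, r, line, d2);
                    for (int i = 0; i < d2; ++i) out[base + s2 * i] = buf[i];
                }
        }
    }
    (void)n;
    return out;
}

// ---- box (Chebyshev ball) dilation ---------------------------------------

// [[Rcpp::export]]
LogicalVector dilate_box_cpp(LogicalVector mask, IntegerVector dim,
                             IntegerVector radius) {
    const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
    LogicalVector cur = clone(mask);
    for (int ax = 0; ax < 3; ++ax) {
        int r = radius[ax];
        if (r <= 0) continue;
        LogicalVector nxt((R_xlen_t)d0 * d1 * d2, FALSE);
        int dn = (ax == 0) ? d0 : (ax == 1) ? d1 : d2;
        R_xlen_t stride = (ax == 0) ? 1 : (ax == 1) ? d0 : (R_xlen_t)d0 * d1;
        int n_lines0 = (ax == 0) ? d1 : d0;
        int n_lines1 = (ax == 2) ? d1 : d2;
        for (int b = 0; b < n_lines1; ++b)
            for (int a = 0; a < n_lines0; ++a) {
                R_xlen_t base;
                if (ax == 0)
                    base = (R_xlen_t)d0 * (a + (R_xlen_t)d1 * b);
                else if (ax == 1)
                    base = a + (R_xlen_t)d0 * d1 * b;
                else
                    base = a + (R_xlen_t)d0 * b;
                for (int i = 0; i < dn; ++i) {
                    bool any = false;
                    int lo = std::max(0, i - r), hi = std::min(dn - 1, i + r);
                    for (int j = lo; j <= hi && !any; ++j)
                        if (cur[base + stride * j]) any = true;
                    if (any) nxt[base + stride * i] = TRUE;
                }
            }
        cur = nxt;
    }
    return cur;
}
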