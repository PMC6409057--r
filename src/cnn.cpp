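// 3D CNN contour-position classifier: direct (loop-based) conv3d with 'same'
// zero padding, per-channel batch normalization over the spatial positions of
// the single-example batch, channelwise PReLU, 2x2x2 max pooling, fully
// connected layers with dropout, softmax cross-entropy with an L2 penalty,
// and SGD-with-momentum updates v <- zeta v - alpha grad - eta w; w <- w + v.
// Single-example batches throughout (batch size 1).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
using namespace Rcpp;

struct Geom {
  int nb;
  std::vector<std::array<int, 3>> bin;   // input dims per block
  std::vector<std::array<int, 3>> bconv; // dims after conv (= bin, same pad)
  std::vector<std::array<int, 3>> bout;  // dims after pooling
  std::vector<int> cin, cout;
  std::vector<int> pool;
  std::vector<int> fc; // sizes: flat, hidden..., 3
};

static Geom parse_geom(List g) {
  Geom G;
  List blocks = g["blocks"];
  G.nb = blocks.size();
  for (int b = 0; b < G.nb; ++b) {
    List bl = blocks[b];
    IntegerVector di = bl["in_dim"], dc = bl["conv_dim"], dp = bl["out_dim"];
    G.bin.push_back({di[0], di[1], di[2]});
    G.bconv.push_back({dc[0], dc[1], dc[2]});
    G.bout.push_back({dp[0], dp[1], dp[2]});
    G.cin.push_back(as<int>(bl["cin"]));
    G.cout.push_back(as<int>(bl["cout"]));
    G.pool.push_back(as<int>(bl["pool"]));
  }
  IntegerVector fc = g["fc"];
  G.fc.assign(fc.begin(), fc.end());
  return G;
}

static inline size_t vidx(int x, int y, int z, int c, int nx, int ny, int nz) {
  return (size_t)x + (size_t)nx * (y + (size_t)ny * (z + (size_t)nz * c));
}

// conv3d 'same', kernel 3x3x3, weight layout (3,3,3,cin,cout) column-major.
static void conv3d(const double* in, const double* w, const double* b,
                   double* out, int nx, int ny, int nz, int cin, int cout) {
  for (int m = 0; m < cout; ++m) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          double acc = b[m];
          for (int c = 0; c < cin; ++c) {
            const double* wc = w + 27 * ((size_t)c + (size_t)cin * m);
            for (int dz = -1; dz <= 1; ++dz) {
              int zz = z + dz;
              if (zz < 0 || zz >= nz) continue;
              for (int dy = -1; dy <= 1; ++dy) {
                int yy = y + dy;
                if (yy < 0 || yy >= ny) continue;
                const double* row = in + vidx(0, yy, zz, c, nx, ny, nz);
                for (int dx = -1; dx <= 1; ++dx) {
                  int xx = x + dx;
                  if (xx < 0 || xx >= nx) continue;
                  acc += wc[(dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1))] * row[xx];
                }
              }
            }
          }
          out[vidx(x, y, z, m, nx, ny, nz)] = acc;
        }
  }
}

// conv backward: accumulate dW, dB and (if dIn != null) dIn.
static void conv3d_back(const double* in, const double* w, const double* dout,
                        double* dW, double* dB, double* dIn,
                        int nx, int ny, int nz, int cin, int cout) {
  for (int m = 0; m < cout; ++m) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          double g = dout[vidx(x, y, z, m, nx, ny, nz)];
          if (g == 0.0) { continue; }
          dB[m] += g;
          for (int c = 0; c < cin; ++c) {
            const double* wc = w + 27 * ((size_t)c + (size_t)cin * m);
            double* dwc = dW + 27 * ((size_t)c + (size_t)cin * m);
            for (int dz = -1; dz <= 1; ++dz) {
              int zz = z + dz;
              if (zz < 0 || zz >= nz) continue;
              for (int dy = -1; dy <= 1; ++dy) {
                int yy = y + dy;
                if (yy < 0 || yy >= ny) continue;
                for (int dx = -1; dx <= 1; ++dx) {
                  int xx = x + dx;
                  if (xx < 0 || xx >= nx) continue;
                  int k = (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
                  size_t ii = vidx(xx, yy, zz, c, nx, ny, nz);
                  dwc[k] += in[ii] * g;
                  if (dIn) dIn[ii] += wc[k] * g;
                }
              }
            }
          }
        }
  }
}

struct BlockCache {
  std::vector<double> in;       // block input
  std::vector<double> xhat;     // normalized conv output
  std::vector<double> invstd;   // per channel
  std::vector<double> bmean, bvar;
  std::vector<double> act;      // PReLU output (pool input)
  std::vector<double> prein;    // BN output (PReLU input)
  std::vector<int> argmax;      // pool argmax (index into act), empty if no pool
  std::vector<double> out;      // block output
};

struct FcCache {
  std::vector<double> in;    // layer input (post-dropout of previous)
  std::vector<double> pre;   // pre-activation
  std::vector<double> act;   // post-activation (pre-dropout)
  std::vector<double> mask;  // dropout mask (scaled), empty if none
};

struct Net {
  Geom G;
  std::vector<double*> cw, cb, gam, bet, pa, rmean, rvar;
  std::vector<double*> fw, fb, fpa;
};

static Net bind_net(List params, List state, const Geom& G) {
  Net N;
  N.G = G;
  for (int b = 0; b < G.nb; ++b) {
    std::string s = std::to_string(b + 1);
    N.cw.push_back(REAL(as<NumericVector>(params["conv_w" + s])));
    N.cb.push_back(REAL(as<NumericVector>(params["conv_b" + s])));
    N.gam.push_back(REAL(as<NumericVector>(params["bn_gamma" + s])));
    N.bet.push_back(REAL(as<NumericVector>(params["bn_beta" + s])));
    N.pa.push_back(REAL(as<NumericVector>(params["prelu" + s])));
    N.rmean.push_back(REAL(as<NumericVector>(state["bn_mean" + s])));
    N.rvar.push_back(REAL(as<NumericVector>(state["bn_var" + s])));
  }
  int nfc = (int)G.fc.size() - 1;
  for (int l = 0; l < nfc; ++l) {
    std::string s = std::to_string(l + 1);
    N.fw.push_back(REAL(as<NumericVector>(params["fc_w" + s])));
    N.fb.push_back(REAL(as<NumericVector>(params["fc_b" + s])));
    if (l < nfc - 1) N.fpa.push_back(REAL(as<NumericVector>(params["fc_prelu" + s])));
  }
  return N;
}

// Forward pass. training: batch statistics + dropout (+ running-stat update);
// eval: running statistics, no dropout. Returns class probabilities.
static std::vector<double> net_forward(const Net& N, const double* x0,
                                       bool training, double keep,
                                       double bn_eps, double bn_decay,
                                       std::vector<BlockCache>* BC,
                                       std::vector<FcCache>* FC_) {
  const Geom& G = N.G;
  std::vector<double> cur(x0, x0 + (size_t)G.bin[0][0] * G.bin[0][1] * G.bin[0][2] * G.cin[0]);
  for (int b = 0; b < G.nb; ++b) {
    int nx = G.bconv[b][0], ny = G.bconv[b][1], nz = G.bconv[b][2];
    int cc = G.cout[b];
    size_t V = (size_t)nx * ny * nz;
    std::vector<double> conv(V * cc);
    conv3d(cur.data(), N.cw[b], N.cb[b], conv.data(), nx, ny, nz, G.cin[b], cc);
    // batch norm per channel
    std::vector<double> xhat(V * cc), invstd(cc), bmean(cc), bvar(cc);
    for (int m = 0; m < cc; ++m) {
      double* ch = conv.data() + V * m;
      double mu, var;
      if (training && V < 2) {
        // single spatial position: batch statistics are degenerate
        mu = N.rmean[b][m];
        var = N.rvar[b][m];
      } else if (training) {
        double s = 0, s2 = 0;
        for (size_t i = 0; i < V; ++i) { s += ch[i]; }
        mu = s / V;
        for (size_t i = 0; i < V; ++i) { double d = ch[i] - mu; s2 += d * d; }
        var = s2 / V;
        N.rmean[b][m] = bn_decay * N.rmean[b][m] + (1 - bn_decay) * mu;
        N.rvar[b][m] = bn_decay * N.rvar[b][m] + (1 - bn_decay) * var;
      } else {
        mu = N.rmean[b][m];
        var = N.rvar[b][m];
      }
      double is = 1.0 / std::sqrt(var + bn_eps);
      invstd[m] = is; bmean[m] = mu; bvar[m] = var;
      double g = N.gam[b][m], be = N.bet[b][m];
      for (size_t i = 0; i < V; ++i) {
        double xh = (ch[i] - mu) * is;
        xhat[V * m + i] = xh;
        ch[i] = g * xh + be;
      }
    }
    // PReLU (conv now holds BN output)
    std::vector<double> prein;
    if (BC) prein = conv;
    for (int m = 0; m < cc; ++m) {
      double a = N.pa[b][m];
      double* ch = conv.data() + V * m;
      for (size_t i = 0; i < V; ++i) if (ch[i] <= 0) ch[i] *= a;
    }
    // max pool
    std::vector<double> out;
    std::vector<int> argmax;
    if (G.pool[b]) {
      int ox = G.bout[b][0], oy = G.bout[b][1], oz = G.bout[b][2];
      size_t OV = (size_t)ox * oy * oz;
      out.assign(OV * cc, 0.0);
      argmax.assign(OV * cc, 0);
      for (int m = 0; m < cc; ++m)
        for (int z = 0; z < oz; ++z)
          for (int y = 0; y < oy; ++y)
            for (int x = 0; x < ox; ++x) {
              double best = -1e300; int bi = 0;
              for (int dz = 0; dz < 2; ++dz) {
                if (2 * z + dz >= nz) continue;
                for (int dy = 0; dy < 2; ++dy) {
                  if (2 * y + dy >= ny) continue;
                  for (int dx = 0; dx < 2; ++dx) {
                    if (2 * x + dx >= nx) continue;
                    size_t ii = vidx(2 * x + dx, 2 * y + dy, 2 * z + dz, m, nx, ny, nz);
                    if (conv[ii] > best) { best = conv[ii]; bi = (int)ii; }
                  }
                }
              }
              size_t oi = vidx(x, y, z, m, ox, oy, oz);
              out[oi] = best;
              argmax[oi] = bi;
            }
    } else {
      out = conv;
    }
    if (BC) {
      BlockCache& C = (*BC)[b];
      C.in = cur;
      C.xhat = std::move(xhat);
      C.invstd = invstd; C.bmean = bmean; C.bvar = bvar;
      C.prein = std::move(prein);
      C.act = conv; // PReLU output
      C.argmax = std::move(argmax);
      C.out = out;
    }
    cur = std::move(out);
  }
  // fully connected stack
  int nfc = (int)G.fc.size() - 1;
  for (int l = 0; l < nfc; ++l) {
    int ni = G.fc[l], no = G.fc[l + 1];
    std::vector<double> pre(no);
    const double* W = N.fw[l];
    for (int j = 0; j < no; ++j) {
      double acc = N.fb[l][j];
      const double* wj = W + (size_t)ni * j;
      for (int i = 0; i < ni; ++i) acc += wj[i] * cur[i];
      pre[j] = acc;
    }
    std::vector<double> act = pre;
    std::vector<double> mask;
    if (l < nfc - 1) {
      double a = N.fpa[l][0];
      for (int j = 0; j < no; ++j) if (act[j] <= 0) act[j] *= a;
      if (training && keep < 1.0) {
        mask.resize(no);
        for (int j = 0; j < no; ++j) {
          double u = R::unif_rand();
          mask[j] = (u < keep) ? 1.0 / keep : 0.0;
          act[j] *= mask[j];
        }
      }
    }
    if (FC_) {
      FcCache& C = (*FC_)[l];
      C.in = cur; C.pre = pre; C.act = act; C.mask = std::move(mask);
    }
    cur = std::move(act);
  }
  // softmax
  double mx = cur[0];
  for (double v : cur) if (v > mx) mx = v;
  double s = 0;
  for (double& v : cur) { v = std::exp(v - mx); s += v; }
  for (double& v : cur) v /= s;
  return cur;
}

struct GradBuf {
  std::vector<std::vector<double>> g; // aligned with flat param order
};

// Backward pass; fills gradient buffers (same order as flatten_params below).
static void net_backward(const Net& N, const std::vector<double>& probs,
                         int label, std::vector<BlockCache>& BC,
                         std::vector<FcCache>& FC_,
                         std::vector<std::vector<double>>& gcw,
                         std::vector<std::vector<double>>& gcb,
                         std::vector<std::vector<double>>& ggam,
                         std::vector<std::vector<double>>& gbet,
                         std::vector<std::vector<double>>& gpa,
                         std::vector<std::vector<double>>& gfw,
                         std::vector<std::vector<double>>& gfb,
                         std::vector<std::vector<double>>& gfpa) {
  const Geom& G = N.G;
  int nfc = (int)G.fc.size() - 1;
  std::vector<double> delta(probs);
  delta[label] -= 1.0; // dL/dlogits
  for (int l = nfc - 1; l >= 0; --l) {
    int ni = G.fc[l], no = G.fc[l + 1];
    FcCache& C = FC_[l];
    std::vector<double> dpre;
    if (l == nfc - 1) {
      dpre = delta;
    } else {
      // delta is grad wrt layer OUTPUT (post prelu+dropout)
      dpre.assign(no, 0.0);
      double a = N.fpa[l][0], da = 0.0;
      for (int j = 0; j < no; ++j) {
        double d = delta[j];
        if (!C.mask.empty()) d *= C.mask[j];
        if (C.pre[j] > 0) dpre[j] = d;
        else { dpre[j] = d * a; da += d * C.pre[j]; }
      }
      gfpa[l][0] += da;
    }
    double* gW = gfw[l].data();
    for (int j = 0; j < no; ++j) {
      double d = dpre[j];
      gfb[l][j] += d;
      double* gwj = gW + (size_t)ni * j;
      for (int i = 0; i < ni; ++i) gwj[i] += d * C.in[i];
    }
    std::vector<double> dnext(ni, 0.0);
    const double* W = N.fw[l];
    for (int j = 0; j < no; ++j) {
      double d = dpre[j];
      if (d == 0.0) continue;
      const double* wj = W + (size_t)ni * j;
      for (int i = 0; i < ni; ++i) dnext[i] += wj[i] * d;
    }
    delta = std::move(dnext);
  }
  // delta now wrt flattened output of last block
  for (int b = G.nb - 1; b >= 0; --b) {
    BlockCache& C = BC[b];
    int nx = G.bconv[b][0], ny = G.bconv[b][1], nz = G.bconv[b][2];
    int cc = G.cout[b];
    size_t V = (size_t)nx * ny * nz;
    std::vector<double> dact(V * cc, 0.0);
    if (G.pool[b]) {
      for (size_t oi = 0; oi < C.argmax.size(); ++oi)
        dact[C.argmax[oi]] += delta[oi];
    } else {
      dact = delta;
    }
    // PReLU backward
    std::vector<double> dbn(V * cc);
    for (int m = 0; m < cc; ++m) {
      double a = N.pa[b][m], da = 0.0;
      for (size_t i = 0; i < V; ++i) {
        size_t ii = V * m + i;
        double pi = C.prein[ii];
        if (pi > 0) dbn[ii] = dact[ii];
        else { dbn[ii] = dact[ii] * a; da += dact[ii] * pi; }
      }
      gpa[b][m] += da;
    }
    // BN backward (batch statistics of the single example)
    std::vector<double> dconv(V * cc);
    for (int m = 0; m < cc; ++m) {
      double g = N.gam[b][m], is = C.invstd[m];
      double sdy = 0, sdyx = 0;
      const double* xh = C.xhat.data() + V * m;
      const double* dy = dbn.data() + V * m;
      for (size_t i = 0; i < V; ++i) { sdy += dy[i]; sdyx += dy[i] * xh[i]; }
      ggam[b][m] += sdyx;
      gbet[b][m] += sdy;
      double* dc = dconv.data() + V * m;
      if (V < 2) {
        // running statistics were used in the forward pass
        dc[0] = g * is * dy[0];
      } else {
        double mdy = sdy / V, mdyx = sdyx / V;
        for (size_t i = 0; i < V; ++i)
          dc[i] = g * is * (dy[i] - mdy - xh[i] * mdyx);
      }
    }
    // conv backward
    std::vector<double> din;
    double* dinp = nullptr;
    if (b > 0) {
      din.assign(C.in.size(), 0.0);
      dinp = din.data();
    }
    conv3d_back(C.in.data(), N.cw[b], dconv.data(), gcw[b].data(),
                gcb[b].data(), dinp, nx, ny, nz, G.cin[b], cc);
    if (b > 0) delta = std::move(din);
  }
}

// [[Rcpp::export(name = ".cnn_forward_cpp")]]
NumericVector cnn_forward_cpp(NumericVector x, List params, List state,
                              List geom, bool training, double keep,
                              double bn_eps, double bn_decay) {
  Geom G = parse_geom(geom);
  Net N = bind_net(params, state, G);
  std::vector<double> p = net_forward(N, REAL(x), training, keep, bn_eps,
                                      bn_decay, nullptr, nullptr);
  return NumericVector(p.begin(), p.end());
}

// Full training loop: shuffled single-example steps, staircase learning-rate
// decay, SGD with momentum and decoupled L2 term (Eq-style v update), optional
// per-epoch held-out accuracy with early stop once `stop_acc` is reached.
// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(List examples, IntegerVector labels, List params, List state,
                   List geom, List cfg, List eval_examples,
                   IntegerVector eval_labels, double stop_acc) {
  Geom G = parse_geom(geom);
  // clone parameters/state so the input object is untouched
  List P = clone(params), S = clone(state);
  Net N = bind_net(P, S, G);
  double lr0 = as<double>(cfg["lr_init"]);
  double decay = as<double>(cfg["lr_decay"]);
  int decay_steps = as<int>(cfg["decay_steps"]);
  double zeta = as<double>(cfg["momentum"]);
  double eta = as<double>(cfg["weight_decay"]);
  double bn_eps = as<double>(cfg["bn_eps"]);
  double bn_decay = as<double>(cfg["bn_decay"]);
  double keep = as<double>(cfg["dropout_keep"]);
  int epochs = as<int>(cfg["epochs"]);
  int nex = examples.size();

  // flat parameter table: pointer, length, decay flag, grad/velocity buffers
  struct Slot { double* w; size_t n; bool decay; std::vector<double>* g; std::vector<double> v; };
  int nfc = (int)G.fc.size() - 1;
  std::vector<std::vector<double>> gcw(G.nb), gcb(G.nb), ggam(G.nb), gbet(G.nb),
      gpa(G.nb), gfw(nfc), gfb(nfc), gfpa(std::max(0, nfc - 1));
  std::vector<Slot> slots;
  for (int b = 0; b < G.nb; ++b) {
    size_t nw = 27ul * G.cin[b] * G.cout[b];
    gcw[b].assign(nw, 0.0); gcb[b].assign(G.cout[b], 0.0);
    ggam[b].assign(G.cout[b], 0.0); gbet[b].assign(G.cout[b], 0.0);
    gpa[b].assign(G.cout[b], 0.0);
    slots.push_back({N.cw[b], nw, true, &gcw[b], std::vector<double>(nw, 0.0)});
    slots.push_back({N.cb[b], (size_t)G.cout[b], false, &gcb[b], std::vector<double>(G.cout[b], 0.0)});
    slots.push_back({N.gam[b], (size_t)G.cout[b], false, &ggam[b], std::vector<double>(G.cout[b], 0.0)});
    slots.push_back({N.bet[b], (size_t)G.cout[b], false, &gbet[b], std::vector<double>(G.cout[b], 0.0)});
    slots.push_back({N.pa[b], (size_t)G.cout[b], false, &gpa[b], std::vector<double>(G.cout[b], 0.0)});
  }
  for (int l = 0; l < nfc; ++l) {
    size_t nw = (size_t)G.fc[l] * G.fc[l + 1];
    gfw[l].assign(nw, 0.0); gfb[l].assign(G.fc[l + 1], 0.0);
    slots.push_back({N.fw[l], nw, true, &gfw[l], std::vector<double>(nw, 0.0)});
    slots.push_back({N.fb[l], (size_t)G.fc[l + 1], false, &gfb[l], std::vector<double>(G.fc[l + 1], 0.0)});
    if (l < nfc - 1) {
      gfpa[l].assign(1, 0.0);
      slots.push_back({N.fpa[l], 1, false, &gfpa[l], std::vector<double>(1, 0.0)});
    }
  }

  std::vector<double> loss_hist;
  std::vector<double> acc_hist;
  int step = 0, epochs_run = 0;
  bool stopped = false, diverged = false;
  std::vector<BlockCache> BC(G.nb);
  std::vector<FcCache> FCC(nfc);

  for (int ep = 0; ep < epochs && !stopped && !diverged; ++ep) {
    // Fisher-Yates shuffle with R RNG
    std::vector<int> ord(nex);
    for (int i = 0; i < nex; ++i) ord[i] = i;
    for (int i = nex - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    for (int t = 0; t < nex; ++t) {
      NumericVector ex = examples[ord[t]];
      int lab = labels[ord[t]];
      std::vector<double> probs = net_forward(N, REAL(ex), true, keep, bn_eps,
                                              bn_decay, &BC, &FCC);
      double l2 = 0;
      for (auto& sl : slots)
        if (sl.decay) for (size_t i = 0; i < sl.n; ++i) l2 += sl.w[i] * sl.w[i];
      double loss = -std::log(std::max(probs[lab], 1e-300)) + 0.5 * eta * l2;
      loss_hist.push_back(loss);
      if (!std::isfinite(loss)) { diverged = true; break; }
      for (auto& sl : slots) std::fill(sl.g->begin(), sl.g->end(), 0.0);
      net_backward(N, probs, lab, BC, FCC, gcw, gcb, ggam, gbet, gpa, gfw, gfb, gfpa);
      double lr = lr0 * std::pow(decay, (double)(step / decay_steps));
      for (auto& sl : slots) {
        const std::vector<double>& g = *sl.g;
        for (size_t i = 0; i < sl.n; ++i) {
          double vi = zeta * sl.v[i] - lr * g[i] - (sl.decay ? eta * sl.w[i] : 0.0);
          sl.v[i] = vi;
          sl.w[i] += vi;
        }
      }
      ++step;
    }
    ++epochs_run;
    if (eval_examples.size() > 0 && !diverged) {
      int ok = 0;
      for (int t = 0; t < eval_examples.size(); ++t) {
        NumericVector ex = eval_examples[t];
        std::vector<double> p = net_forward(N, REAL(ex), false, 1.0, bn_eps,
                                            bn_decay, nullptr, nullptr);
        int am = 0;
        for (int m = 1; m < 3; ++m) if (p[m] > p[am]) am = m;
        if (am == eval_labels[t]) ++ok;
      }
      double acc = (double)ok / eval_examples.size();
      acc_hist.push_back(acc);
      if (stop_acc > 0 && acc >= stop_acc) stopped = true;
    }
  }
  return List::create(_["params"] = P, _["state"] = S,
                      _["loss_history"] = NumericVector(loss_hist.begin(), loss_hist.end()),
                      _["eval_accuracy"] = NumericVector(acc_hist.begin(), acc_hist.end()),
                      _["epochs_run"] = epochs_run, _["steps"] = step,
                      _["diverged"] = diverged);
}
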