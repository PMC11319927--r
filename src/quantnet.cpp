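// Shared-backbone multi-head residual regression network.
//
// Convolutions are im2col + GEMM; backprop is manual; the optimizer is Adam.
// All randomness (batch shuffling, flip augmentation) goes through R's RNG so
// training is deterministic under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

struct ConvSpec {
  int in, out, k, stride, pad, groups;
};

struct BlockSpec {
  bool bottleneck;
  int in, mid, out, stride, groups;
  bool proj;
  std::vector<int> convIds; // indices into the flat conv list
};

struct NetSpec {
  ConvSpec stem;
  std::vector<BlockSpec> blocks;
  std::vector<ConvSpec> convs; // flat, conv 0 = stem
  int nHeads, featDim;
};

static NetSpec parseSpec(const List& sp) {
  NetSpec ns;
  List stem = sp["stem"];
  ns.stem = ConvSpec{as<int>(stem["in"]), as<int>(stem["out"]),
                     as<int>(stem["k"]), as<int>(stem["stride"]),
                     as<int>(stem["pad"]), 1};
  ns.convs.push_back(ns.stem);
  List blocks = sp["blocks"];
  int cur = ns.stem.out;
  for (int b = 0; b < blocks.size(); ++b) {
    List bl = blocks[b];
    BlockSpec bs;
    std::string type = as<std::string>(bl["type"]);
    bs.bottleneck = (type == "bottleneck");
    bs.in = cur;
    bs.mid = as<int>(bl["mid"]);
    bs.out = as<int>(bl["out"]);
    bs.stride = as<int>(bl["stride"]);
    bs.groups = as<int>(bl["groups"]);
    bs.proj = (bs.in != bs.out) || (bs.stride != 1);
    if (bs.bottleneck) {
      bs.convIds.push_back((int)ns.convs.size());
      ns.convs.push_back(ConvSpec{bs.in, bs.mid, 1, 1, 0, 1});
      bs.convIds.push_back((int)ns.convs.size());
      ns.convs.push_back(ConvSpec{bs.mid, bs.mid, 3, bs.stride, 1, bs.groups});
      bs.convIds.push_back((int)ns.convs.size());
      ns.convs.push_back(ConvSpec{bs.mid, bs.out, 1, 1, 0, 1});
    } else {
      bs.convIds.push_back((int)ns.convs.size());
      ns.convs.push_back(ConvSpec{bs.in, bs.out, 3, bs.stride, 1, 1});
      bs.convIds.push_back((int)ns.convs.size());
      ns.convs.push_back(ConvSpec{bs.out, bs.out, 3, 1, 1, 1});
    }
    if (bs.proj) {
      bs.convIds.push_back((int)ns.convs.size());
      ns.convs.push_back(ConvSpec{bs.in, bs.out, 1, bs.stride, 0, 1});
    }
    cur = bs.out;
    ns.blocks.push_back(bs);
  }
  ns.featDim = cur;
  ns.nHeads = as<int>(sp["nHeads"]);
  return ns;
}

static mat im2col(const cube& x, int k, int s, int p, int c0, int cg,
                  int Ho, int Wo) {
  int H = x.n_rows, W = x.n_cols;
  mat col(k * k * cg, Ho * Wo, fill::zeros);
  for (int c = 0; c < cg; ++c)
    for (int ki = 0; ki < k; ++ki)
      for (int kj = 0; kj < k; ++kj) {
        int r = c * k * k + ki * k + kj;
        for (int oj = 0; oj < Wo; ++oj) {
          int jj = oj * s - p + kj;
          if (jj < 0 || jj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            int ii = oi * s - p + ki;
            if (ii < 0 || ii >= H) continue;
            col(r, oj * Ho + oi) = x(ii, jj, c0 + c);
          }
        }
      }
  return col;
}

static void col2imAdd(const mat& dcol, cube& dX, int k, int s, int p,
                      int c0, int cg, int Ho, int Wo) {
  int H = dX.n_rows, W = dX.n_cols;
  for (int c = 0; c < cg; ++c)
    for (int ki = 0; ki < k; ++ki)
      for (int kj = 0; kj < k; ++kj) {
        int r = c * k * k + ki * k + kj;
        for (int oj = 0; oj < Wo; ++oj) {
          int jj = oj * s - p + kj;
          if (jj < 0 || jj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            int ii = oi * s - p + ki;
            if (ii < 0 || ii >= H) continue;
            dX(ii, jj, c0 + c) += dcol(r, oj * Ho + oi);
          }
        }
      }
}

static cube convF(const cube& x, const mat& W, const vec& b,
                  const ConvSpec& cs, std::vector<mat>* cache) {
  int H = x.n_rows, Wd = x.n_cols;
  int Ho = (H + 2 * cs.pad - cs.k) / cs.stride + 1;
  int Wo = (Wd + 2 * cs.pad - cs.k) / cs.stride + 1;
  if (Ho < 1 || Wo < 1) stop("input spatial size too small for this backbone");
  int cg = cs.in / cs.groups, og = cs.out / cs.groups;
  cube y(Ho, Wo, cs.out);
  if (cache) cache->resize(cs.groups);
  for (int g = 0; g < cs.groups; ++g) {
    mat col = im2col(x, cs.k, cs.stride, cs.pad, g * cg, cg, Ho, Wo);
    mat Yg = W.rows(g * og, (g + 1) * og - 1) * col;
    Yg.each_col() += b.subvec(g * og, (g + 1) * og - 1);
    for (int c = 0; c < og; ++c)
      y.slice(g * og + c) = reshape(Yg.row(c).t(), Ho, Wo);
    if (cache) (*cache)[g] = std::move(col);
  }
  return y;
}

static cube convB(const cube& dY, const std::vector<mat>& cache, const mat& W,
                  const ConvSpec& cs, int Hin, int Win,
                  mat& dW, vec& db) {
  int Ho = dY.n_rows, Wo = dY.n_cols;
  int cg = cs.in / cs.groups, og = cs.out / cs.groups;
  cube dX(Hin, Win, cs.in, fill::zeros);
  for (int g = 0; g < cs.groups; ++g) {
    mat dYg(og, Ho * Wo);
    for (int c = 0; c < og; ++c)
      dYg.row(c) = vectorise(dY.slice(g * og + c)).t();
    dW.rows(g * og, (g + 1) * og - 1) += dYg * cache[g].t();
    db.subvec(g * og, (g + 1) * og - 1) += sum(dYg, 1);
    mat dcol = W.rows(g * og, (g + 1) * og - 1).t() * dYg;
    col2imAdd(dcol, dX, cs.k, cs.stride, cs.pad, g * cg, cg, Ho, Wo);
  }
  return dX;
}

struct Params {
  std::vector<mat> W; // one per conv, + heads at the end
  std::vector<vec> b;
  mat headW;          // nHeads x featDim
  vec headB;
};

static Params paramsFromR(const List& pl, const NetSpec& ns) {
  Params p;
  int nc = (int)ns.convs.size();
  if (pl.size() != nc + 1)
    stop("parameter list has %d entries, expected %d", (int)pl.size(), nc + 1);
  for (int i = 0; i < nc; ++i) {
    List li = pl[i];
    p.W.push_back(as<mat>(li["W"]));
    p.b.push_back(as<vec>(li["b"]));
  }
  List lh = pl[nc];
  p.headW = as<mat>(lh["W"]);
  p.headB = as<vec>(lh["b"]);
  if ((int)p.headW.n_rows != ns.nHeads || (int)p.headW.n_cols != ns.featDim)
    stop("head weight shape mismatch");
  return p;
}

static List paramsToR(const Params& p) {
  List out(p.W.size() + 1);
  for (size_t i = 0; i < p.W.size(); ++i)
    out[i] = List::create(_["W"] = p.W[i], _["b"] = p.b[i]);
  out[p.W.size()] = List::create(_["W"] = p.headW, _["b"] = p.headB);
  return out;
}

struct FwdCache {
  std::vector<std::vector<mat>> cols; // per conv
  cube stemOut;
  std::vector<cube> blkIn, blkA1, blkA2, blkOut;
  vec feat;
};

// Forward one sample; fills caches when `cache` is non-null.
static vec forwardSample(const cube& x, const Params& p, const NetSpec& ns,
                         FwdCache* cache) {
  std::vector<std::vector<mat>> localCols;
  std::vector<std::vector<mat>>& cols = cache ? cache->cols : localCols;
  cols.resize(ns.convs.size());
  cube cur = convF(x, p.W[0], p.b[0], ns.convs[0], cache ? &cols[0] : nullptr);
  cur.transform([](double v) { return v > 0 ? v : 0.0; });
  if (cache) cache->stemOut = cur;
  for (size_t bI = 0; bI < ns.blocks.size(); ++bI) {
    const BlockSpec& bs = ns.blocks[bI];
    if (cache) cache->blkIn.push_back(cur);
    cube a1 = convF(cur, p.W[bs.convIds[0]], p.b[bs.convIds[0]],
                    ns.convs[bs.convIds[0]],
                    cache ? &cols[bs.convIds[0]] : nullptr);
    a1.transform([](double v) { return v > 0 ? v : 0.0; });
    cube pre;
    if (bs.bottleneck) {
      cube a2 = convF(a1, p.W[bs.convIds[1]], p.b[bs.convIds[1]],
                      ns.convs[bs.convIds[1]],
                      cache ? &cols[bs.convIds[1]] : nullptr);
      a2.transform([](double v) { return v > 0 ? v : 0.0; });
      pre = convF(a2, p.W[bs.convIds[2]], p.b[bs.convIds[2]],
                  ns.convs[bs.convIds[2]],
                  cache ? &cols[bs.convIds[2]] : nullptr);
      if (cache) { cache->blkA1.push_back(a1); cache->blkA2.push_back(a2); }
    } else {
      pre = convF(a1, p.W[bs.convIds[1]], p.b[bs.convIds[1]],
                  ns.convs[bs.convIds[1]],
                  cache ? &cols[bs.convIds[1]] : nullptr);
      if (cache) { cache->blkA1.push_back(a1); cache->blkA2.push_back(cube()); }
    }
    if (bs.proj) {
      int pc = bs.convIds.back();
      cube sc = convF(cur, p.W[pc], p.b[pc], ns.convs[pc],
                      cache ? &cols[pc] : nullptr);
      pre += sc;
    } else {
      pre += cur;
    }
    pre.transform([](double v) { return v > 0 ? v : 0.0; });
    if (cache) cache->blkOut.push_back(pre);
    cur = pre;
  }
  vec feat(ns.featDim);
  double hw = (double)(cur.n_rows * cur.n_cols);
  for (int c = 0; c < ns.featDim; ++c) feat(c) = accu(cur.slice(c)) / hw;
  if (cache) cache->feat = feat;
  return p.headW * feat + p.headB;
}

// Backward one sample given d(loss)/d(pred); accumulates into grads g.
static void backwardSample(const cube& x, const Params& p, const NetSpec& ns,
                           const FwdCache& c, const vec& dpred, Params& g) {
  g.headW += dpred * c.feat.t();
  g.headB += dpred;
  vec dfeat = p.headW.t() * dpred;
  const cube& last = c.blkOut.empty() ? c.stemOut : c.blkOut.back();
  double hw = (double)(last.n_rows * last.n_cols);
  cube dcur(last.n_rows, last.n_cols, last.n_slices);
  for (int ch = 0; ch < (int)last.n_slices; ++ch)
    dcur.slice(ch).fill(dfeat(ch) / hw);
  for (int bI = (int)ns.blocks.size() - 1; bI >= 0; --bI) {
    const BlockSpec& bs = ns.blocks[bI];
    const cube& out = c.blkOut[bI];
    const cube& in = c.blkIn[bI];
    cube dpre = dcur;
    for (uword i = 0; i < out.n_elem; ++i) if (out(i) <= 0) dpre(i) = 0;
    cube dIn;
    if (bs.proj) {
      int pc = bs.convIds.back();
      dIn = convB(dpre, c.cols[pc], p.W[pc], ns.convs[pc],
                  in.n_rows, in.n_cols, g.W[pc], g.b[pc]);
    } else {
      dIn = dpre;
    }
    if (bs.bottleneck) {
      const cube& a2 = c.blkA2[bI];
      cube dA2 = convB(dpre, c.cols[bs.convIds[2]], p.W[bs.convIds[2]],
                       ns.convs[bs.convIds[2]], a2.n_rows, a2.n_cols,
                       g.W[bs.convIds[2]], g.b[bs.convIds[2]]);
      for (uword i = 0; i < a2.n_elem; ++i) if (a2(i) <= 0) dA2(i) = 0;
      const cube& a1 = c.blkA1[bI];
      cube dA1 = convB(dA2, c.cols[bs.convIds[1]], p.W[bs.convIds[1]],
                       ns.convs[bs.convIds[1]], a1.n_rows, a1.n_cols,
                       g.W[bs.convIds[1]], g.b[bs.convIds[1]]);
      for (uword i = 0; i < a1.n_elem; ++i) if (a1(i) <= 0) dA1(i) = 0;
      dIn += convB(dA1, c.cols[bs.convIds[0]], p.W[bs.convIds[0]],
                   ns.convs[bs.convIds[0]], in.n_rows, in.n_cols,
                   g.W[bs.convIds[0]], g.b[bs.convIds[0]]);
    } else {
      const cube& a1 = c.blkA1[bI];
      cube dA1 = convB(dpre, c.cols[bs.convIds[1]], p.W[bs.convIds[1]],
                       ns.convs[bs.convIds[1]], a1.n_rows, a1.n_cols,
                       g.W[bs.convIds[1]], g.b[bs.convIds[1]]);
      for (uword i = 0; i < a1.n_elem; ++i) if (a1(i) <= 0) dA1(i) = 0;
      dIn += convB(dA1, c.cols[bs.convIds[0]], p.W[bs.convIds[0]],
                   ns.convs[bs.convIds[0]], in.n_rows, in.n_cols,
                   g.W[bs.convIds[0]], g.b[bs.convIds[0]]);
    }
    dcur = dIn;
  }
  const cube& so = c.stemOut;
  cube dstem = dcur;
  for (uword i = 0; i < so.n_elem; ++i) if (so(i) <= 0) dstem(i) = 0;
  convB(dstem, c.cols[0], p.W[0], ns.convs[0], x.n_rows, x.n_cols,
        g.W[0], g.b[0]);
}

static Params zerosLike(const Params& p) {
  Params z;
  for (size_t i = 0; i < p.W.size(); ++i) {
    z.W.push_back(mat(p.W[i].n_rows, p.W[i].n_cols, fill::zeros));
    z.b.push_back(vec(p.b[i].n_elem, fill::zeros));
  }
  z.headW = mat(p.headW.n_rows, p.headW.n_cols, fill::zeros);
  z.headB = vec(p.headB.n_elem, fill::zeros);
  return z;
}

static cube sampleCube(const cube& X, int i, bool flip) {
  cube x(X.n_rows, X.n_cols, 1);
  x.slice(0) = X.slice(i);
  if (flip) x.slice(0) = fliplr(x.slice(0));
  return x;
}

static double evalMSE(const Params& p, const NetSpec& ns, const cube& X,
                      const mat& Y) {
  double tot = 0;
  int N = X.n_slices;
  for (int i = 0; i < N; ++i) {
    cube x = sampleCube(X, i, false);
    vec pred = forwardSample(x, p, ns, nullptr);
    vec d = pred - Y.col(i);
    tot += dot(d, d) / ns.nHeads;
  }
  return tot / N;
}

// [[Rcpp::export]]
List cpp_train(List paramsR, List specR,
               const arma::cube& trX, const arma::mat& trY,
               const arma::cube& vaX, const arma::mat& vaY,
               double lr, int batchSize, int epochs, bool flip,
               double beta1 = 0.9, double beta2 = 0.999,
               double adamEps = 1e-8) {
  NetSpec ns = parseSpec(specR);
  Params p = paramsFromR(paramsR, ns);
  Params m = zerosLike(p), v = zerosLike(p);
  int N = trX.n_slices;
  if ((int)trY.n_cols != N) stop("label/image count mismatch");
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  NumericVector trainHist(epochs), valHist(epochs);
  long tAdam = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle through R's RNG
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double epLoss = 0;
    for (int start = 0; start < N; start += batchSize) {
      int nb = std::min(batchSize, N - start);
      Params g = zerosLike(p);
      for (int bi = 0; bi < nb; ++bi) {
        int i = idx[start + bi];
        bool doFlip = flip && (unif_rand() < 0.5);
        cube x = sampleCube(trX, i, doFlip);
        FwdCache cache;
        vec pred = forwardSample(x, p, ns, &cache);
        vec d = pred - trY.col(i);
        double loss = dot(d, d) / ns.nHeads;
        if (!std::isfinite(loss))
          stop("non-finite training loss at epoch %d", ep + 1);
        epLoss += loss;
        vec dpred = (2.0 / ns.nHeads / nb) * d;
        backwardSample(x, p, ns, cache, dpred, g);
      }
      // Adam step
      ++tAdam;
      double bc1 = 1 - std::pow(beta1, (double)tAdam);
      double bc2 = 1 - std::pow(beta2, (double)tAdam);
      auto upd = [&](mat& w, mat& mw, mat& vw, const mat& gw) {
        mw = beta1 * mw + (1 - beta1) * gw;
        vw = beta2 * vw + (1 - beta2) * square(gw);
        w -= lr * (mw / bc1) / (sqrt(vw / bc2) + adamEps);
      };
      auto updv = [&](vec& w, vec& mw, vec& vw, const vec& gw) {
        mw = beta1 * mw + (1 - beta1) * gw;
        vw = beta2 * vw + (1 - beta2) * square(gw);
        w -= lr * (mw / bc1) / (sqrt(vw / bc2) + adamEps);
      };
      for (size_t i = 0; i < p.W.size(); ++i) {
        upd(p.W[i], m.W[i], v.W[i], g.W[i]);
        updv(p.b[i], m.b[i], v.b[i], g.b[i]);
      }
      upd(p.headW, m.headW, v.headW, g.headW);
      updv(p.headB, m.headB, v.headB, g.headB);
    }
    trainHist[ep] = epLoss / N;
    valHist[ep] = vaX.n_slices > 0 ? evalMSE(p, ns, vaX, vaY) : NA_REAL;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = paramsToR(p),
                      _["trainMSE"] = trainHist,
                      _["valMSE"] = valHist);
}

// [[Rcpp::export]]
arma::mat cpp_predict(List paramsR, List specR, const arma::cube& X) {
  NetSpec ns = parseSpec(specR);
  Params p = paramsFromR(paramsR, ns);
  int N = X.n_slices;
  mat out(ns.nHeads, N);
  for (int i = 0; i < N; ++i) {
    cube x = sampleCube(X, i, false);
    out.col(i) = forwardSample(x, p, ns, nullptr);
  }
  return out;
}

// Final convolutional feature map and pooled feature vector for one image
// (used by Grad-CAM).
// [[Rcpp::export]]
List cpp_features(List paramsR, List specR, const arma::mat& img) {
  NetSpec ns = parseSpec(specR);
  Params p = paramsFromR(paramsR, ns);
  cube x(img.n_rows, img.n_cols, 1);
  x.slice(0) = img;
  FwdCache cache;
  vec pred = forwardSample(x, p, ns, &cache);
  const cube& last = cache.blkOut.empty() ? cache.stemOut : cache.blkOut.back();
  return List::create(_["feat"] = cache.feat, _["lastConv"] = last,
                      _["pred"] = pred);
}

// Pooled (GAP) trunk features for a stack of images: featDim x N.
// [[Rcpp::export]]
arma::mat cpp_trunk_features(List paramsR, List specR, const arma::cube& X) {
  NetSpec ns = parseSpec(specR);
  Params p = paramsFromR(paramsR, ns);
  int N = X.n_slices;
  mat out(ns.featDim, N);
  for (int i = 0; i < N; ++i) {
    cube x = sampleCube(X, i, false);
    FwdCache cache;
    forwardSample(x, p, ns, &cache);
    out.col(i) = cache.feat;
  }
  return out;
}
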