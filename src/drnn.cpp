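// Batched forward/backward kernel for the stacked (bi)directional LSTM
// classifier. Parameter vector layout (must match param_shapes() on the R
// side): for each layer l = 1..L, for direction f (then b when
// bidirectional): Wx (in_l x 4H), Wh (H x 4H), b (4H); then Wout (top x C),
// bout (C). Gate order within the 4H axis is [i | f | g | o].
//
// Templated over the element type: double for exact agreement with the
// plain-R reference implementation, float for fast training.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

namespace {

struct Arch {
  int L, H, C, in_dim, act_g;  // act_g: 0 tanh, 1 sigmoid
  bool bidir, late_sum;
};

Arch parse_arch(const List& a) {
  Arch s;
  s.L = Rcpp::as<int>(a["num_layers"]);
  s.H = Rcpp::as<int>(a["hidden"]);
  s.C = Rcpp::as<int>(a["num_classes"]);
  s.in_dim = Rcpp::as<int>(a["input_dim"]);
  s.bidir = Rcpp::as<bool>(a["bidirectional"]);
  std::string fusion = Rcpp::as<std::string>(a["fusion"]);
  s.late_sum = (fusion == "late_sum");
  std::string g = Rcpp::as<std::string>(a["act_g"]);
  s.act_g = (g == "sigmoid") ? 1 : 0;
  return s;
}

inline int layer_in(const Arch& a, int l) {  // l is 0-based
  return l == 0 ? a.in_dim : (a.bidir ? 2 * a.H : a.H);
}

template <typename eT>
inline Mat<eT> sigm(const Mat<eT>& z) {
  return eT(1) / (eT(1) + exp(-z));
}

// sequential read of parameter blocks from a flat vector
template <typename eT>
struct ParamCursor {
  const Col<eT>& v;
  uword pos = 0;
  Mat<eT> next(int r, int c) {
    if (pos + uword(r) * c > v.n_elem) Rcpp::stop("parameter vector too short");
    Mat<eT> m(v.memptr() + pos, r, c);
    pos += uword(r) * c;
    return m;
  }
};

template <typename eT>
struct CellActs {  // stored activations of one direction of one layer
  Cube<eT> G;   // 4H x B x T gate activations [i|f|g|o], input-order slices
  Cube<eT> C;   // H x B x T internal state
  Cube<eT> Hh;  // H x B x T hidden state
};

// run one direction of one layer over the whole chunk
template <typename eT>
void lstm_forward(const Mat<eT>& Wx, const Mat<eT>& Wh, const Mat<eT>& b,
                  const Cube<eT>& X, bool backward, int act_g, int H,
                  CellActs<eT>& acts) {
  const int B = X.n_cols, T = X.n_slices, in = X.n_rows;
  acts.G.set_size(4 * H, B, T);
  acts.C.set_size(H, B, T);
  acts.Hh.set_size(H, B, T);
  // input projection for all steps at once
  const Mat<eT> Xm(const_cast<eT*>(X.memptr()), in, uword(B) * T, false, true);
  Mat<eT> Ain = Wx.t() * Xm;  // 4H x B*T
  Col<eT> bv = vectorise(b);
  Mat<eT> h(H, B, fill::zeros), c(H, B, fill::zeros);
  Mat<eT> A(4 * H, B);
  for (int s = 0; s < T; ++s) {
    const int t = backward ? (T - 1 - s) : s;
    A = Ain.cols(uword(t) * B, uword(t) * B + B - 1) + Wh.t() * h;
    A.each_col() += bv;
    // gate activations in place: [i | f | o] sigmoid, g tanh (or sigmoid)
    eT* a = A.memptr();
    const uword n4 = A.n_elem;
    if (act_g) {
      for (uword k = 0; k < n4; ++k) a[k] = eT(1) / (eT(1) + std::exp(-a[k]));
    } else {
      for (uword j = 0; j < uword(B); ++j) {
        eT* col = a + j * 4 * H;
        for (int k = 0; k < 2 * H; ++k)
          col[k] = eT(1) / (eT(1) + std::exp(-col[k]));
        for (int k = 2 * H; k < 3 * H; ++k) col[k] = std::tanh(col[k]);
        for (int k = 3 * H; k < 4 * H; ++k)
          col[k] = eT(1) / (eT(1) + std::exp(-col[k]));
      }
    }
    c = A.rows(H, 2 * H - 1) % c + A.rows(2 * H, 3 * H - 1) % A.rows(0, H - 1);
    h = tanh(c) % A.rows(3 * H, 4 * H - 1);
    acts.G.slice(t) = A;
    acts.C.slice(t) = c;
    acts.Hh.slice(t) = h;
  }
}

// backpropagate one direction of one layer; accumulates parameter grads and
// adds the input gradient into dX
template <typename eT>
void lstm_backward(const Mat<eT>& Wx, const Mat<eT>& Wh,
                   const Cube<eT>& X, const CellActs<eT>& acts,
                   const Cube<eT>& dH_ext, bool backward, int act_g, int H,
                   Mat<eT>& dWx, Mat<eT>& dWh, Mat<eT>& db, Cube<eT>& dX) {
  const int B = X.n_cols, T = X.n_slices, in = X.n_rows;
  Cube<eT> DA(4 * H, B, T);
  Mat<eT> dh_rec(H, B, fill::zeros), dc_rec(H, B, fill::zeros);
  const Mat<eT> zero(H, B, fill::zeros);
  Mat<eT> tc(H, B), dh(H, B), dc(H, B);
  for (int s = T - 1; s >= 0; --s) {
    const int t = backward ? (T - 1 - s) : s;     // this step (input order)
    const int tp = backward ? (T - s) : (s - 1);  // previously processed step
    const bool has_prev = s > 0;
    const auto gi = acts.G.slice(t).rows(0, H - 1);
    const auto gf = acts.G.slice(t).rows(H, 2 * H - 1);
    const auto gg = acts.G.slice(t).rows(2 * H, 3 * H - 1);
    const auto go = acts.G.slice(t).rows(3 * H, 4 * H - 1);
    tc = tanh(acts.C.slice(t));
    dh = dH_ext.slice(t) + dh_rec;
    dc = dc_rec + dh % go % (eT(1) - tc % tc);
    const Mat<eT>& c_prev = has_prev ? acts.C.slice(tp) : zero;
    Mat<eT>& DAs = DA.slice(t);
    DAs.rows(0, H - 1) = (dc % gg) % gi % (eT(1) - gi);
    DAs.rows(H, 2 * H - 1) = (dc % c_prev) % gf % (eT(1) - gf);
    if (act_g)
      DAs.rows(2 * H, 3 * H - 1) = (dc % gi) % gg % (eT(1) - gg);
    else
      DAs.rows(2 * H, 3 * H - 1) = (dc % gi) % (eT(1) - gg % gg);
    DAs.rows(3 * H, 4 * H - 1) = (dh % tc) % go % (eT(1) - go);
    const Mat<eT>& h_prev = has_prev ? acts.Hh.slice(tp) : zero;
    dWh += h_prev * DA.slice(t).t();
    db += sum(DA.slice(t), 1);
    dh_rec = Wh * DA.slice(t);
    dc_rec = dc % gf;
  }
  const Mat<eT> Xm(const_cast<eT*>(X.memptr()), in, uword(B) * T, false, true);
  const Mat<eT> DAm(const_cast<eT*>(DA.memptr()), 4 * H, uword(B) * T, false,
                    true);
  dWx += Xm * DAm.t();
  Mat<eT> dXm(dX.memptr(), in, uword(B) * T, false, true);
  dXm += Wx * DAm;
}

template <typename eT>
List drnn_batch_impl(const Col<eT>& theta, const Arch& a, const Mat<eT>& X,
                     const Rcpp::IntegerVector& y0, bool want_grad,
                     const Mat<eT>& drop_mask, double keep_prob) {
  const int T = X.n_rows, B = X.n_cols, H = a.H;
  if (T < 1 || B < 1) Rcpp::stop("empty input");
  const int ndir = a.bidir ? 2 : 1;
  const int top = a.bidir ? 2 * H : H;
  const eT kp = eT(keep_prob);

  ParamCursor<eT> cur{theta};
  std::vector<std::vector<Mat<eT>>> Wx(a.L), Wh(a.L), bb(a.L);
  for (int l = 0; l < a.L; ++l)
    for (int d = 0; d < ndir; ++d) {
      Wx[l].push_back(cur.next(layer_in(a, l), 4 * H));
      Wh[l].push_back(cur.next(H, 4 * H));
      bb[l].push_back(cur.next(4 * H, 1));
    }
  Mat<eT> Wout = cur.next(top, a.C);
  Mat<eT> bout = cur.next(a.C, 1);
  if (cur.pos != theta.n_elem) Rcpp::stop("parameter vector has trailing elements");

  // ---- forward through the stack ----
  std::vector<Cube<eT>> layer_in_x(a.L + 1);  // input per layer (+ top repr)
  layer_in_x[0].set_size(1, B, T);
  for (int t = 0; t < T; ++t) layer_in_x[0].slice(t) = X.row(t);
  std::vector<std::vector<CellActs<eT>>> acts(
      a.L, std::vector<CellActs<eT>>(ndir));
  for (int l = 0; l < a.L; ++l) {
    for (int d = 0; d < ndir; ++d)
      lstm_forward<eT>(Wx[l][d], Wh[l][d], bb[l][d], layer_in_x[l], d == 1,
                       a.act_g, H, acts[l][d]);
    Cube<eT>& nx = layer_in_x[l + 1];
    nx.set_size(a.bidir ? 2 * H : H, B, T);
    for (int t = 0; t < T; ++t) {
      nx.slice(t).rows(0, H - 1) = acts[l][0].Hh.slice(t);
      if (a.bidir) nx.slice(t).rows(H, 2 * H - 1) = acts[l][1].Hh.slice(t);
    }
  }
  Cube<eT>& Htop = layer_in_x[a.L];
  const bool dropout = keep_prob < 1.0 && drop_mask.n_elem > 0;
  if (dropout) {
    for (int t = 0; t < T; ++t)
      Htop.slice(t) = (Htop.slice(t) % drop_mask) / kp;
  }

  // fused window scores
  Mat<eT> Y(a.C, B);
  Mat<eT> Hmean;
  if (a.late_sum) {
    Hmean = Mat<eT>(top, B, fill::zeros);
    for (int t = 0; t < T; ++t) Hmean += Htop.slice(t);
    Hmean /= eT(T);
    Y = Wout.t() * Hmean;
  } else {
    Y = Wout.t() * Htop.slice(T - 1);
  }
  Y.each_col() += vectorise(bout);

  if (y0.size() == 0)
    return List::create(Named("scores") = conv_to<mat>::from(Y));

  // softmax + mean cross-entropy
  Mat<eT> P = Y;
  P.each_row() -= max(P, 0);
  P = exp(P);
  P.each_row() /= sum(P, 0);
  double loss = 0.0;
  for (int j = 0; j < B; ++j)
    loss -= std::log(std::max(double(P(y0[j], j)), 1e-300));
  loss /= B;

  if (!want_grad)
    return List::create(Named("loss") = loss,
                        Named("scores") = conv_to<mat>::from(Y));

  // ---- backward ----
  std::vector<std::vector<Mat<eT>>> dWx(a.L), dWh(a.L), dbb(a.L);
  for (int l = 0; l < a.L; ++l)
    for (int d = 0; d < ndir; ++d) {
      dWx[l].push_back(Mat<eT>(layer_in(a, l), 4 * H, fill::zeros));
      dWh[l].push_back(Mat<eT>(H, 4 * H, fill::zeros));
      dbb[l].push_back(Mat<eT>(4 * H, 1, fill::zeros));
    }
  Mat<eT> dWout(top, a.C, fill::zeros);
  Mat<eT> dbout(a.C, 1, fill::zeros);

  Mat<eT> dY = P;
  for (int j = 0; j < B; ++j) dY(y0[j], j) -= eT(1);
  dY /= eT(B);

  Cube<eT> dHtop(top, B, T);
  if (a.late_sum) {
    dWout += Hmean * dY.t();
    Mat<eT> dh_const = (Wout * dY) / eT(T);
    for (int t = 0; t < T; ++t) dHtop.slice(t) = dh_const;
  } else {
    dHtop.zeros();
    dWout += Htop.slice(T - 1) * dY.t();
    dHtop.slice(T - 1) = Wout * dY;
  }
  dbout += sum(dY, 1);
  if (dropout) {
    for (int t = 0; t < T; ++t)
      dHtop.slice(t) = (dHtop.slice(t) % drop_mask) / kp;
  }

  Cube<eT> dcur = dHtop;
  for (int l = a.L - 1; l >= 0; --l) {
    Cube<eT> dlower(layer_in(a, l), B, T, fill::zeros);
    for (int d = 0; d < ndir; ++d) {
      Cube<eT> dH_dir(H, B, T);
      for (int t = 0; t < T; ++t)
        dH_dir.slice(t) = d == 0 ? dcur.slice(t).rows(0, H - 1)
                                 : dcur.slice(t).rows(H, 2 * H - 1);
      lstm_backward<eT>(Wx[l][d], Wh[l][d], layer_in_x[l], acts[l][d], dH_dir,
                       d == 1, a.act_g, H, dWx[l][d], dWh[l][d], dbb[l][d],
                       dlower);
    }
    dcur = dlower;
  }

  // serialize the gradient in the parameter layout order
  Rcpp::NumericVector grad(theta.n_elem);
  uword pos = 0;
  auto emit = [&](const Mat<eT>& m) {
    for (uword k = 0; k < m.n_elem; ++k) grad[pos + k] = double(m.memptr()[k]);
    pos += m.n_elem;
  };
  for (int l = 0; l < a.L; ++l)
    for (int d = 0; d < ndir; ++d) {
      emit(dWx[l][d]); emit(dWh[l][d]); emit(dbb[l][d]);
    }
  emit(dWout); emit(dbout);

  return List::create(Named("loss") = loss,
                      Named("scores") = conv_to<mat>::from(Y),
                      Named("grad") = grad);
}

}  // namespace

// Forward pass (and, when labels are given, cross-entropy loss and full
// gradient) over a chunk of equal-length windows.
//   X: T x B matrix, one scalar-sample window per column
//   y0: 0-based class labels (length B), or empty for scores only
//   drop_mask: top_dim x B 0/1 matrix (empty for no dropout), applied to the
//              top-layer representation with inverted scaling by keep_prob
//   single_prec: compute in float (fast training path) instead of double
// [[Rcpp::export]]
List cpp_drnn_batch(const arma::vec& theta, List arch_spec,
                    const arma::mat& X, Rcpp::IntegerVector y0,
                    bool want_grad, const arma::mat& drop_mask,
                    double keep_prob, bool single_prec = false) {
  const Arch a = parse_arch(arch_spec);
  if (a.in_dim != 1) Rcpp::stop("kernel supports scalar (input_dim = 1) windows");
  if (single_prec) {
    fvec theta_f = conv_to<fvec>::from(theta);
    fmat X_f = conv_to<fmat>::from(X);
    fmat mask_f = conv_to<fmat>::from(drop_mask);
    return drnn_batch_impl<float>(theta_f, a, X_f, y0, want_grad, mask_f,
                                  keep_prob);
  }
  return drnn_batch_impl<double>(theta, a, X, y0, want_grad, drop_mask,
                                 keep_prob);
}
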