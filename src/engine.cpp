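#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Dual-tap delay-line pitch shifter (harmonizer).
//
// The tap delay drifts at (1 - ratio) samples per sample and wraps inside
// [0, wrap_len]; the second tap runs half a wrap period behind. Raised-cosine
// crossfades localized around each tap's wrap (fade width = FADE_FRAC of the
// wrap period; complementary gains, exact sum 1) hand the signal over so the
// wrap of either tap is silent; outside the fades a single tap is heard at
// gain exactly 1, which keeps the blend-induced pitch flutter confined to a
// small fraction of the time. wrap_len is an even integer so the initial tap
// can sit at an exactly integer delay (wrap_len / 2) with gain exactly 1: a
// unity ratio is then a bit-exact pure delay.
//
// State layout (modified in place so block-wise streaming carries over):
//   buf   : ring buffer of past input, length buf_len
//   pos   : next write index into buf
//   d1    : current delay (samples) of the primary tap
// [[Rcpp::export(name = ".harmonizer_process_cpp")]]
NumericVector harmonizer_process_cpp(NumericVector block,
                                     NumericVector ratio,
                                     NumericVector buf,
                                     IntegerVector pos_io,
                                     NumericVector d1_io,
                                     double wrap_len) {
    int n = block.size();
    int buf_len = buf.size();
    int pos = pos_io[0];
    double d1 = d1_io[0];
    double half = wrap_len / 2.0;
    const double pi = 3.14159265358979323846;
    NumericVector out(n);

    for (int i = 0; i < n; ++i) {
        // write current input sample first: delay 0 = current sample
        buf[pos] = block[i];

        double d2 = d1 + half;
        if (d2 >= wrap_len) d2 -= wrap_len;

        // primary-tap gain as a function of wrap phase p = d1 / wrap_len:
        // raised-cosine rise on [0, w], solo (gain 1) on [w, 1/2],
        // mirrored fall on [1/2, 1/2 + w], silent on [1/2 + w, 1).
        const double w = 0.125;  // FADE_FRAC
        double p = d1 / wrap_len;
        double g1;
        if (p < w)
            g1 = 0.5 - 0.5 * std::cos(pi * p / w);
        else if (p <= 0.5)
            g1 = 1.0;
        else if (p < 0.5 + w)
            g1 = 0.5 + 0.5 * std::cos(pi * (p - 0.5) / w);
        else
            g1 = 0.0;
        double g2 = 1.0 - g1;

        double y = 0.0;
        if (g1 != 0.0) {
            int i0 = (int)std::floor(d1);
            double fr = d1 - i0;
            int k0 = pos - i0; if (k0 < 0) k0 += buf_len;
            if (fr == 0.0) {
                y += g1 * buf[k0];
            } else {
                int k1 = k0 - 1; if (k1 < 0) k1 += buf_len;
                y += g1 * ((1.0 - fr) * buf[k0] + fr * buf[k1]);
            }
        }
        if (g2 != 0.0) {
            int i0 = (int)std::floor(d2);
            double fr = d2 - i0;
            int k0 = pos - i0; if (k0 < 0) k0 += buf_len;
            if (fr == 0.0) {
                y += g2 * buf[k0];
            } else {
                int k1 = k0 - 1; if (k1 < 0) k1 += buf_len;
                y += g2 * ((1.0 - fr) * buf[k0] + fr * buf[k1]);
            }
        }
        out[i] = y;

        d1 += 1.0 - ratio[i];
        while (d1 < 0.0) d1 += wrap_len;
        while (d1 >= wrap_len) d1 -= wrap_len;

        ++pos;
        if (pos == buf_len) pos = 0;
    }

    pos_io[0] = pos;
    d1_io[0] = d1;
    return out;
}

// Direct-form II transposed IIR filter with carried state, so block-wise
// application is bit-identical to whole-signal application.
// b, a: coefficient vectors (a[0] must be 1); z: state, length max(nb,na)-1.
// [[Rcpp::export(name = ".iir_df2t_cpp")]]
NumericVector iir_df2t_cpp(NumericVector b, NumericVector a,
                           NumericVector x, NumericVector z) {
    int n = x.size();
    int nb = b.size(), na = a.size();
    int nz = z.size();
    NumericVector y(n);
    for (int i = 0; i < n; ++i) {
        double xi = x[i];
        double yi = b[0] * xi + (nz > 0 ? z[0] : 0.0);
        for (int k = 0; k < nz; ++k) {
            double zk1 = (k + 1 < nz) ? z[k + 1] : 0.0;
            double bterm = (k + 1 < nb) ? b[k + 1] * xi : 0.0;
            double aterm = (k + 1 < na) ? a[k + 1] * yi : 0.0;
            z[k] = zk1 + bterm - aterm;
        }
        y[i] = yi;
    }
    return y;
}
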