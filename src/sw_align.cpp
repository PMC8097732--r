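#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps, Gotoh three-state DP.
// Gap of length L costs gap_open + (L-1) * gap_extend.  I<->D adjacency is
// allowed (at open cost) so the DP's path space matches exhaustive
// enumeration over all local alignment paths.
//
// Deterministic tie-breaking: among equal-scoring end cells the one with the
// smallest reference coordinate, then smallest read coordinate, is chosen;
// traceback prefers diagonal over gap states (fewest gaps).
//
// Returns 1-based coordinates and a per-column op string over {=,X,I,D}
// where I consumes a read base (insertion relative to the reference) and D
// consumes a reference base (deletion from the read).
// [[Rcpp::export]]
List sw_align_cpp(std::string read, std::string ref,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
    const int n = (int) read.size();
    const int m = (int) ref.size();
    const double NEG = -std::numeric_limits<double>::infinity();
    if (n == 0 || m == 0) {
        return List::create(_["score"] = 0.0, _["read_start"] = 0,
                            _["read_end"] = 0, _["ref_start"] = 0,
                            _["ref_end"] = 0, _["ops"] = "");
    }
    const size_t W = (size_t) m + 1;
    std::vector<double> M((n + 1) * W, 0.0), Ix((n + 1) * W, NEG),
        Iy((n + 1) * W, NEG);
    // traceback codes -- M: 0 fresh start, 1 from M, 2 from Ix, 3 from Iy
    //                    Ix/Iy: 1 open from M, 2 extend, 3 open from other gap
    std::vector<unsigned char> tbM((n + 1) * W, 0), tbIx((n + 1) * W, 0),
        tbIy((n + 1) * W, 0);

    double best = 0.0;
    int bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            const size_t c = (size_t) i * W + j;
            const size_t d = (size_t) (i - 1) * W + (j - 1);
            const size_t u = (size_t) (i - 1) * W + j;
            const size_t l = (size_t) i * W + (j - 1);
            // aligned column
            double s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
            double db = 0.0; unsigned char dc = 0;
            if (M[d] > db) { db = M[d]; dc = 1; }
            if (Ix[d] > db) { db = Ix[d]; dc = 2; }
            if (Iy[d] > db) { db = Iy[d]; dc = 3; }
            M[c] = db + s; tbM[c] = dc;
            // gap in reference (consume read base i)
            double vo = M[u] + gap_open, ve = Ix[u] + gap_extend,
                   vx = Iy[u] + gap_open;
            if (vo >= ve && vo >= vx) { Ix[c] = vo; tbIx[c] = 1; }
            else if (ve >= vx)        { Ix[c] = ve; tbIx[c] = 2; }
            else                      { Ix[c] = vx; tbIx[c] = 3; }
            // gap in read (consume reference base j)
            vo = M[l] + gap_open; ve = Iy[l] + gap_extend; vx = Ix[l] + gap_open;
            if (vo >= ve && vo >= vx) { Iy[c] = vo; tbIy[c] = 1; }
            else if (ve >= vx)        { Iy[c] = ve; tbIy[c] = 2; }
            else                      { Iy[c] = vx; tbIy[c] = 3; }
            // local alignments end on an aligned column
            if (M[c] > best ||
                (M[c] == best && (j < bj || (j == bj && i < bi)))) {
                if (M[c] > 0) { best = M[c]; bi = i; bj = j; }
            }
        }
    }
    if (best <= 0.0 || bi == 0) {
        return List::create(_["score"] = 0.0, _["read_start"] = 0,
                            _["read_end"] = 0, _["ref_start"] = 0,
                            _["ref_end"] = 0, _["ops"] = "");
    }
    // traceback
    std::string ops;
    int i = bi, j = bj, state = 0;  // 0 = M, 1 = Ix, 2 = Iy
    while (true) {
        const size_t c = (size_t) i * W + j;
        if (state == 0) {
            ops.push_back(read[i - 1] == ref[j - 1] ? '=' : 'X');
            unsigned char t = tbM[c];
            --i; --j;
            if (t == 0) break;
            state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
        } else if (state == 1) {
            ops.push_back('I');
            unsigned char t = tbIx[c];
            --i;
            state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
        } else {
            ops.push_back('D');
            unsigned char t = tbIy[c];
            --j;
            state = (t == 1) ? 0 : (t == 2 ? 2 : 1);
        }
    }
    std::reverse(ops.begin(), ops.end());
    return List::create(_["score"] = best, _["read_start"] = i + 1,
                        _["read_end"] = bi, _["ref_start"] = j + 1,
                        _["ref_end"] = bj, _["ops"] = ops);
}
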