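#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// All-vs-all cross-genome protein search: exact k-mer seeds, X-drop ungapped
// extension as a screen, then banded affine-gap Smith-Waterman around the
// best seed diagonal. Gap of length L costs gap_open + gap_ext * L.

namespace {

const int NEG = -1000000000;

struct AlnResult {
    int score, qstart, qend, sstart, send;
    int ident, length, mismatches, gapopens, gaps;
};

// ungapped X-drop extension around a k-mer seed; returns best segment score
int ungapped_extend(const std::vector<int8_t>& a, const std::vector<int8_t>& b,
                    int qp, int sp, int k, const int* S, int nA, int xdrop) {
    int score = 0;
    for (int t = 0; t < k; ++t) score += S[a[qp + t] * nA + b[sp + t]];
    // right
    int best = score, cur = score;
    int i = qp + k, j = sp + k;
    while (i < (int)a.size() && j < (int)b.size()) {
        cur += S[a[i] * nA + b[j]];
        if (cur > best) best = cur;
        if (best - cur > xdrop) break;
        ++i; ++j;
    }
    // left
    int cur2 = best;
    int bestL = best;
    i = qp - 1; j = sp - 1;
    while (i >= 0 && j >= 0) {
        cur2 += S[a[i] * nA + b[j]];
        if (cur2 > bestL) bestL = cur2;
        if (bestL - cur2 > xdrop) break;
        --i; --j;
    }
    return bestL;
}

// banded affine local alignment; band centred on diagonal d0 (q - s)
AlnResult banded_sw(const std::vector<int8_t>& a, const std::vector<int8_t>& b,
                    int d0, int band, const int* S, int nA,
                    int gap_open, int gap_ext) {
    int m = (int)a.size(), n = (int)b.size();
    int W = 2 * band + 1;
    std::vector<int> H((m + 1) * W, NEG), E((m + 1) * W, NEG), F((m + 1) * W, NEG);
    // column c in row i corresponds to subject index jj = i - d0 - band + c
    auto JJ = [&](int i, int c) { return i - d0 - band + c; };
    int bestScore = 0, bi = -1, bc = -1;
    for (int c = 0; c < W; ++c) { int jj = JJ(0, c); if (jj >= 0 && jj <= n) H[c] = 0; }
    for (int i = 1; i <= m; ++i) {
        for (int c = 0; c < W; ++c) {
            int jj = JJ(i, c);
            if (jj < 0 || jj > n) continue;
            int idx = i * W + c;
            if (jj == 0) { H[idx] = 0; continue; }
            // E: gap in query (left move, same i, jj-1 => c-1)
            int e = NEG;
            if (c - 1 >= 0 && JJ(i, c - 1) >= 0) {
                int pidx = i * W + (c - 1);
                if (H[pidx] > NEG / 2) e = H[pidx] - gap_open - gap_ext;
                if (E[pidx] > NEG / 2 && E[pidx] - gap_ext > e) e = E[pidx] - gap_ext;
            }
            // F: gap in subject (up move, i-1, same jj => c+1 in row i-1)
            int f = NEG;
            if (c + 1 < W) {
                int pidx = (i - 1) * W + (c + 1);
                if (H[pidx] > NEG / 2) f = H[pidx] - gap_open - gap_ext;
                if (F[pidx] > NEG / 2 && F[pidx] - gap_ext > f) f = F[pidx] - gap_ext;
            }
            // diagonal (i-1, jj-1 => same c in row i-1)
            int d = NEG;
            {
                int pidx = (i - 1) * W + c;
                if (H[pidx] > NEG / 2) d = H[pidx] + S[a[i - 1] * nA + b[jj - 1]];
            }
            int h = 0;
            if (d > h) h = d;
            if (e > h) h = e;
            if (f > h) h = f;
            E[idx] = e; F[idx] = f; H[idx] = h;
            if (h > bestScore) { bestScore = h; bi = i; bc = c; }
        }
    }
    AlnResult r; r.score = bestScore;
    r.qstart = r.qend = r.sstart = r.send = 0;
    r.ident = r.length = r.mismatches = r.gapopens = r.gaps = 0;
    if (bestScore <= 0) return r;
    // traceback
    int i = bi, c = bc, jj = JJ(bi, bc);
    r.qend = i; r.send = jj;
    int state = 0; // 0 = H, 1 = E, 2 = F
    bool inGapRun = false;
    while (true) {
        int idx = i * W + c;
        if (state == 0) {
            if (H[idx] == 0) break;
            int d = NEG, pidx = (i - 1) * W + c;
            if (i >= 1 && jj >= 1 && H[pidx] > NEG / 2)
                d = H[pidx] + S[a[i - 1] * nA + b[jj - 1]];
            if (H[idx] == d) {
                r.length++; if (a[i - 1] == b[jj - 1]) r.ident++; else r.mismatches++;
                inGapRun = false;
                i--; jj--; // c unchanged
            } else if (H[idx] == E[idx]) { state = 1; }
            else { state = 2; }
        } else if (state == 1) { // gap in query: consume subject char
            r.length++; r.gaps++;
            if (!inGapRun) { r.gapopens++; inGapRun = true; }
            int pidx = i * W + (c - 1);
            bool fromE = (E[i * W + c] == E[pidx] - gap_ext) && E[pidx] > NEG / 2;
            bool fromH = (E[i * W + c] == H[pidx] - gap_open - gap_ext);
            jj--; c--;
            if (fromE && !fromH) { /* stay in E */ }
            else { state = 0; inGapRun = false; }
        } else { // F: gap in subject: consume query char
            r.length++; r.gaps++;
            if (!inGapRun) { r.gapopens++; inGapRun = true; }
            int pidx = (i - 1) * W + (c + 1);
            bool fromF = (F[i * W + c] == F[pidx] - gap_ext) && F[pidx] > NEG / 2;
            bool fromH = (F[i * W + c] == H[pidx] - gap_open - gap_ext);
            i--; c++;
            if (fromF && !fromH) { /* stay in F */ }
            else { state = 0; inGapRun = false; }
        }
    }
    r.qstart = i + 1; r.sstart = jj + 1;
    return r;
}

} // namespace

// [[Rcpp::export(name = ".align_all_cpp")]]
DataFrame align_all_cpp(List enc_seqs, IntegerVector genome,
                        IntegerMatrix score_mat,
                        int k, int screen_min, int xdrop, int band,
                        int gap_open, int gap_ext, int max_seeds) {
    int nG = enc_seqs.size();
    int nA = score_mat.nrow();
    std::vector<int> S(nA * nA);
    for (int i = 0; i < nA; ++i)
        for (int j = 0; j < nA; ++j) S[i * nA + j] = score_mat(i, j);
    std::vector<std::vector<int8_t> > seqs(nG);
    for (int g = 0; g < nG; ++g) {
        IntegerVector v = enc_seqs[g];
        seqs[g].assign(v.begin(), v.end());
    }
    // k-mer postings; key in base nA (nA <= 32 keeps key < 2^20 for k = 4)
    int64_t nkey = 1;
    for (int t = 0; t < k; ++t) nkey *= nA;
    std::vector<std::vector<std::pair<int,int> > > postings((size_t)nkey);
    for (int g = 0; g < nG; ++g) {
        const std::vector<int8_t>& sq = seqs[g];
        if ((int)sq.size() < k) continue;
        int64_t key = 0;
        int64_t topmul = 1;
        for (int t = 0; t < k - 1; ++t) topmul *= nA;
        for (int p = 0; p + k <= (int)sq.size(); ++p) {
            if (p == 0) {
                key = 0;
                for (int t = 0; t < k; ++t) key = key * nA + sq[t];
            } else {
                key = (key % (topmul)) * nA + sq[p + k - 1];
            }
            postings[(size_t)key].push_back(std::make_pair(g, p));
        }
    }
    // per-query accumulation: for each gene i, collect up to max_seeds
    // seeds against every candidate j > i in another genome, then screen
    // with an ungapped extension and align the survivors
    std::vector<int> oQ, oS, oScore, oQs, oQe, oSs, oSe, oId, oLen, oMm, oGo, oGp;
    std::vector<uint8_t> nseed(nG, 0);
    std::vector<int> seedq(nG * max_seeds), seeds(nG * max_seeds);
    std::vector<int> touched; touched.reserve(1024);
    for (int i = 0; i < nG; ++i) {
        const std::vector<int8_t>& sq = seqs[i];
        if ((int)sq.size() < k) continue;
        int64_t key = 0, topmul = 1;
        for (int t = 0; t < k - 1; ++t) topmul *= nA;
        for (int p = 0; p + k <= (int)sq.size(); ++p) {
            if (p == 0) { key = 0; for (int t = 0; t < k; ++t) key = key * nA + sq[t]; }
            else key = (key % topmul) * nA + sq[p + k - 1];
            const std::vector<std::pair<int,int> >& pl = postings[(size_t)key];
            for (size_t x = 0; x < pl.size(); ++x) {
                int j = pl[x].first;
                if (j <= i || genome[j] == genome[i]) continue;
                uint8_t& c = nseed[j];
                if (c == 0) touched.push_back(j);
                if (c < max_seeds) {
                    seedq[j * max_seeds + c] = p;
                    seeds[j * max_seeds + c] = pl[x].second;
                    ++c;
                }
            }
        }
        for (size_t t = 0; t < touched.size(); ++t) {
            int j = touched[t];
            int best = NEG, bd = 0;
            for (int s = 0; s < nseed[j]; ++s) {
                int qp = seedq[j * max_seeds + s], sp = seeds[j * max_seeds + s];
                int sc = ungapped_extend(seqs[i], seqs[j], qp, sp,
                                         k, S.data(), nA, xdrop);
                if (sc > best) { best = sc; bd = qp - sp; }
            }
            nseed[j] = 0;
            if (best < screen_min) continue;
            AlnResult r = banded_sw(seqs[i], seqs[j], bd, band, S.data(), nA,
                                    gap_open, gap_ext);
            if (r.score <= 0) continue;
            oQ.push_back(i + 1); oS.push_back(j + 1);
            oScore.push_back(r.score);
            oQs.push_back(r.qstart); oQe.push_back(r.qend);
            oSs.push_back(r.sstart); oSe.push_back(r.send);
            oId.push_back(r.ident); oLen.push_back(r.length);
            oMm.push_back(r.mismatches); oGo.push_back(r.gapopens); oGp.push_back(r.gaps);
        }
        touched.clear();
    }
    return DataFrame::create(
        _["qi"] = oQ, _["si"] = oS, _["raw_score"] = oScore,
        _["qstart"] = oQs, _["qend"] = oQe, _["sstart"] = oSs, _["send"] = oSe,
        _["ident"] = oId, _["aln_len"] = oLen, _["mismatches"] = oMm,
        _["gapopens"] = oGo, _["gaps"] = oGp);
}

// full (unbanded) local affine alignment score for one pair; used for
// spot-checking the banded search on individual pairs
// [[Rcpp::export(name = ".sw_score_cpp")]]
int sw_score_cpp(IntegerVector ea, IntegerVector eb, IntegerMatrix score_mat,
                 int gap_open, int gap_ext) {
    int m = ea.size(), n = eb.size(), nA = score_mat.nrow();
    std::vector<int> S(nA * nA);
    for (int i = 0; i < nA; ++i)
        for (int j = 0; j < nA; ++j) S[i * nA + j] = score_mat(i, j);
    std::vector<int> Hp(n + 1, 0), H(n + 1, 0), Ep(n + 1, NEG), E(n + 1, NEG), F(n + 1, NEG);
    int best = 0;
    for (int i = 1; i <= m; ++i) {
        H[0] = 0; E[0] = NEG; int Fi = NEG;
        for (int j = 1; j <= n; ++j) {
            int e = std::max(H[j - 1] - gap_open - gap_ext,
                             (E[j - 1] > NEG / 2 ? E[j - 1] - gap_ext : NEG));
            int f = std::max(Hp[j] - gap_open - gap_ext,
                             (F[j] > NEG / 2 ? F[j] - gap_ext : NEG));
            int d = Hp[j - 1] + S[ea[i - 1] * nA + eb[j - 1]];
            int h = 0;
            if (d > h) h = d;
            if (e > h) h = e;
            if (f > h) h = f;
            E[j] = e; F[j] = f; H[j] = h;
            if (h > best) best = h;
            (void)Fi;
        }
        std::swap(Hp, H); std::swap(Ep, E);
    }
    return best;
}
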