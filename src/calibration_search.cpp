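// Inner loop of the composition-matched random-subset calibration search.
// Uses R's RNG (unif_rand) so results are reproducible from set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// average ranks of x (ties averaged), writing into out
static void avgRank(const std::vector<double>& x, std::vector<int>& ord,
                    std::vector<double>& out) {
    const int n = (int)x.size();
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&x](int a, int b) { return x[a] < x[b]; });
    int i = 0;
    while (i < n) {
        int j = i;
        while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
        double r = 0.5 * (i + j) + 1.0;  // average of ranks i+1..j+1
        for (int k = i; k <= j; ++k) out[ord[k]] = r;
        i = j + 1;
    }
}

// sample k of n without replacement (partial Fisher-Yates), indices 0..n-1
static void sampleK(int n, int k, std::vector<int>& pool,
                    std::vector<int>& out) {
    for (int i = 0; i < n; ++i) pool[i] = i;
    for (int i = 0; i < k; ++i) {
        int j = i + (int)(unif_rand() * (n - i));
        if (j >= n) j = n - 1;
        std::swap(pool[i], pool[j]);
        out[i] = pool[i];
    }
}

// [[Rcpp::export]]
List calibration_search_cpp(NumericMatrix studyRef, IntegerVector refCalls,
                            NumericMatrix training, IntegerVector trainLabels,
                            NumericMatrix centroidRank, int kmin, int kmax,
                            int niter, int maxRedraw) {
    const int g = studyRef.nrow();
    const int nref = studyRef.ncol();
    const int ntrain = training.ncol();
    const int nsub = centroidRank.ncol();

    // training column indices per subtype (1-based labels)
    std::vector<std::vector<int>> pools(nsub);
    for (int j = 0; j < ntrain; ++j)
        pools[trainLabels[j] - 1].push_back(j);

    // centroid rank moments for Pearson-on-ranks
    std::vector<double> cMean(nsub), cSd(nsub);
    for (int s = 0; s < nsub; ++s) {
        double m = 0;
        for (int i = 0; i < g; ++i) m += centroidRank(i, s);
        m /= g;
        double v = 0;
        for (int i = 0; i < g; ++i) {
            double d = centroidRank(i, s) - m;
            v += d * d;
        }
        cMean[s] = m;
        cSd[s] = std::sqrt(v / (g - 1));
    }

    // flat column-major copies for fast access in the hot loop
    std::vector<double> S(studyRef.begin(), studyRef.end());       // g x nref
    std::vector<double> T(training.begin(), training.end());      // g x ntrain
    std::vector<double> C(g * nsub);                              // centered centroid ranks
    for (int s = 0; s < nsub; ++s)
        for (int i = 0; i < g; ++i)
            C[s * g + i] = centroidRank(i, s) - cMean[s];

    std::vector<int> refIdx(kmax), pool(std::max(nref, ntrain));
    std::vector<int> comp(nsub), trainSub;
    std::vector<double> centering(g), prof(g), ranks(g);
    std::vector<int> ord(g);

    double bestConc = -1.0, bestMeanCor = -2.0;
    std::vector<double> bestCentering(g, 0.0);
    int bestK = 0, skipped = 0;
    std::vector<int> bestComp(nsub, 0);

    for (int iter = 0; iter < niter; ++iter) {
        bool matched = false;
        int k = 0;
        for (int attempt = 0; attempt <= maxRedraw && !matched; ++attempt) {
            k = kmin + (int)(unif_rand() * (kmax - kmin + 1));
            if (k > kmax) k = kmax;
            if (k > nref) k = nref;
            sampleK(nref, k, pool, refIdx);
            std::fill(comp.begin(), comp.end(), 0);
            for (int i = 0; i < k; ++i) comp[refCalls[refIdx[i]] - 1]++;
            matched = true;
            for (int s = 0; s < nsub; ++s)
                if (comp[s] > (int)pools[s].size()) { matched = false; break; }
        }
        if (!matched) { ++skipped; continue; }

        // composition-matched training subset
        trainSub.clear();
        for (int s = 0; s < nsub; ++s) {
            int need = comp[s];
            if (need == 0) continue;
            int m = (int)pools[s].size();
            for (int i = 0; i < m; ++i) pool[i] = pools[s][i];
            for (int i = 0; i < need; ++i) {
                int j = i + (int)(unif_rand() * (m - i));
                if (j >= m) j = m - 1;
                std::swap(pool[i], pool[j]);
                trainSub.push_back(pool[i]);
            }
        }

        // centering = mean(study subset) - mean(training subset), per gene
        std::fill(centering.begin(), centering.end(), 0.0);
        for (int a = 0; a < k; ++a) {
            const double* col = &S[(size_t)refIdx[a] * g];
            for (int i = 0; i < g; ++i) centering[i] += col[i];
        }
        for (int i = 0; i < g; ++i) centering[i] /= k;
        const double invT = 1.0 / (double)trainSub.size();
        for (size_t a = 0; a < trainSub.size(); ++a) {
            const double* col = &T[(size_t)trainSub[a] * g];
            for (int i = 0; i < g; ++i) centering[i] -= col[i] * invT;
        }

        // classify every reference sample, count concordance
        int hits = 0;
        double sumCor = 0;
        const double rMean = (g + 1) / 2.0;
        for (int j = 0; j < nref; ++j) {
            const double* col = &S[(size_t)j * g];
            for (int i = 0; i < g; ++i)
                prof[i] = col[i] - centering[i];
            avgRank(prof, ord, ranks);
            double rVar = 0;
            for (int i = 0; i < g; ++i) {
                double d = ranks[i] - rMean;
                rVar += d * d;
            }
            double rSd = std::sqrt(rVar / (g - 1));
            int label = 0;
            double bestCor = -2.0;
            if (rSd > 0) {
                for (int s = 0; s < nsub; ++s) {
                    const double* cc = &C[(size_t)s * g];
                    double sxy = 0;
                    for (int i = 0; i < g; ++i)
                        sxy += (ranks[i] - rMean) * cc[i];
                    double cor = sxy / ((g - 1) * rSd * cSd[s]);
                    if (cor > bestCor + 1e-12) { bestCor = cor; label = s + 1; }
                }
            }
            if (label == refCalls[j]) ++hits;
            sumCor += (label > 0) ? bestCor : 0.0;
        }
        double conc = (double)hits / nref;
        double meanCor = sumCor / nref;
        if (conc > bestConc + 1e-15 ||
            (conc > bestConc - 1e-15 && meanCor > bestMeanCor + 1e-12)) {
            bestConc = conc;
            bestMeanCor = meanCor;
            bestK = k;
            for (int s = 0; s < nsub; ++s) bestComp[s] = comp[s];
            std::copy(centering.begin(), centering.end(),
                      bestCentering.begin());
        }
    }

    return List::create(
        _["centering"] = NumericVector(bestCentering.begin(),
                                       bestCentering.end()),
        _["k"] = bestK,
        _["composition"] = IntegerVector(bestComp.begin(), bestComp.end()),
        _["concordance"] = bestConc,
        _["mean_cor"] = bestMeanCor,
        _["skipped"] = skipped);
}
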