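#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// N mismatches everything, including another N
static inline bool within_hamming(const std::string &a, int pa,
                                  const std::string &b, int pb,
                                  int K, int E) {
    int mm = 0;
    for (int i = 0; i < K; ++i) {
        const char x = a[pa + i], y = b[pb + i];
        if (x == 'N' || y == 'N' || x != y) {
            if (++mm > E) return false;
        }
    }
    return true;
}

// occ(p) = number of length-K windows across all of `seqs` within Hamming
// distance <= E of the window starting at p. Callers pass the forward
// chromosomes followed by their reverse complements so that both strands are
// indexed; only the first n_query sequences are scored. Exactness rests on
// the pigeonhole principle: a window with <= E mismatches must agree exactly
// on at least one of E+1 disjoint chunks, so exact chunk lookup generates a
// candidate superset which full verification then filters.
// [[Rcpp::export]]
List mappability_occ(std::vector<std::string> seqs, int n_query, int K, int E) {
    const int n_seq = (int) seqs.size();
    const int n_chunk = E + 1;

    std::vector<int> chunk_off(n_chunk + 1);
    for (int c = 0; c <= n_chunk; ++c)
        chunk_off[c] = (int) ((long long) c * K / n_chunk);

    // enumerate windows
    std::vector<int> win_seq, win_start;
    std::vector<long long> first_win(n_seq + 1, 0);
    for (int s = 0; s < n_seq; ++s) {
        const long long L = (long long) seqs[s].size();
        first_win[s + 1] = first_win[s] + (L >= K ? L - K + 1 : 0);
        for (long long q = 0; q + K <= L; ++q) {
            win_seq.push_back(s);
            win_start.push_back((int) q);
        }
    }
    const long long n_win = (long long) win_seq.size();

    // chunk index: exact substring -> window ids
    std::vector<std::unordered_map<std::string, std::vector<int>>> index(n_chunk);
    for (int c = 0; c < n_chunk; ++c)
        index[c].reserve((size_t) n_win * 2);
    for (long long w = 0; w < n_win; ++w) {
        const std::string &s = seqs[win_seq[w]];
        const int q = win_start[w];
        for (int c = 0; c < n_chunk; ++c) {
            index[c][s.substr(q + chunk_off[c], chunk_off[c + 1] - chunk_off[c])]
                .push_back((int) w);
        }
    }

    std::vector<long long> seen(n_win, -1);
    List out(n_query);
    long long qid = 0;
    for (int s = 0; s < n_query; ++s) {
        const std::string &qs = seqs[s];
        const long long nw = first_win[s + 1] - first_win[s];
        NumericVector occ(nw);
        for (long long i = 0; i < nw; ++i, ++qid) {
            const int qpos = (int) i;
            int count = 0;
            for (int c = 0; c < n_chunk; ++c) {
                auto it = index[c].find(
                    qs.substr(qpos + chunk_off[c], chunk_off[c + 1] - chunk_off[c]));
                if (it == index[c].end()) continue;
                for (const int w : it->second) {
                    if (seen[w] == qid) continue;
                    seen[w] = qid;
                    if (within_hamming(qs, qpos, seqs[win_seq[w]], win_start[w], K, E))
                        ++count;
                }
            }
            occ[i] = (double) count;
        }
        out[s] = occ;
    }
    return out;
}
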