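// k-mer seeded candidate-pair detection for the all-against-all similarity
// search: sequence pairs sharing >= min_hits distinct k-mers are candidates
// for Smith-Waterman scoring.
#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Murphy-style 10-letter reduced alphabet (LVIM C A G ST P FYW EDNQ KR H):
// conserves hydrophobic/charge classes so seeds survive conservative
// substitutions in diverged homologs.
static char reduce_aa(char c) {
  switch (toupper(c)) {
  case 'L': case 'V': case 'I': case 'M': return 'L';
  case 'C': return 'C';
  case 'A': return 'A';
  case 'G': return 'G';
  case 'S': case 'T': return 'S';
  case 'P': return 'P';
  case 'F': case 'Y': case 'W': return 'F';
  case 'E': case 'D': case 'N': case 'Q': return 'E';
  case 'K': case 'R': return 'K';
  case 'H': return 'H';
  default: return 'X';
  }
}

// [[Rcpp::export]]
IntegerMatrix kmer_candidate_pairs_cpp(std::vector<std::string> seqs,
                                       int k = 5, int min_hits = 2,
                                       int max_bucket = 5000,
                                       bool reduced = false) {
  const int n = (int)seqs.size();
  if (reduced)
    for (int i = 0; i < n; ++i)
      for (size_t p = 0; p < seqs[i].size(); ++p)
        seqs[i][p] = reduce_aa(seqs[i][p]);
  std::unordered_map<std::string, std::vector<int> > buckets;
  buckets.reserve(1 << 20);
  for (int i = 0; i < n; ++i) {
    const std::string &s = seqs[i];
    if ((int)s.size() < k) continue;
    std::unordered_map<std::string, char> seen;
    seen.reserve(s.size());
    for (size_t p = 0; p + k <= s.size(); ++p) {
      std::string km = s.substr(p, k);
      if (seen.emplace(km, 1).second) buckets[km].push_back(i);
    }
  }
  std::unordered_map<long long, int> counts;
  counts.reserve(1 << 20);
  for (auto &kv : buckets) {
    const std::vector<int> &v = kv.second;
    const int m = (int)v.size();
    if (m < 2 || m > max_bucket) continue;
    for (int a = 0; a < m; ++a)
      for (int b = a + 1; b < m; ++b)
        counts[(long long)v[a] * n + v[b]] += 1;
    Rcpp::checkUserInterrupt();
  }
  std::vector<std::pair<int, int> > pairs;
  for (auto &kv : counts)
    if (kv.second >= min_hits)
      pairs.push_back(std::make_pair((int)(kv.first / n), (int)(kv.first % n)));
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix out((int)pairs.size(), 2);
  for (size_t p = 0; p < pairs.size(); ++p) {
    out(p, 0) = pairs[p].first + 1;   // 1-based for R
    out(p, 1) = pairs[p].second + 1;
  }
  return out;
}
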