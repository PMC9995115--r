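#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int nt_index(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
CharacterVector translate_cpp(CharacterVector nt, CharacterVector code) {
  // code: 64-element character vector named by codon (e.g. "TTT" -> "F")
  std::unordered_map<int, char> table;
  CharacterVector codons = code.names();
  for (int i = 0; i < code.size(); ++i) {
    std::string c = as<std::string>(codons[i]);
    int key = nt_index(c[0]) * 16 + nt_index(c[1]) * 4 + nt_index(c[2]);
    table[key] = as<std::string>(code[i])[0];
  }
  int n = nt.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(nt[i]);
    int L = s.size();
    if (L == 0 || L % 3 != 0) { out[i] = NA_STRING; continue; }
    std::string aa(L / 3, 'X');
    bool ok = true;
    for (int j = 0; j < L / 3; ++j) {
      int a = nt_index(s[3 * j]), b = nt_index(s[3 * j + 1]), c = nt_index(s[3 * j + 2]);
      if (a < 0 || b < 0 || c < 0) { ok = false; break; }
      aa[j] = table[a * 16 + b * 4 + c];
    }
    out[i] = ok ? String(aa) : NA_STRING;
  }
  return out;
}

// Exact generation probability of nucleotide junctions under the V-ins-J
// model: sum over all (V, del_v) x insertion x (del_j, J) scenarios whose
// concatenation equals the query. vparts/jparts are the pre-trimmed segment
// remainders with combined usage x deletion probabilities.
// [[Rcpp::export]]
NumericVector pgen_nt_cpp(CharacterVector seqs,
                          CharacterVector vparts, NumericVector vprobs,
                          CharacterVector jparts, NumericVector jprobs,
                          NumericVector ins_len_pmf, NumericVector ins_nt) {
  int nv = vparts.size(), nj = jparts.size(), max_ins = ins_len_pmf.size() - 1;
  std::vector<std::string> vs(nv), js(nj);
  for (int i = 0; i < nv; ++i) vs[i] = as<std::string>(vparts[i]);
  for (int i = 0; i < nj; ++i) js[i] = as<std::string>(jparts[i]);
  int ns = seqs.size();
  NumericVector out(ns);
  for (int s = 0; s < ns; ++s) {
    std::string q = as<std::string>(seqs[s]);
    int n = q.size();
    double total = 0.0;
    for (int vi = 0; vi < nv; ++vi) {
      int a = vs[vi].size();
      if (a > n) continue;
      if (q.compare(0, a, vs[vi]) != 0) continue;
      for (int ji = 0; ji < nj; ++ji) {
        int b = js[ji].size();
        int m = n - a - b;
        if (m < 0 || m > max_ins) continue;
        double pl = ins_len_pmf[m];
        if (pl <= 0.0) continue;
        if (q.compare(n - b, b, js[ji]) != 0) continue;
        double p = vprobs[vi] * jprobs[ji] * pl;
        for (int t = a; t < n - b && p > 0.0; ++t) {
          int idx = nt_index(q[t]);
          p *= (idx < 0) ? 0.0 : ins_nt[idx];
        }
        total += p;
      }
    }
    out[s] = total;
  }
  return out;
}

// Exact amino-acid level pgen: for each V/J trim scenario the nucleotide
// positions are independent (fixed V/J chars, i.i.d. insertions), so the
// probability that the junction translates to the query factorises over
// codons; each codon factor sums over synonymous codons.
// [[Rcpp::export]]
NumericVector pgen_aa_cpp(CharacterVector aas,
                          CharacterVector vparts, NumericVector vprobs,
                          CharacterVector jparts, NumericVector jprobs,
                          NumericVector ins_len_pmf, NumericVector ins_nt,
                          CharacterVector aa_keys, List codon_list) {
  int nv = vparts.size(), nj = jparts.size(), max_ins = ins_len_pmf.size() - 1;
  std::vector<std::string> vs(nv), js(nj);
  for (int i = 0; i < nv; ++i) vs[i] = as<std::string>(vparts[i]);
  for (int i = 0; i < nj; ++i) js[i] = as<std::string>(jparts[i]);
  std::unordered_map<char, std::vector<std::string> > codons;
  for (int i = 0; i < aa_keys.size(); ++i) {
    char key = as<std::string>(aa_keys[i])[0];
    CharacterVector cv = codon_list[i];
    std::vector<std::string> v(cv.size());
    for (int j = 0; j < cv.size(); ++j) v[j] = as<std::string>(cv[j]);
    codons[key] = v;
  }
  int ns = aas.size();
  NumericVector out(ns);
  for (int s = 0; s < ns; ++s) {
    std::string aa = as<std::string>(aas[s]);
    int L = aa.size(), n = 3 * L;
    bool valid = true;
    for (int i = 0; i < L; ++i)
      if (codons.find(aa[i]) == codons.end()) { valid = false; break; }
    if (!valid) { out[s] = NA_REAL; continue; }
    double total = 0.0;
    for (int vi = 0; vi < nv; ++vi) {
      int a = vs[vi].size();
      if (a > n) continue;
      const std::string &vp = vs[vi];
      for (int ji = 0; ji < nj; ++ji) {
        int b = js[ji].size();
        int m = n - a - b;
        if (m < 0 || m > max_ins) continue;
        double pl = ins_len_pmf[m];
        if (pl <= 0.0) continue;
        const std::string &jp = js[ji];
        double p = vprobs[vi] * jprobs[ji] * pl;
        for (int i = 0; i < L && p > 0.0; ++i) {
          const std::vector<std::string> &cs = codons[aa[i]];
          double csum = 0.0;
          for (size_t ci = 0; ci < cs.size(); ++ci) {
            double w = 1.0;
            for (int t = 0; t < 3; ++t) {
              int pos = 3 * i + t;
              char req = cs[ci][t];
              if (pos < a) { if (vp[pos] != req) { w = 0.0; break; } }
              else if (pos >= n - b) { if (jp[pos - (n - b)] != req) { w = 0.0; break; } }
              else w *= ins_nt[nt_index(req)];
            }
            csum += w;
          }
          p *= csum;
        }
        total += p;
      }
    }
    out[s] = total;
  }
  return out;
}

static std::vector<long long> kmer_codes(const std::string &s, int k) {
  std::vector<long long> v;
  int L = s.size();
  if (L < k) return v;
  for (int i = 0; i + k <= L; ++i) {
    long long code = 0;
    for (int t = 0; t < k; ++t) code = code * 27 + (s[i + t] - 'A' + 1);
    v.push_back(code);
  }
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  return v;
}

// [[Rcpp::export]]
int shared_kmer_count_cpp(std::string a, std::string b, int k) {
  std::vector<long long> ka = kmer_codes(a, k), kb = kmer_codes(b, k);
  int i = 0, j = 0, shared = 0;
  while (i < (int)ka.size() && j < (int)kb.size()) {
    if (ka[i] == kb[j]) { ++shared; ++i; ++j; }
    else if (ka[i] < kb[j]) ++i;
    else ++j;
  }
  return shared;
}

// All unordered pairs (i, j), i < j, sharing >= tau distinct k-mers.
// Incremental inverted index: after processing sequence i, the per-pair
// counters hold the exact intersection sizes |kmers(i) ^ kmers(j)| for all
// j < i, so the edge decision needs no second pass. Sequences with fewer
// than tau distinct k-mers can never form an edge and are skipped entirely.
// Returns a 2-column 1-based index matrix.
// [[Rcpp::export]]
IntegerMatrix kmer_edges_cpp(CharacterVector seqs, int k, int tau) {
  int n = seqs.size();
  std::unordered_map<long long, std::vector<int> > postings;
  std::vector<int> cnt(n, 0), touched;
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i) {
    std::vector<long long> kmers = kmer_codes(as<std::string>(seqs[i]), k);
    if ((int)kmers.size() < tau) continue;
    touched.clear();
    for (size_t t = 0; t < kmers.size(); ++t) {
      std::unordered_map<long long, std::vector<int> >::iterator it =
        postings.find(kmers[t]);
      if (it == postings.end()) continue;
      const std::vector<int> &lst = it->second;
      for (size_t u = 0; u < lst.size(); ++u) {
        int j = lst[u];
        if (cnt[j]++ == 0) touched.push_back(j);
      }
    }
    for (size_t u = 0; u < touched.size(); ++u) {
      int j = touched[u];
      if (cnt[j] >= tau) { ei.push_back(j + 1); ej.push_back(i + 1); }
      cnt[j] = 0;
    }
    for (size_t t = 0; t < kmers.size(); ++t) postings[kmers[t]].push_back(i);
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t r = 0; r < ei.size(); ++r) { out(r, 0) = ei[r]; out(r, 1) = ej[r]; }
  return out;
}
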