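#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdio>

using namespace Rcpp;

// Pairwise stem relationships are held in an n x n integer relation matrix:
//   0 = row includes column (I, directed), 1 = column includes row,
//   2 = overlapping/pseudoknot (O), 3 = mutually exclusive (X), 4 = serial (no edge).
// rel(b,a) is the mirror of rel(a,b) (0 <-> 1).

static const int REL_NONE = 4;

// ---------------------------------------------------------------------------
// canonical code: lexicographically minimal upper-triangle encoding over all
// vertex orderings, found by branch-and-bound on column-wise prefixes.
// Equal codes <=> isomorphic (label- and I-direction-preserving) by
// construction, since the code determines the full relation matrix.
// ---------------------------------------------------------------------------

static const int REL_INF = 5;    // sentinel: larger than any relation code

struct MinCodeCtx {
    int n;
    const int* rel;              // flattened n x n, row-major: rel[a*n + b]
    std::vector<int> best, perm;
    std::vector<bool> used;
};

// Invariant on entry: best[0..prefixLen) equals the code of the current
// partial ordering, and best[prefixLen..] is the tail of the smallest
// completed code seen so far within that prefix (or REL_INF sentinels before
// any completion). A candidate column is pruned the moment it exceeds best;
// a strictly smaller entry overwrites best and invalidates its tail, and the
// subtree below is guaranteed to reach a leaf, so best always ends up equal
// to the minimum over all vertex orderings.
static void min_code_rec(MinCodeCtx& c, int k, int prefixLen) {
    if (k == c.n) return;
    for (int v = 0; v < c.n; ++v) {
        if (c.used[v]) continue;
        bool prune = false;
        for (int x = 0; x < k; ++x) {
            int code = c.rel[c.perm[x] * c.n + v];
            int b = c.best[prefixLen + x];
            if (code > b) { prune = true; break; }
            if (code < b) {
                c.best[prefixLen + x] = code;
                std::fill(c.best.begin() + prefixLen + x + 1, c.best.end(), REL_INF);
            }
        }
        if (prune) continue;
        c.used[v] = true;
        c.perm[k] = v;
        min_code_rec(c, k + 1, prefixLen + k);
        c.used[v] = false;
    }
}

static std::string code_string(const std::vector<int>& best, int n) {
    if (n == 1) return "0";
    // reconstruct upper-triangle matrix from column-major pair order
    std::vector<int> M(n * n, REL_NONE);
    int pos = 0;
    for (int y = 1; y < n; ++y)
        for (int x = 0; x < y; ++x)
            M[x * n + y] = best[pos++];
    static const char lab[4] = {'i', 'j', 'o', 'x'};
    std::string out;
    char buf[32];
    for (int x = 0; x < n - 1; ++x)
        for (int y = x + 1; y < n; ++y) {
            int v = M[x * n + y];
            if (v == REL_NONE) continue;
            std::snprintf(buf, sizeof(buf), "%d.%d.%c|", x + 1, y + 1, lab[v]);
            out += buf;
        }
    return out;
}

static std::string min_code(const int* rel, int n) {
    if (n == 1) return "0";
    MinCodeCtx c;
    c.n = n;
    c.rel = rel;
    int len = n * (n - 1) / 2;
    c.best.assign(len, REL_INF);
    c.perm.assign(n, 0);
    c.used.assign(n, false);
    min_code_rec(c, 0, 0);
    return code_string(c.best, n);
}

// connectivity by BFS; edgeMask selects which relation values count as edges
static bool connected_rel(const int* rel, int n, bool includeX) {
    if (n <= 1) return true;
    std::vector<int> stack;
    std::vector<bool> seen(n, false);
    stack.push_back(0);
    seen[0] = true;
    int nseen = 1;
    while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        for (int u = 0; u < n; ++u) {
            if (seen[u] || u == v) continue;
            int r = rel[v * n + u];
            bool edge = (r == 0 || r == 1 || r == 2 || (includeX && r == 3));
            if (edge) {
                seen[u] = true;
                ++nseen;
                stack.push_back(u);
            }
        }
    }
    return nseen == n;
}

// [[Rcpp::export(name = ".min_code_rel")]]
String min_code_rel(IntegerMatrix rel) {
    int n = rel.nrow();
    std::vector<int> rm(n * n);   // row-major copy (IntegerMatrix is column-major)
    for (int a = 0; a < n; ++a)
        for (int b = 0; b < n; ++b)
            rm[a * n + b] = rel(a, b);
    return min_code(rm.data(), n);
}

// ---------------------------------------------------------------------------
// arrangements: a row of 2n labels, each label twice, first occurrences
// ascending. Derive the relation matrix, test IO-connectivity, canonicalize.
// ---------------------------------------------------------------------------

static void rel_from_arrangement(const int* arr, int n, std::vector<int>& rel) {
    std::vector<int> first(n, -1), second(n, -1);
    for (int p = 0; p < 2 * n; ++p) {
        int lab = arr[p] - 1;
        if (first[lab] < 0) first[lab] = p; else second[lab] = p;
    }
    rel.assign(n * n, REL_NONE);
    for (int j = 0; j < n; ++j)
        for (int k = 0; k < n; ++k) {
            if (j == k) continue;
            if (first[j] > first[k]) continue;  // handled from the other side
            int code;
            if (second[j] < first[k]) code = REL_NONE;          // serial
            else if (second[k] < second[j]) code = 0;           // j includes k
            else code = 2;                                      // overlapping
            rel[j * n + k] = code;
            rel[k * n + j] = (code == 0) ? 1 : code;
        }
}

// [[Rcpp::export(name = ".arrangement_codes")]]
CharacterVector arrangement_codes(IntegerMatrix arrs) {
    int m = arrs.nrow();
    int n2 = arrs.ncol();
    int n = n2 / 2;
    CharacterVector out(m);
    std::vector<int> row(n2), rel;
    for (int i = 0; i < m; ++i) {
        for (int j = 0; j < n2; ++j) row[j] = arrs(i, j);
        rel_from_arrangement(row.data(), n, rel);
        if (!connected_rel(rel.data(), n, false)) {
            out[i] = NA_STRING;
        } else {
            out[i] = min_code(rel.data(), n);
        }
    }
    return out;
}

// [[Rcpp::export(name = ".arrangement_rel")]]
IntegerMatrix arrangement_rel(IntegerVector arr) {
    int n = arr.size() / 2;
    std::vector<int> a(arr.begin(), arr.end()), rel;
    rel_from_arrangement(a.data(), n, rel);
    IntegerMatrix out(n, n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            out(i, j) = rel[i * n + j];
    return out;
}

// codes of all single-vertex deletions that leave an IO-connected graph
// [[Rcpp::export(name = ".parent_codes_rel")]]
CharacterVector parent_codes_rel(IntegerMatrix rel) {
    int n = rel.nrow();
    std::vector<std::string> seen;
    for (int d = 0; d < n; ++d) {
        int m = n - 1;
        std::vector<int> sub(m * m);
        std::vector<int> keep;
        for (int v = 0; v < n; ++v) if (v != d) keep.push_back(v);
        for (int a = 0; a < m; ++a)
            for (int b = 0; b < m; ++b)
                sub[a * m + b] = rel(keep[a], keep[b]);
        if (!connected_rel(sub.data(), m, false)) continue;
        std::string code = min_code(sub.data(), m);
        bool dup = false;
        for (size_t i = 0; i < seen.size(); ++i)
            if (seen[i] == code) { dup = true; break; }
        if (!dup) seen.push_back(code);
    }
    CharacterVector out(seen.size());
    for (size_t i = 0; i < seen.size(); ++i) out[i] = seen[i];
    return out;
}

// ---------------------------------------------------------------------------
// ESU (Wernicke) enumeration of connected induced k-subsets; connectivity via
// I/O edges. Returns the canonical code of each subset (one entry per subset).
// ---------------------------------------------------------------------------

struct EsuCtx {
    int n, k;
    const int* rel;
    std::vector<std::vector<int> > adj;   // I/O adjacency
    std::vector<bool> blocked;            // in subgraph or its neighborhood
    std::vector<int> sub;
    std::vector<std::string> codes;
};

static void esu_record(EsuCtx& c) {
    int m = (int)c.sub.size();
    std::vector<int> rel(m * m);
    for (int a = 0; a < m; ++a)
        for (int b = 0; b < m; ++b)
            rel[a * m + b] = c.rel[c.sub[a] * c.n + c.sub[b]];
    c.codes.push_back(min_code(rel.data(), m));
}

static void esu_extend(EsuCtx& c, std::vector<int>& ext, int root) {
    if ((int)c.sub.size() == c.k) {
        esu_record(c);
        return;
    }
    while (!ext.empty()) {
        int w = ext.back();
        ext.pop_back();
        std::vector<int> ext2 = ext;
        for (size_t i = 0; i < c.adj[w].size(); ++i) {
            int u = c.adj[w][i];
            if (u > root && !c.blocked[u]) ext2.push_back(u);
        }
        std::vector<int> newly;
        if (!c.blocked[w]) { c.blocked[w] = true; newly.push_back(w); }
        for (size_t i = 0; i < c.adj[w].size(); ++i) {
            int u = c.adj[w][i];
            if (!c.blocked[u]) { c.blocked[u] = true; newly.push_back(u); }
        }
        c.sub.push_back(w);
        esu_extend(c, ext2, root);
        c.sub.pop_back();
        for (size_t i = 0; i < newly.size(); ++i) c.blocked[newly[i]] = false;
    }
}

// [[Rcpp::export(name = ".esu_codes")]]
CharacterVector esu_codes(IntegerMatrix rel, int k) {
    EsuCtx c;
    c.n = rel.nrow();
    c.k = k;
    std::vector<int> rm(c.n * c.n);
    for (int a = 0; a < c.n; ++a)
        for (int b = 0; b < c.n; ++b)
            rm[a * c.n + b] = rel(a, b);
    c.rel = rm.data();
    c.adj.assign(c.n, std::vector<int>());
    for (int a = 0; a < c.n; ++a)
        for (int b = 0; b < c.n; ++b) {
            int r = rm[a * c.n + b];
            if (a != b && (r == 0 || r == 1 || r == 2)) c.adj[a].push_back(b);
        }
    c.blocked.assign(c.n, false);
    for (int v = 0; v < c.n; ++v) {
        std::fill(c.blocked.begin(), c.blocked.end(), false);
        c.blocked[v] = true;
        for (size_t i = 0; i < c.adj[v].size(); ++i) c.blocked[c.adj[v][i]] = true;
        std::vector<int> ext;
        for (size_t i = 0; i < c.adj[v].size(); ++i)
            if (c.adj[v][i] > v) ext.push_back(c.adj[v][i]);
        c.sub.assign(1, v);
        esu_extend(c, ext, v);
    }
    CharacterVector out(c.codes.size());
    for (size_t i = 0; i < c.codes.size(); ++i) out[i] = c.codes[i];
    return out;
}

// ---------------------------------------------------------------------------
// random connected-subgraph sampling: start at a uniform vertex, repeatedly
// add a uniform choice among I/O neighbors of the current set, stop at
// `size` vertices or when no neighbor exists. Returns one canonical code per
// iteration ("0" marks a singleton sample). Uses R's RNG.
// ---------------------------------------------------------------------------

static int unif_index(int k) {
    int r = (int)(unif_rand() * k);
    return (r >= k) ? k - 1 : r;
}

// [[Rcpp::export(name = ".sample_codes")]]
CharacterVector sample_codes(IntegerMatrix rel, int size, int m) {
    int n = rel.nrow();
    std::vector<int> rm(n * n);
    for (int a = 0; a < n; ++a)
        for (int b = 0; b < n; ++b)
            rm[a * n + b] = rel(a, b);
    std::vector<std::vector<int> > adj(n);
    for (int a = 0; a < n; ++a)
        for (int b = 0; b < n; ++b) {
            int r = rm[a * n + b];
            if (a != b && (r == 0 || r == 1 || r == 2)) adj[a].push_back(b);
        }
    CharacterVector out(m);
    std::vector<bool> inSet(n, false), inNbr(n, false);
    std::vector<int> set;
    std::vector<int> nbrs;
    for (int it = 0; it < m; ++it) {
        std::fill(inSet.begin(), inSet.end(), false);
        set.clear();
        int v = unif_index(n);
        set.push_back(v);
        inSet[v] = true;
        while ((int)set.size() < size) {
            nbrs.clear();
            std::fill(inNbr.begin(), inNbr.end(), false);
            for (size_t i = 0; i < set.size(); ++i)
                for (size_t j = 0; j < adj[set[i]].size(); ++j) {
                    int u = adj[set[i]][j];
                    if (!inSet[u] && !inNbr[u]) { inNbr[u] = true; nbrs.push_back(u); }
                }
            if (nbrs.empty()) break;
            int u = nbrs[unif_index((int)nbrs.size())];  // uniform over the neighbor SET
            set.push_back(u);
            inSet[u] = true;
        }
        int k = (int)set.size();
        std::vector<int> sub(k * k);
        for (int a = 0; a < k; ++a)
            for (int b = 0; b < k; ++b)
                sub[a * k + b] = rm[set[a] * n + set[b]];
        out[it] = min_code(sub.data(), k);
    }
    return out;
}
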