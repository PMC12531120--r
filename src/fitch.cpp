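#include <Rcpp.h>
using namespace Rcpp;

// Small parsimony for binary presence/absence characters by the Sankoff
// (min-cost) recursion with unit costs; exact on any (also multifurcating)
// rooted orientation, so the score is that of the unrooted tree.
//
// edge: 2-column integer matrix in postorder (parent, child), 1-based node
// ids with tips 1..nTip. tipStates: nTip x nChar matrix of 0/1.

static const int BIG = 1 << 28;

// [[Rcpp::export(name = ".fitchScoreCpp")]]
int fitchScoreCpp(IntegerMatrix edge, int nTip, IntegerMatrix tipStates) {
    int nChar = tipStates.ncol();
    int nEdge = edge.nrow();
    int nNode = 0;
    for (int e = 0; e < nEdge; ++e)
        nNode = std::max(nNode, std::max(edge(e, 0), edge(e, 1)));
    int root = edge(nEdge - 1, 0);
    std::vector<int> c0(nNode + 1), c1(nNode + 1);
    long total = 0;
    for (int ch = 0; ch < nChar; ++ch) {
        for (int v = 1; v <= nNode; ++v) {
            if (v <= nTip) {
                int s = tipStates(v - 1, ch);
                c0[v] = s == 0 ? 0 : BIG;
                c1[v] = s == 1 ? 0 : BIG;
            } else {
                c0[v] = 0;
                c1[v] = 0;
            }
        }
        for (int e = 0; e < nEdge; ++e) {
            int p = edge(e, 0), c = edge(e, 1);
            c0[p] += std::min(c0[c], c1[c] + 1);
            c1[p] += std::min(c1[c], c0[c] + 1);
        }
        total += std::min(c0[root], c1[root]);
    }
    return (int) total;
}

// [[Rcpp::export(name = ".fitchScoresManyCpp")]]
IntegerVector fitchScoresManyCpp(List edges, int nTip,
                                 IntegerMatrix tipStates) {
    int n = edges.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = fitchScoreCpp(as<IntegerMatrix>(edges[i]), nTip,
                               tipStates);
    return out;
}

// Per-edge change counts under one most-parsimonious reconstruction
// (top-down state choice: prefer the parent's state on ties; root prefers
// state 0, the ancestral absence state).
// [[Rcpp::export(name = ".fitchEdgeChangesCpp")]]
IntegerVector fitchEdgeChangesCpp(IntegerMatrix edge, int nTip,
                                  IntegerMatrix tipStates) {
    int nChar = tipStates.ncol();
    int nEdge = edge.nrow();
    int nNode = 0;
    for (int e = 0; e < nEdge; ++e)
        nNode = std::max(nNode, std::max(edge(e, 0), edge(e, 1)));
    int root = edge(nEdge - 1, 0);
    std::vector<int> c0(nNode + 1), c1(nNode + 1), st(nNode + 1);
    IntegerVector changes(nEdge);
    for (int ch = 0; ch < nChar; ++ch) {
        for (int v = 1; v <= nNode; ++v) {
            if (v <= nTip) {
                int s = tipStates(v - 1, ch);
                c0[v] = s == 0 ? 0 : BIG;
                c1[v] = s == 1 ? 0 : BIG;
            } else {
                c0[v] = 0;
                c1[v] = 0;
            }
        }
        for (int e = 0; e < nEdge; ++e) {
            int p = edge(e, 0), c = edge(e, 1);
            c0[p] += std::min(c0[c], c1[c] + 1);
            c1[p] += std::min(c1[c], c0[c] + 1);
        }
        st[root] = (c0[root] <= c1[root]) ? 0 : 1;
        for (int e = nEdge - 1; e >= 0; --e) {
            int p = edge(e, 0), c = edge(e, 1), sp = st[p];
            int stay = (sp == 0 ? c0[c] : c1[c]);
            int move = (sp == 0 ? c1[c] : c0[c]) + 1;
            if (move < stay) {
                st[c] = 1 - sp;
                changes[e] += 1;
            } else {
                st[c] = sp;
            }
        }
    }
    return changes;
}
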