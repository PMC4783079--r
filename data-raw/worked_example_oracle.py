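"""Independent brute-force oracle for the worked-example fixture.

Recomputes, from the literal fixture definition, every association
feature, the hit partition and the c1 enrichment profile, using naive
double loops and exact rational hypergeometric sums, then freezes them
as TSVs under inst/extdata/worked_example/.
"""
from fractions import Fraction
from math import comb
import os

OUT = os.path.join(os.path.dirname(__file__), "..", "inst", "extdata",
                   "worked_example")
os.makedirs(OUT, exist_ok=True)

fp = {
    "c1": set(range(0, 8)),
    "c2": set(range(0, 7)) | {8},
    "c3": set(range(0, 7)) | {9},
    "c4": set(range(0, 5)) | {8, 9, 10},
    "c5": set(range(8, 16)),
    "c6": set(range(4, 12)),
}
targets = {
    "c1": {"g01", "g02"},
    "c2": {"g02", "g03"},
    "c3": {"g01", "g03"},
    "c4": {"g04", "g05"},
    "c5": {"g05"},
}
expr = {  # (owner, context) -> (up, down)
    ("c1", "ctxA"): ({"g01", "g02", "g04"}, {"g11", "g14", "g15"}),
    ("c1", "ctxB"): ({"g01", "g03", "g05"}, {"g12", "g14", "g16"}),
    ("c2", "ctxA"): ({"g02", "g03", "g06"}, {"g11", "g12", "g17"}),
    ("c3", "ctxA"): ({"g01", "g06", "g07"}, {"g13", "g18", "g19"}),
    ("c4", "ctxA"): ({"g04", "g06", "g08"}, {"g15", "g17", "g20"}),
    ("c5", "ctxA"): ({"g05", "g07", "g09"}, {"g16", "g18", "g20"}),
    ("c6", "ctxA"): ({"g02", "g08", "g09"}, {"g13", "g19", "g20"}),
}
disease_sigs = [({"g01", "g02", "g03"}, {"g11", "g12", "g13"})]
kd = ["c1"]
cd = ["c1", "c2"]
compounds = ["c1", "c2", "c3", "c4", "c5", "c6"]
pathways = {
    "pwA": {"g01", "g02", "g03", "g04"},
    "pwB": {"g11", "g12", "g13", "g14"},
    "pwC": {"g05", "g06", "g07", "g08", "g09", "g10"},
}
universe = {f"g{i:02d}" for i in range(1, 21)}


def tanimoto(a, b):
    a, b = set(a), set(b)
    return len(a & b) / len(a | b)


def mean_pairwise(cs, rs):
    if not cs or not rs:
        return None
    vals = [tanimoto(a, b) for a in cs for b in rs]
    return sum(vals) / len(vals)


def combined_e(owner):
    return [up | dn for (o, _c), (up, dn) in sorted(expr.items()) if o == owner]


# disease-side pools (full pools: descriptive mode)
pool_S = [fp[d] for d in kd]
pool_T = [targets[d] for d in kd if d in targets]
pool_Ekd = [s for d in kd for s in combined_e(d)]
pool_Edis = [up | dn for up, dn in disease_sigs]

rows = []
for c in compounds:
    cs_S = [fp[c]] if c in fp else []
    cs_T = [targets[c]] if c in targets else []
    cs_E = combined_e(c)
    rows.append({
        "compound_id": c,
        "S_S": mean_pairwise(cs_S, pool_S),
        "T_T": mean_pairwise(cs_T, pool_T),
        "T_Ekd": mean_pairwise(cs_T, pool_Ekd),
        "T_Edis": mean_pairwise(cs_T, pool_Edis),
        "E_T": mean_pairwise(cs_E, pool_T),
        "E_Ekd": mean_pairwise(cs_E, pool_Ekd),
        "E_Edis": mean_pairwise(cs_E, pool_Edis),
    })

feat_names = ["S_S", "T_T", "T_Ekd", "T_Edis", "E_T", "E_Ekd", "E_Edis"]
with open(os.path.join(OUT, "features.tsv"), "w") as fh:
    fh.write("compound_id\t" + "\t".join(feat_names) + "\n")
    for r in rows:
        vals = ["NA" if r[f] is None else repr(r[f]) for f in feat_names]
        fh.write(r["compound_id"] + "\t" + "\t".join(vals) + "\n")

# ---- hit partition (analog_threshold 0.7 strict, min_analogs 2) ------
hits = ["c1", "c2", "c3", "c4"]
tested = compounds
core = [c for c in compounds if c in fp and c in targets and combined_e(c)]
scope_hits = [h for h in hits if h in core]
excluded = [h for h in scope_hits if h in kd]
rest = [h for h in scope_hits if h not in kd]
cat = {}
for h in rest:
    if h in cd:
        cat[h] = "anticancer"
    else:
        analogs = sum(1 for d in cd if tanimoto(fp[h], fp[d]) > 0.7)
        cat[h] = "anticancer" if analogs >= 2 else "novel"
with open(os.path.join(OUT, "partition.tsv"), "w") as fh:
    fh.write("compound_id\tcategory\n")
    for c in sorted(set(tested) & set(core)):
        if c in excluded:
            label = "excluded_known"
        elif c in cat:
            label = cat[c]
        elif c in scope_hits:
            label = "?"
        else:
            label = "nonhit"
        fh.write(f"{c}\t{label}\n")

# ---- enrichment profile for c1 (q_cutoff 0.1) ------------------------


def hyper_upper(k, K, n, N):
    """P(X >= k), exact rational."""
    if k <= 0:
        return Fraction(1)
    tot = Fraction(0)
    for j in range(k, min(K, n) + 1):
        tot += Fraction(comb(K, j) * comb(N - K, n - j), comb(N, n))
    return tot


def bh(ps):
    m = len(ps)
    order = sorted(range(m), key=lambda i: ps[i])
    q = [0.0] * m
    running = 1.0
    for rank_pos in range(m - 1, -1, -1):
        i = order[rank_pos]
        running = min(running, ps[i] * m / (rank_pos + 1))
        q[i] = running
    return q

c1_sigs = {"up": [expr[("c1", "ctxA")][0], expr[("c1", "ctxB")][0]],
           "down": [expr[("c1", "ctxA")][1], expr[("c1", "ctxB")][1]]}
ent = []
for pw_id in ["pwA", "pwB", "pwC"]:
    for direction in ["up", "down"]:
        ps, ks = [], []
        for sig in c1_sigs[direction]:
            sig_u = sig & universe
            pw_u = pathways[pw_id] & universe
            k = len(sig_u & pw_u)
            ks.append(k)
            ps.append(float(hyper_upper(k, len(pw_u), len(sig_u),
                                        len(universe))))
        m = len(ps)
        p_rep = m / sum(1.0 / p for p in ps)
        ent.append({"pathway_id": pw_id, "direction": direction,
                    "p_rep": p_rep, "overlap": max(ks)})
qs = bh([e["p_rep"] for e in ent])
for e, q in zip(ent, qs):
    e["q"] = q
    e["significant"] = q < 0.1
with open(os.path.join(OUT, "enrichment_c1.tsv"), "w") as fh:
    fh.write("pathway_id\tdirection\tp_rep\tq\toverlap\tsignificant\n")
    for e in ent:
        fh.write("\t".join([e["pathway_id"], e["direction"],
                            repr(e["p_rep"]), repr(e["q"]),
                            str(e["overlap"]),
                            "TRUE" if e["significant"] else "FALSE"]) + "\n")

print("written to", OUT)
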