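"""JSON-lines chemistry worker.

Reads one JSON request per line on stdin ({"op": ..., "args": {...}}) and
writes one JSON response per line on stdout. All molecular heavy lifting for
the R package lives here so that R never needs a cheminformatics toolkit of
its own. The worker is stateless apart from caches; it performs no I/O other
than stdin/stdout and uses no randomness, so results are fully deterministic.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Crippen, DataStructs, Descriptors
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

_MOL_CACHE = {}
_RXN_CACHE = {}
_PATT_CACHE = {}


def _mol(smiles):
    if smiles in _MOL_CACHE:
        return _MOL_CACHE[smiles]
    m = Chem.MolFromSmiles(smiles) if isinstance(smiles, str) else None
    if len(_MOL_CACHE) > 200000:
        _MOL_CACHE.clear()
    _MOL_CACHE[smiles] = m
    return m


def _rxn(smarts):
    if smarts in _RXN_CACHE:
        return _RXN_CACHE[smarts]
    try:
        r = AllChem.ReactionFromSmarts(smarts)
        if r is not None:
            r.Initialize()
    except Exception:
        r = None
    _RXN_CACHE[smarts] = r
    return r


def _patt(smarts):
    if smarts in _PATT_CACHE:
        return _PATT_CACHE[smarts]
    p = Chem.MolFromSmarts(smarts) if isinstance(smarts, str) else None
    _PATT_CACHE[smarts] = p
    return p


def op_ping(args):
    import rdkit

    return {"ok": True, "rdkit": rdkit.__version__}


def op_canon(args):
    out = []
    for s in args["smiles"]:
        m = _mol(s)
        out.append(Chem.MolToSmiles(m) if m is not None else None)
    return {"r": out}


def op_substruct(args):
    patts = []
    for p in args["patterns"]:
        q = _patt(p)
        if q is None:
            return {"error": "bad pattern: %s" % p}
        patts.append(q)
    rows = []
    for s in args["smiles"]:
        m = _mol(s)
        rows.append(None if m is None else [m.HasSubstructMatch(q) for q in patts])
    return {"r": rows}


def op_rxn_info(args):
    out = []
    for s in args["smarts"]:
        r = _rxn(s)
        if r is None:
            out.append({"ok": False, "error": "unparsable reaction SMARTS"})
        else:
            out.append(
                {
                    "ok": True,
                    "n_reactants": r.GetNumReactantTemplates(),
                    "n_products": r.GetNumProductTemplates(),
                }
            )
    return {"r": out}


def op_match_slots(args):
    """For each molecule x each reaction: 0-based reactant slots it matches."""
    rxns = []
    for s in args["rxns"]:
        r = _rxn(s)
        if r is None:
            return {"error": "unparsable reaction SMARTS: %s" % s}
        rxns.append(r)
    rows = []
    for s in args["smiles"]:
        m = _mol(s)
        if m is None:
            rows.append(None)
            continue
        per_rxn = []
        for r in rxns:
            hits = [
                i
                for i in range(r.GetNumReactantTemplates())
                if m.HasSubstructMatch(r.GetReactantTemplate(i))
            ]
            per_rxn.append(hits)
        rows.append(per_rxn)
    return {"r": rows}


def op_react(args):
    """Forward-apply one reaction SMARTS to each ordered reactant tuple.

    Returns, per tuple, the sorted set of distinct canonical products over all
    symmetry-equivalent match sites; products that fail sanitization are
    dropped. ok=False when a reactant does not parse.
    """
    r = _rxn(args["smarts"])
    if r is None:
        return {"error": "unparsable reaction SMARTS: %s" % args["smarts"]}
    n = r.GetNumReactantTemplates()
    out = []
    for tup in args["tuples"]:
        mols = [_mol(s) for s in tup]
        if len(mols) != n or any(m is None for m in mols):
            out.append({"ok": False, "products": []})
            continue
        prods = set()
        try:
            results = r.RunReactants(mols)
        except Exception:
            results = []
        for ptup in results:
            for p in ptup:
                try:
                    Chem.SanitizeMol(p)
                    prods.add(Chem.MolToSmiles(p))
                except Exception:
                    pass
        out.append({"ok": True, "products": sorted(prods)})
    return {"r": out}


def op_morgan(args):
    radius = int(args["radius"])
    n_bits = int(args["n_bits"])
    out = []
    for s in args["smiles"]:
        m = _mol(s)
        if m is None:
            out.append(None)
        else:
            fp = AllChem.GetMorganFingerprintAsBitVect(m, radius, nBits=n_bits)
            out.append(list(fp.GetOnBits()))
    return {"r": out}


def op_murcko(args):
    out = []
    for s in args["smiles"]:
        m = _mol(s)
        if m is None:
            out.append(None)
        else:
            sc = MurckoScaffold.GetScaffoldForMol(m)
            out.append(Chem.MolToSmiles(sc) if sc is not None else "")
    return {"r": out}


def op_gobbi(args):
    from rdkit.Chem.Pharm2D import Generate, Gobbi_Pharm2D

    out = []
    for s in args["smiles"]:
        m = _mol(s)
        if m is None:
            out.append(None)
        else:
            fp = Generate.Gen2DFingerprint(m, Gobbi_Pharm2D.factory)
            out.append(sorted(fp.GetOnBits()))
    return {"r": out}


def op_lipinski(args):
    out = []
    for s in args["smiles"]:
        m = _mol(s)
        if m is None:
            out.append(None)
        else:
            out.append(
                Descriptors.MolWt(m) <= 500.0
                and Crippen.MolLogP(m) <= 5.0
                and Chem.Lipinski.NumHDonors(m) <= 5
                and Chem.Lipinski.NumHAcceptors(m) <= 10
            )
    return {"r": out}


def op_tanimoto(args):
    """Reference Tanimoto via RDKit DataStructs (used as an independent oracle)."""
    radius = int(args["radius"])
    n_bits = int(args["n_bits"])
    out = []
    for a, b in zip(args["a"], args["b"]):
        ma, mb = _mol(a), _mol(b)
        if ma is None or mb is None:
            out.append(None)
            continue
        fa = AllChem.GetMorganFingerprintAsBitVect(ma, radius, nBits=n_bits)
        fb = AllChem.GetMorganFingerprintAsBitVect(mb, radius, nBits=n_bits)
        out.append(DataStructs.TanimotoSimilarity(fa, fb))
    return {"r": out}


OPS = {
    "ping": op_ping,
    "canon": op_canon,
    "substruct": op_substruct,
    "rxn_info": op_rxn_info,
    "match_slots": op_match_slots,
    "react": op_react,
    "morgan": op_morgan,
    "murcko": op_murcko,
    "gobbi": op_gobbi,
    "lipinski": op_lipinski,
    "tanimoto": op_tanimoto,
}


def main():
    out = sys.stdout
    for line in iter(sys.stdin.readline, ""):
        line = line.strip()
        if not line:
            continue
        try:
            req = json.loads(line)
            fn = OPS.get(req.get("op"))
            if fn is None:
                res = {"error": "unknown op: %r" % req.get("op")}
            else:
                res = fn(req.get("args") or {})
        except Exception as exc:  # never die on a bad request
            res = {"error": "%s: %s" % (type(exc).__name__, exc)}
        out.write(json.dumps(res))
        out.write("\n")
        out.flush()


if __name__ == "__main__":
    main()
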