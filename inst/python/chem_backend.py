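"""Batched chemistry primitives for the oximescreen R package.

Reads one JSON request on stdin, writes one JSON response on stdout.
Every command is vectorised over molecules so R pays the interpreter
start-up cost once per batch, not once per molecule.

Request:  {"cmd": <name>, ...payload}
Response: {"ok": true, ...result} | {"ok": false, "error": <msg>}
"""

import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors
import rdkit

RDLogger.DisableLog("rdApp.*")

OXIME_SMARTS = Chem.MolFromSmarts("[CX3]=[NX2][OX2H1]")


def _parse(smiles):
    if not isinstance(smiles, str) or smiles == "":
        return None
    return Chem.MolFromSmiles(smiles)


def cmd_version(req):
    return {"rdkit_version": rdkit.__version__}


def cmd_canon(req):
    out, errors = [], []
    for i, s in enumerate(req["smiles"]):
        mol = _parse(s)
        if mol is None:
            out.append(None)
            errors.append({"index": i + 1, "smiles": s,
                           "message": "unparseable SMILES"})
        else:
            out.append(Chem.MolToSmiles(mol))
    return {"canonical": out, "errors": errors}


def _descriptor_names():
    # the toolkit's full 2D battery, in its native (version-pinned) order,
    # plus the oxime-group count the screening models need
    return [name for name, _ in Descriptors._descList] + ["NumOximeGroups"]


def cmd_descriptor_names(req):
    return {"names": _descriptor_names()}


def cmd_descriptors(req):
    names = _descriptor_names()
    rows, errors = [], []
    for i, s in enumerate(req["smiles"]):
        mol = _parse(s)
        if mol is None:
            rows.append(None)
            errors.append({"index": i + 1, "smiles": s,
                           "message": "unparseable SMILES"})
            continue
        vals = Descriptors.CalcMolDescriptors(mol)
        row = [vals[n] for n in names[:-1]]
        row.append(float(len(mol.GetSubstructMatches(OXIME_SMARTS))))
        bad = [names[j] for j, v in enumerate(row)
               if v is None or not math.isfinite(float(v))]
        if bad:
            rows.append(None)
            errors.append({"index": i + 1, "smiles": s,
                           "message": "non-finite descriptor(s): "
                           + ", ".join(bad)})
        else:
            rows.append([float(v) for v in row])
    return {"names": names, "rows": rows, "errors": errors}


def cmd_sdf_read(req):
    """Parse SDF text into (name, canonical SMILES) records."""
    supplier = Chem.SDMolSupplier()
    supplier.SetData(req["sdf_text"], sanitize=True, removeHs=True)
    records, errors = [], []
    for i, mol in enumerate(supplier):
        if mol is None:
            errors.append({"index": i + 1, "message": "unparseable record"})
            continue
        name = mol.GetProp("_Name") if mol.HasProp("_Name") else ""
        records.append({"index": i + 1, "name": name,
                        "smiles": Chem.MolToSmiles(mol)})
    return {"records": records, "errors": errors}


def cmd_substruct_count(req):
    patt = Chem.MolFromSmarts(req["smarts"])
    if patt is None:
        raise ValueError("unparseable SMARTS: %s" % req["smarts"])
    counts = []
    for s in req["smiles"]:
        mol = _parse(s)
        if mol is None:
            counts.append(None)
        else:
            counts.append(len(mol.GetSubstructMatches(patt)))
    return {"counts": counts}


def cmd_graphs(req):
    """Atom/bond tables (1-based indices) for graph walks on the R side."""
    mols = []
    for s in req["smiles"]:
        mol = _parse(s)
        if mol is None:
            mols.append(None)
            continue
        atoms = [{
            "index": a.GetIdx() + 1,
            "symbol": a.GetSymbol(),
            "charge": a.GetFormalCharge(),
            "aromatic": a.GetIsAromatic(),
            "in_ring": a.IsInRing(),
            "n_h": a.GetTotalNumHs(),
            "degree": a.GetDegree(),
        } for a in mol.GetAtoms()]
        bonds = [{
            "a": b.GetBeginAtomIdx() + 1,
            "b": b.GetEndAtomIdx() + 1,
            "order": b.GetBondTypeAsDouble(),
            "aromatic": b.GetIsAromatic(),
        } for b in mol.GetBonds()]
        mols.append({"atoms": atoms, "bonds": bonds})
    return {"mols": mols}


def cmd_cut_fragments(req):
    """Cut the listed bonds and return dummy-capped fragment SMILES.

    jobs: [{"smiles": s, "cuts": [[a, b], ...]}]  (1-based atom indices;
    for each cut, atom `a` stays on the core side, `b` on the fragment side)
    Each returned fragment is rooted at one of its dummy atoms so the SMILES
    string starts with the attachment point; `cut_ids` says which cuts its
    dummies correspond to (1-based into the job's cut list).
    """
    results = []
    for job in req["jobs"]:
        mol = _parse(job["smiles"])
        if mol is None:
            results.append({"error": "unparseable SMILES"})
            continue
        cuts = job["cuts"]
        bond_ids = []
        err = None
        for a, b in cuts:
            bond = mol.GetBondBetweenAtoms(a - 1, b - 1)
            if bond is None:
                err = "cut does not name an existing bond"
                break
            if bond.GetIsAromatic():
                err = ("cut bond %d-%d is aromatic; fused aromatic "
                       "substituents are not decomposable" % (a, b))
                break
            bond_ids.append(bond.GetIdx())
        if err is not None:
            results.append({"error": err})
            continue
        # label each dummy with (cut id, cut id) so fragments know which
        # attachment they carry; isotopes encode the label
        labels = [(i + 1, i + 1) for i in range(len(cuts))]
        frag_mol = Chem.FragmentOnBonds(mol, bond_ids, addDummies=True,
                                        dummyLabels=labels)
        frags = Chem.GetMolFrags(frag_mol, asMols=True, sanitizeFrags=True)
        frag_out = []
        for fm in frags:
            dummies = [a for a in fm.GetAtoms() if a.GetAtomicNum() == 0]
            cut_ids = sorted(a.GetIsotope() for a in dummies)
            pairs = [(a.GetIdx(), a.GetIsotope()) for a in dummies]
            for a in dummies:
                a.SetIsotope(0)
            rooted = [{"cut_id": iso,
                       "smiles": Chem.MolToSmiles(fm, rootedAtAtom=idx,
                                                  canonical=True)}
                      for idx, iso in pairs]
            frag_out.append({
                "smiles": rooted[0]["smiles"] if rooted
                else Chem.MolToSmiles(fm),
                "canonical": Chem.MolToSmiles(fm),
                "cut_ids": cut_ids,
                "rooted": rooted,
                "n_dummies": len(dummies),
            })
        results.append({"fragments": frag_out})
    return {"results": results}


COMMANDS = {
    "version": cmd_version,
    "canon": cmd_canon,
    "descriptor_names": cmd_descriptor_names,
    "descriptors": cmd_descriptors,
    "sdf_read": cmd_sdf_read,
    "substruct_count": cmd_substruct_count,
    "graphs": cmd_graphs,
    "cut_fragments": cmd_cut_fragments,
}


def main():
    req = json.load(sys.stdin)
    cmd = req.get("cmd")
    if cmd not in COMMANDS:
        json.dump({"ok": False, "error": "unknown command: %r" % cmd},
                  sys.stdout)
        return
    try:
        res = COMMANDS[cmd](req)
    except Exception as exc:  # surfaced as an R error by the caller
        json.dump({"ok": False, "error": str(exc)}, sys.stdout)
        return
    res["ok"] = True
    json.dump(res, sys.stdout)


if __name__ == "__main__":
    main()
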