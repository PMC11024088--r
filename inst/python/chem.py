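"""RDKit worker: structure properties, Morgan bits, 2D descriptors.

Called as:  python chem.py <command> <request.json> <response.json>
Commands:
  props        {"smiles": [...]} ->
               per molecule: canonical smiles, average MW, fragment count,
               organic-subset flag, validity
  morgan       {"smiles": [...], "radius": r, "n_bits": m} -> bit strings
  descriptors2d {"smiles": [...]} -> RDKit 2D descriptor table (NaN -> null)
"""
import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors

RDLogger.DisableLog("rdApp.*")

ORGANIC_SUBSET = {"H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"}


def _mol(smi):
    if not isinstance(smi, str) or not smi.strip():
        return None
    return Chem.MolFromSmiles(smi)


def cmd_props(req):
    out = []
    for smi in req["smiles"]:
        mol = _mol(smi)
        if mol is None:
            out.append({"valid": False})
            continue
        frags = Chem.GetMolFrags(mol)
        organic = all(a.GetSymbol() in ORGANIC_SUBSET for a in mol.GetAtoms())
        out.append({
            "valid": True,
            "canonical_smiles": Chem.MolToSmiles(mol),
            "mw": Descriptors.MolWt(mol),
            "n_fragments": len(frags),
            "organic": organic,
        })
    return {"records": out}


def cmd_morgan(req):
    radius = int(req["radius"])
    n_bits = int(req["n_bits"])
    gen = AllChem.GetMorganGenerator(radius=radius, fpSize=n_bits)
    out = []
    for smi in req["smiles"]:
        mol = _mol(smi)
        if mol is None:
            out.append(None)
            continue
        out.append(gen.GetFingerprint(mol).ToBitString())
    return {"bits": out}


def cmd_descriptors2d(req):
    names = [n for n, _ in Descriptors.descList]
    rows = []
    valid = []
    for smi in req["smiles"]:
        mol = _mol(smi)
        if mol is None:
            valid.append(False)
            rows.append([None] * len(names))
            continue
        valid.append(True)
        vals = []
        for _, fn in Descriptors.descList:
            try:
                v = fn(mol)
                if v is None or (isinstance(v, float) and not math.isfinite(v)):
                    v = None
            except Exception:
                v = None
            vals.append(v)
        rows.append(vals)
    return {"names": names, "rows": rows, "valid": valid}


def main():
    command, req_path, res_path = sys.argv[1], sys.argv[2], sys.argv[3]
    with open(req_path) as fh:
        req = json.load(fh)
    handler = {"props": cmd_props,
               "morgan": cmd_morgan,
               "descriptors2d": cmd_descriptors2d}[command]
    res = handler(req)
    with open(res_path, "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main()
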