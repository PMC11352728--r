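"""rdkit helpers behind the R API: Morgan (circular) fingerprints and
deterministic SMILES-to-3D embedding.  Invoked as

    python chemtools.py <command> <request.json> <response.json>

with JSON payloads on both sides.  Kept dependency-minimal: rdkit + stdlib.
"""
import json
import sys

from rdkit import Chem
from rdkit.Chem import AllChem


def cmd_ecfp(req):
    radius = int(req.get("radius", 2))
    n_bits = int(req.get("n_bits", 512))
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            return {"error": f"unparsable SMILES: {smi!r}"}
        fp = AllChem.GetMorganFingerprintAsBitVect(mol, radius, nBits=n_bits)
        out.append([int(b) for b in fp.ToBitString()])
    return {"bits": out, "n_bits": n_bits}


def cmd_embed(req):
    smi = req["smiles"]
    seed = int(req.get("seed", 1))
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"error": f"unparsable SMILES: {smi!r}"}
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    if AllChem.EmbedMolecule(mol, params) != 0:
        return {"error": f"3D embedding failed for {smi!r}"}
    try:
        AllChem.MMFFOptimizeMolecule(mol)
    except Exception:
        pass  # unrelaxed distance-geometry coordinates are still usable
    conf = mol.GetConformer()
    elements = [a.GetSymbol() for a in mol.GetAtoms()]
    coords = [[conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y,
               conf.GetAtomPosition(i).z] for i in range(mol.GetNumAtoms())]
    double_cc = [
        [b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1]
        for b in mol.GetBonds()
        if b.GetBondType() == Chem.BondType.DOUBLE
        and b.GetBeginAtom().GetSymbol() == "C"
        and b.GetEndAtom().GetSymbol() == "C"
    ]
    return {"elements": elements, "coords": coords,
            "double_cc_bonds": double_cc, "charge": Chem.GetFormalCharge(mol)}


def main():
    cmd, req_path, resp_path = sys.argv[1], sys.argv[2], sys.argv[3]
    with open(req_path) as fh:
        req = json.load(fh)
    fn = {"ecfp": cmd_ecfp, "embed": cmd_embed}[cmd]
    resp = fn(req)
    with open(resp_path, "w") as fh:
        json.dump(resp, fh)


if __name__ == "__main__":
    main()
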