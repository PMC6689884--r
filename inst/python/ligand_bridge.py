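"""Ligand chemistry bridge for the vgnp R package.

Reads a JSON array of ligand requests from argv[1], writes a JSON array of
results to argv[2].  Each request:

    {"ligand_id": str,
     "structure": str,            # SMILES or MOL/SDF block text
     "format": "smiles"|"molfile",
     "seed": int,                 # distance-geometry embedding seed
     "attachment_smarts": str}    # substructure pattern for the anchor atom

Each result carries column-wise atom arrays (element, x, y, z, aromatic,
formal_charge, crippen_logp), column-wise bonds (i, j, order, aromatic;
1-based), 1-based candidate attachment indices in atom-numbering order, and
the whole-molecule Crippen logP.  Failures are reported per ligand as
{"ligand_id": ..., "error": "parse"|"embed"|"smarts", "detail": ...} so the
R side can raise a classed condition naming the ligand.

Atom numbering convention: heavy atoms keep their input order; explicit
hydrogens are appended by AddHs.  This is the canonical ordering documented
for attachment-atom tie-breaking.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Crippen, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def embed(mol, seed):
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed)
    return AllChem.EmbedMolecule(mol, params)


def process(req):
    lid = req.get("ligand_id", "?")
    fmt = req.get("format", "smiles")
    structure = req["structure"]
    seed = int(req.get("seed", 42))

    if fmt == "smiles":
        mol = Chem.MolFromSmiles(structure)
        if mol is None:
            return {"ligand_id": lid, "error": "parse",
                    "detail": "unparsable SMILES"}
        mol = Chem.AddHs(mol)
        if embed(mol, seed) != 0:
            return {"ligand_id": lid, "error": "embed",
                    "detail": "distance-geometry embedding failed"}
    elif fmt == "molfile":
        mol = Chem.MolFromMolBlock(structure, removeHs=False)
        if mol is None:
            return {"ligand_id": lid, "error": "parse",
                    "detail": "unparsable MOL/SDF block"}
        has3d = mol.GetNumConformers() > 0 and mol.GetConformer().Is3D()
        mol = Chem.AddHs(mol, addCoords=has3d)
        if not has3d and embed(mol, seed) != 0:
            return {"ligand_id": lid, "error": "embed",
                    "detail": "distance-geometry embedding failed"}
    else:
        return {"ligand_id": lid, "error": "parse",
                "detail": "unknown format %r" % fmt}

    contribs = rdMolDescriptors._CalcCrippenContribs(mol)
    conf = mol.GetConformer()
    n = mol.GetNumAtoms()
    atoms = {"element": [], "x": [], "y": [], "z": [],
             "aromatic": [], "formal_charge": [], "crippen_logp": []}
    for a in mol.GetAtoms():
        p = conf.GetAtomPosition(a.GetIdx())
        atoms["element"].append(a.GetSymbol())
        atoms["x"].append(p.x)
        atoms["y"].append(p.y)
        atoms["z"].append(p.z)
        atoms["aromatic"].append(a.GetIsAromatic())
        atoms["formal_charge"].append(a.GetFormalCharge())
        atoms["crippen_logp"].append(contribs[a.GetIdx()][0])

    bonds = {"i": [], "j": [], "order": [], "aromatic": []}
    for b in mol.GetBonds():
        bonds["i"].append(b.GetBeginAtomIdx() + 1)
        bonds["j"].append(b.GetEndAtomIdx() + 1)
        bonds["order"].append(b.GetBondTypeAsDouble())
        bonds["aromatic"].append(b.GetIsAromatic())

    smarts = req.get("attachment_smarts") or ""
    matches = []
    if smarts:
        patt = Chem.MolFromSmarts(smarts)
        if patt is None:
            return {"ligand_id": lid, "error": "smarts",
                    "detail": "invalid SMARTS %r" % smarts}
        matches = sorted({m[0] + 1 for m in mol.GetSubstructMatches(patt)})

    return {"ligand_id": lid, "n_atoms": n, "atoms": atoms, "bonds": bonds,
            "attachment_matches": matches,
            "mol_logp": Crippen.MolLogP(mol), "seed": seed}


def main():
    with open(sys.argv[1]) as fh:
        requests = json.load(fh)
    results = [process(r) for r in requests]
    with open(sys.argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
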