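"""RDKit bridge for the orcoscreen R package.

Called as:  python mol_bridge.py <mode> <in.json> <out.json>

Modes
-----
parse     : SMILES -> heavy-atom molecular graphs + per-atom Crippen logP
            contributions and approximate per-atom van der Waals surface
            areas (Labute ASA, heavy atoms carry their implicit-H share).
embed     : SMILES -> seeded ETKDGv3 conformer ensembles (heavy-atom
            coordinates, RMSD-deduplicated).
extended  : SMILES -> one conformer with every acyclic heavy-atom torsion
            set to 180 degrees (all-anti, "fully extended").
read      : read a SMILES list or SDF V2000 file; invalid records are
            skipped and counted. SDF conformers are retained.
write_sdf : write molecules (+ optional conformers) to an SDF file.

All payloads are JSON. The bridge contains no science: descriptor math,
feature annotation and matching all live on the R side.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdMolDescriptors, rdMolTransforms

RDLogger.DisableLog("rdApp.*")


def _graph(mol):
    """Heavy-atom graph with per-atom Crippen/VSA parameters."""
    mol = Chem.RemoveHs(mol)
    crippen = rdMolDescriptors._CalcCrippenContribs(mol)
    # Labute approximate VSA; index 0 of the returned tuple is the H share
    vsa = list(rdMolDescriptors._CalcLabuteASAContribs(mol)[0])
    atoms = []
    for atom, (logp, _mr) in zip(mol.GetAtoms(), crippen):
        atoms.append({
            "element": atom.GetSymbol(),
            "aromatic": atom.GetIsAromatic(),
            "hyb": str(atom.GetHybridization()),
            "charge": atom.GetFormalCharge(),
            "degree": atom.GetDegree(),
            "n_h": atom.GetTotalNumHs(),
            "in_ring": atom.IsInRing(),
            "crippen_logp": logp,
            "vsa": vsa[atom.GetIdx()],
        })
    bonds = [{
        "i": b.GetBeginAtomIdx() + 1,   # 1-based for R
        "j": b.GetEndAtomIdx() + 1,
        "order": b.GetBondTypeAsDouble(),
        "aromatic": b.GetIsAromatic(),
    } for b in mol.GetBonds()]
    return {
        "smiles_canonical": Chem.MolToSmiles(mol),
        "n_heavy": mol.GetNumHeavyAtoms(),
        "atoms": atoms,
        "bonds": bonds,
    }


def mode_parse(payload):
    out = []
    for smi in payload["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        out.append(None if mol is None else _graph(mol))
    return {"graphs": out}


def _heavy_coords(mol, conf_id):
    conf = mol.GetConformer(conf_id)
    return [[conf.GetAtomPosition(a.GetIdx()).x,
             conf.GetAtomPosition(a.GetIdx()).y,
             conf.GetAtomPosition(a.GetIdx()).z]
            for a in mol.GetAtoms() if a.GetAtomicNum() > 1]


def _heavy_index_map(molh):
    """Positions of heavy atoms in the H-included molecule, in heavy order."""
    return [a.GetIdx() for a in molh.GetAtoms() if a.GetAtomicNum() > 1]


def mode_embed(payload):
    n = int(payload.get("n", 100))
    seed = int(payload.get("seed", 2024))
    rms = float(payload.get("dedup_rms", 0.5))
    optimize = bool(payload.get("optimize", True))
    out = []
    for smi in payload["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"error": "unparsable SMILES"})
            continue
        molh = Chem.AddHs(mol)
        params = AllChem.ETKDGv3()
        params.randomSeed = seed
        params.pruneRmsThresh = rms
        params.useRandomCoords = False
        ids = AllChem.EmbedMultipleConfs(molh, numConfs=n, params=params)
        if len(ids) == 0:
            # retry with random coordinates before giving up
            params.useRandomCoords = True
            ids = AllChem.EmbedMultipleConfs(molh, numConfs=n, params=params)
        if len(ids) == 0:
            out.append({"error": "embedding failed"})
            continue
        if optimize:
            AllChem.MMFFOptimizeMoleculeConfs(molh, maxIters=500)
        heavy = _heavy_index_map(molh)
        confs = []
        for cid in ids:
            conf = molh.GetConformer(cid)
            confs.append([[conf.GetAtomPosition(i).x,
                           conf.GetAtomPosition(i).y,
                           conf.GetAtomPosition(i).z] for i in heavy])
        out.append({"conformers": confs})
    return {"ensembles": out}


def mode_extended(payload):
    seed = int(payload.get("seed", 2024))
    out = []
    for smi in payload["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"error": "unparsable SMILES"})
            continue
        molh = Chem.AddHs(mol)
        params = AllChem.ETKDGv3()
        params.randomSeed = seed
        if AllChem.EmbedMolecule(molh, params) != 0:
            out.append({"error": "embedding failed"})
            continue
        AllChem.MMFFOptimizeMolecule(molh, maxIters=500)
        conf = molh.GetConformer()
        for b in molh.GetBonds():
            if b.GetBondType() != Chem.BondType.SINGLE or b.IsInRing():
                continue
            i, j = b.GetBeginAtom(), b.GetEndAtom()
            if i.GetAtomicNum() == 1 or j.GetAtomicNum() == 1:
                continue
            ni = [a for a in i.GetNeighbors()
                  if a.GetIdx() != j.GetIdx() and a.GetAtomicNum() > 1]
            nj = [a for a in j.GetNeighbors()
                  if a.GetIdx() != i.GetIdx() and a.GetAtomicNum() > 1]
            if not ni or not nj:
                continue
            try:
                rdMolTransforms.SetDihedralDeg(
                    conf, ni[0].GetIdx(), i.GetIdx(), j.GetIdx(),
                    nj[0].GetIdx(), 180.0)
            except ValueError:
                pass  # torsion through colinear atoms; leave as embedded
        heavy = _heavy_index_map(molh)
        out.append({"conformer": [[conf.GetAtomPosition(i).x,
                                   conf.GetAtomPosition(i).y,
                                   conf.GetAtomPosition(i).z]
                                  for i in heavy]})
    return {"conformers": out}


def mode_read(payload):
    path = payload["path"]
    fmt = payload["format"]
    records, skipped = [], 0
    if fmt == "smiles_list":
        with open(path) as fh:
            for line in fh:
                line = line.strip()
                if not line:
                    continue
                parts = line.split(None, 1)
                mol = Chem.MolFromSmiles(parts[0])
                if mol is None:
                    skipped += 1
                    continue
                records.append({
                    "id": parts[1].strip() if len(parts) > 1 else None,
                    "smiles": Chem.MolToSmiles(mol),
                    "conformer": None,
                })
    elif fmt == "sdf":
        supplier = Chem.SDMolSupplier(path, removeHs=False, sanitize=True)
        for mol in supplier:
            if mol is None:
                skipped += 1
                continue
            name = mol.GetProp("_Name") if mol.HasProp("_Name") else None
            conformer = None
            if mol.GetNumConformers() > 0:
                conformer = _heavy_coords(Chem.RemoveHs(mol), 0)
            records.append({
                "id": name or None,
                "smiles": Chem.MolToSmiles(Chem.RemoveHs(mol)),
                "conformer": conformer,
            })
    else:
        raise ValueError("unknown format: %s" % fmt)
    return {"records": records, "skipped": skipped}


def mode_write_sdf(payload):
    writer = Chem.SDWriter(payload["path"])
    n = 0
    for rec in payload["records"]:
        mol = Chem.MolFromSmiles(rec["smiles"])
        if mol is None:
            continue
        mol.SetProp("_Name", str(rec.get("id") or ""))
        conformer = rec.get("conformer")
        if conformer:
            conf = Chem.Conformer(mol.GetNumAtoms())
            for i, xyz in enumerate(conformer):
                conf.SetAtomPosition(i, tuple(float(v) for v in xyz))
            mol.AddConformer(conf, assignId=True)
        writer.write(mol)
        n += 1
    writer.close()
    return {"written": n}


MODES = {
    "parse": mode_parse,
    "embed": mode_embed,
    "extended": mode_extended,
    "read": mode_read,
    "write_sdf": mode_write_sdf,
}


def main(argv):
    mode, fin, fout = argv[1], argv[2], argv[3]
    with open(fin) as fh:
        payload = json.load(fh)
    result = MODES[mode](payload)
    with open(fout, "w") as fh:
        json.dump(result, fh)


if __name__ == "__main__":
    main(sys.argv)
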