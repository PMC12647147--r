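"""Seeded 3D conformer embedding for the chemformer R package.

Reads a tab-separated file of (id, smiles) pairs, embeds one conformer per
molecule with distance geometry (ETKDG) and optimizes it with a classical
force field (UFF by default, MMFF94 optional), then writes an SDF with
explicit hydrogens.  Embedding is deterministic for a fixed seed.

Molecules whose 3D embedding fails fall back to a planar 2D layout with
z = 0; the SD tag ``cf_fallback`` records this.  Molecules that do not parse
are skipped entirely (the caller handles them).

Usage: python embed_conformers.py IN_TSV OUT_SDF SEED FORCEFIELD
"""

import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def embed_one(mol, seed, forcefield):
    mol = Chem.AddHs(mol)
    ok = AllChem.EmbedMolecule(mol, randomSeed=seed, useRandomCoords=False)
    if ok != 0:
        ok = AllChem.EmbedMolecule(mol, randomSeed=seed, useRandomCoords=True)
    if ok == 0:
        try:
            if forcefield == "mmff94":
                AllChem.MMFFOptimizeMolecule(mol, maxIters=500)
            else:
                AllChem.UFFOptimizeMolecule(mol, maxIters=500)
        except Exception:
            pass
        return mol, 0
    AllChem.Compute2DCoords(mol)
    return mol, 1


def main(in_tsv, out_sdf, seed, forcefield):
    writer = Chem.SDWriter(out_sdf)
    writer.SetKekulize(True)
    with open(in_tsv) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            rec_id, smiles = line.split("\t", 1)
            mol = Chem.MolFromSmiles(smiles)
            if mol is None or mol.GetNumHeavyAtoms() == 0:
                continue
            mol, fallback = embed_one(mol, seed, forcefield)
            heavy = [a for a in mol.GetAtoms() if a.GetAtomicNum() > 1]
            mol.SetProp("_Name", rec_id)
            mol.SetProp("cf_fallback", str(fallback))
            mol.SetProp("cf_nh", ",".join(str(a.GetTotalNumHs(includeNeighbors=True)) for a in heavy))
            mol.SetProp("cf_chg", ",".join(str(a.GetFormalCharge()) for a in heavy))
            writer.write(mol)
    writer.close()


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2], int(sys.argv[3]), sys.argv[4])
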