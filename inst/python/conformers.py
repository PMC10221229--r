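"""Conformer-ensemble generation backend.

Reads a JSON job description, embeds each molecule with ETKDGv3 under a
fixed random seed, minimises every conformer with MMFF94 (UFF fallback),
filters to an energy window above the ensemble minimum, deduplicates by
heavy-atom RMSD and writes the surviving conformers to a multi-record SDF
with per-record properties.  Called by the R side; not a public interface.

Usage: python conformers.py <job.json> <out.sdf> <meta.json>
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem
from rdkit.Chem import rdMolAlign

RDLogger.DisableLog("rdApp.*")

KCAL_TO_KJ = 4.184


def heavy_rms(mol, ci, cj):
    """Symmetry-aware best RMSD between two conformers, heavy atoms only."""
    noh = Chem.RemoveHs(Chem.Mol(mol))
    return rdMolAlign.GetBestRMS(noh, noh, prbId=ci, refId=cj, maxMatches=2000)


def process(entry, cfg):
    mol = Chem.MolFromSmiles(entry["smiles"])
    if mol is None:
        return None, {"id": entry["id"], "status": "parse_error"}
    mol = Chem.AddHs(mol)

    params = AllChem.ETKDGv3()
    params.randomSeed = int(cfg["seed"])
    params.useRandomCoords = False
    n_target = int(cfg["target_count"])
    # oversample so the window/dedup filters still leave enough conformers
    cids = AllChem.EmbedMultipleConfs(mol, numConfs=2 * n_target, params=params)
    if len(cids) == 0:
        params.useRandomCoords = True
        cids = AllChem.EmbedMultipleConfs(mol, numConfs=2 * n_target, params=params)
    if len(cids) == 0:
        return None, {"id": entry["id"], "status": "embed_error"}

    forcefield = "MMFF94"
    if AllChem.MMFFHasAllMoleculeParams(mol):
        res = AllChem.MMFFOptimizeMoleculeConfs(mol, maxIters=500)
    else:
        forcefield = "UFF"
        res = AllChem.UFFOptimizeMoleculeConfs(mol, maxIters=500)
    energies = [e for _, e in res]

    emin = min(energies)
    window = float(cfg["energy_window_kj"])
    keep = [
        (cid, (e - emin) * KCAL_TO_KJ)
        for cid, e in zip(cids, energies)
        if (e - emin) * KCAL_TO_KJ <= window
    ]
    keep.sort(key=lambda t: (t[1], t[0]))

    # greedy dedup: keep lowest-energy representative of each geometry
    rms_cut = float(cfg["rms_dedup"])
    kept = []
    for cid, rel in keep:
        if len(kept) >= n_target:
            break
        if all(heavy_rms(mol, cid, k) > rms_cut for k, _ in kept):
            kept.append((cid, rel))

    return (mol, kept, forcefield), {
        "id": entry["id"],
        "status": "ok",
        "n_embedded": len(cids),
        "n_kept": len(kept),
        "forcefield": forcefield,
    }


def main(job_path, sdf_path, meta_path):
    with open(job_path) as fh:
        job = json.load(fh)

    metas = []
    writer = Chem.SDWriter(sdf_path)
    writer.SetKekulize(True)
    for entry in job["molecules"]:
        out, meta = process(entry, job)
        metas.append(meta)
        if out is None:
            continue
        mol, kept, forcefield = out
        for rank, (cid, rel) in enumerate(kept, start=1):
            mol.SetProp("_Name", "%s_conf%d" % (entry["id"], rank))
            mol.SetProp("MOL_ID", str(entry["id"]))
            mol.SetProp("CONF_ID", str(rank))
            mol.SetProp("REL_ENERGY_KJ", "%.6f" % rel)
            mol.SetProp("FORCEFIELD", forcefield)
            writer.write(mol, confId=cid)
    writer.close()

    with open(meta_path, "w") as fh:
        json.dump(metas, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2], sys.argv[3])
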