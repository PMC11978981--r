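"""Bemis-Murcko scaffold Morgan fingerprints via RDKit.

Reads a JSON config {smiles, n_bits, radius, use_scaffold} from argv[1] and
writes per-molecule results [{ok, origin, on_bits}] to argv[2].
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")


def main():
    with open(sys.argv[1]) as fh:
        cfg = json.load(fh)
    gen = rdFingerprintGenerator.GetMorganGenerator(
        radius=int(cfg["radius"]), fpSize=int(cfg["n_bits"])
    )
    out = []
    for smi in cfg["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False})
            continue
        target, origin = mol, "full-molecule"
        if cfg.get("use_scaffold", True):
            scaffold = MurckoScaffold.GetScaffoldForMol(mol)
            if scaffold is not None and scaffold.GetNumAtoms() > 0:
                target, origin = scaffold, "scaffold"
        fp = gen.GetFingerprint(target)
        out.append({"ok": True, "origin": origin, "on_bits": list(fp.GetOnBits())})
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
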