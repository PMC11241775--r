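"""Batch cheminformatics backend.

Reads a JSON request {"ops": [...], "smiles": [...]} from argv[1] and writes a
JSON response to argv[2].  One process handles one batch; the R side caches
per-SMILES results so repeated queries never re-enter Python.

Supported ops (any subset, computed in one pass):
  canonicalize  -> canonical SMILES or null per input
  props         -> {logp, qed, sas} per input (Crippen logP, QED, Ertl-Schuffenhauer SA)
  morgan        -> sorted 0-based on-bit lists, radius-2 1024-bit Morgan fingerprints
  maccs         -> sorted 0-based on-bit lists, 167-bit MACCS keys
  brics         -> list of BRICS fragment keys per input (whole molecule if uncleavable)
  scaffold      -> Bemis-Murcko scaffold canonical SMILES per input ("" if acyclic)
"""
import json
import os
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Crippen, MACCSkeys, QED, RDConfig
from rdkit.Chem.BRICS import BRICSDecompose
from rdkit.Chem.Scaffolds import MurckoScaffold

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

RDLogger.DisableLog("rdApp.*")


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    ops = set(req["ops"])
    smiles = req["smiles"]

    out = {"ok": True, "n": len(smiles)}
    mols = []
    for s in smiles:
        try:
            mols.append(Chem.MolFromSmiles(s) if isinstance(s, str) and s else None)
        except Exception:
            mols.append(None)

    if "canonicalize" in ops:
        out["canonical"] = [Chem.MolToSmiles(m) if m is not None else None for m in mols]

    if "props" in ops:
        logp, qed, sas = [], [], []
        for m in mols:
            if m is None:
                logp.append(None); qed.append(None); sas.append(None)
            else:
                logp.append(Crippen.MolLogP(m))
                qed.append(QED.qed(m))
                sas.append(sascorer.calculateScore(m))
        out["logp"], out["qed"], out["sas"] = logp, qed, sas

    if "morgan" in ops:
        fps = []
        gen = AllChem.GetMorganGenerator(radius=2, fpSize=1024)
        for m in mols:
            fps.append(sorted(gen.GetFingerprint(m).GetOnBits()) if m is not None else None)
        out["morgan"] = fps

    if "maccs" in ops:
        fps = []
        for m in mols:
            fps.append(sorted(MACCSkeys.GenMACCSKeys(m).GetOnBits()) if m is not None else None)
        out["maccs"] = fps

    if "brics" in ops:
        frs = []
        for m in mols:
            if m is None:
                frs.append(None)
                continue
            try:
                pieces = sorted(BRICSDecompose(m))
            except Exception:
                pieces = []
            if not pieces:
                pieces = [Chem.MolToSmiles(m)]
            frs.append(pieces)
        out["brics"] = frs

    if "scaffold" in ops:
        scs = []
        for m in mols:
            if m is None:
                scs.append(None)
                continue
            try:
                sc = MurckoScaffold.GetScaffoldForMol(m)
                scs.append(Chem.MolToSmiles(sc) if sc is not None else "")
            except Exception:
                scs.append("")
        out["scaffold"] = scs

    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
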