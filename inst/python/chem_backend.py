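"""Batched RDKit helper used by the clmdesign R package.

Reads one SMILES per line on stdin and writes one result line per input
line on stdout, so R can drive whole corpora through a single process.

Tasks:
  standardize           -> "<is_valid>\t<canonical_smiles>"
  fp [radius] [nbits]   -> space-separated 0-based on-bit indices, or NA
  augment <fold> <seed> -> tab-separated distinct randomized SMILES, or NA
"""

import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def _clean_fragment(frag):
    """Strip isotopes and stereochemistry, return canonical SMILES or None."""
    for atom in frag.GetAtoms():
        atom.SetIsotope(0)
    Chem.RemoveStereochemistry(frag)
    try:
        Chem.SanitizeMol(frag)
    except Exception:
        return None
    can = Chem.MolToSmiles(frag, isomericSmiles=False, canonical=True)
    # re-parse once so leftovers of the editing pass (e.g. explicit [H]
    # freed by isotope clearing) collapse and the form is a fixed point
    mol = Chem.MolFromSmiles(can)
    if mol is None:
        return None
    return Chem.MolToSmiles(mol, isomericSmiles=False, canonical=True)


def standardize_one(smi):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return None
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    best = None  # (heavy_atoms, canonical)
    for frag in frags:
        can = _clean_fragment(frag)
        if can is None:
            continue
        heavy = frag.GetNumHeavyAtoms()
        # keep the fragment with most heavy atoms; ties -> lexicographically
        # smallest canonical SMILES
        key = (-heavy, can)
        if best is None or key < best[0]:
            best = (key, can)
    return best[1] if best is not None else None


def run_standardize(lines):
    for smi in lines:
        can = standardize_one(smi) if smi else None
        if can is None or can == "":
            sys.stdout.write("0\t\n")
        else:
            sys.stdout.write("1\t%s\n" % can)


def run_fp(lines, radius=2, nbits=2048):
    for smi in lines:
        mol = Chem.MolFromSmiles(smi) if smi else None
        if mol is None:
            sys.stdout.write("NA\n")
            continue
        fp = AllChem.GetMorganFingerprintAsBitVect(mol, radius, nBits=nbits)
        sys.stdout.write(" ".join(str(b) for b in fp.GetOnBits()) + "\n")


def run_augment(lines, fold, seed):
    for i, smi in enumerate(lines):
        mol = Chem.MolFromSmiles(smi) if smi else None
        if mol is None:
            sys.stdout.write("NA\n")
            continue
        variants = Chem.MolToRandomSmilesVect(mol, fold, randomSeed=seed + i)
        seen = []
        for v in variants:
            if v not in seen:
                seen.append(v)
        sys.stdout.write("\t".join(seen) + "\n")


def main():
    task = sys.argv[1]
    lines = [ln.rstrip("\n") for ln in sys.stdin]
    if task == "standardize":
        run_standardize(lines)
    elif task == "fp":
        radius = int(sys.argv[2]) if len(sys.argv) > 2 else 2
        nbits = int(sys.argv[3]) if len(sys.argv) > 3 else 2048
        run_fp(lines, radius, nbits)
    elif task == "augment":
        run_augment(lines, int(sys.argv[2]), int(sys.argv[3]))
    else:
        sys.stderr.write("unknown task: %s\n" % task)
        sys.exit(2)


if __name__ == "__main__":
    main()
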