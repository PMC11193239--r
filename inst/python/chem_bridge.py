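"""Batched RDKit helper for the smilesgen R package.

Reads SMILES (one per line) on stdin, writes TSV on stdout.  Invoked by
system2() from R; one process per batch so the RDKit import cost is paid
once per call, not per molecule.

Tasks
-----
props          ok, canonical, logp, sascore, mw       (mw in Daltons)
match CORE     first line: SMARTS of the bond-order-relaxed core pattern;
               then one line per input: 1 / 0 / NA (NA = unparseable input)
smarts CORE    just the relaxed SMARTS for CORE (no stdin consumed)
"""

import os
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, RDConfig

RDLogger.DisableLog("rdApp.*")

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402


def read_lines():
    for line in sys.stdin:
        yield line.rstrip("\n")


def relaxed_smarts(core):
    """SMARTS retaining element identity and connectivity only.

    Atoms are emitted by RDKit as atomic-number queries ([#6] etc.), which
    match regardless of aromaticity; every bond symbol outside a bracket
    is rewritten to '~' (any bond), so bond orders are not compared.
    """
    mol = Chem.MolFromSmiles(core)
    if mol is None:
        raise ValueError("unparseable core SMILES: %r" % core)
    sm = Chem.MolToSmarts(mol)
    out = []
    in_bracket = False
    for ch in sm:
        if ch == "[":
            in_bracket = True
        elif ch == "]":
            in_bracket = False
        if not in_bracket and ch in "-=#:/\\":
            out.append("~")
        else:
            out.append(ch)
    return "".join(out)


def task_props():
    for smi in read_lines():
        mol = Chem.MolFromSmiles(smi) if smi else None
        if mol is None:
            print("0\tNA\tNA\tNA\tNA")
            continue
        can = Chem.MolToSmiles(mol)  # canonical, stereochemistry kept
        logp = Crippen.MolLogP(mol)
        sa = sascorer.calculateScore(mol)
        mw = Descriptors.MolWt(mol)
        print("1\t%s\t%.10g\t%.10g\t%.10g" % (can, logp, sa, mw))


def task_match(core):
    pat = relaxed_smarts(core)
    query = Chem.MolFromSmarts(pat)
    print(pat)
    for smi in read_lines():
        mol = Chem.MolFromSmiles(smi) if smi else None
        if mol is None:
            print("NA")
        else:
            print("1" if mol.HasSubstructMatch(query) else "0")


def main(argv):
    task = argv[1]
    if task == "props":
        task_props()
    elif task == "match":
        task_match(argv[2])
    elif task == "smarts":
        print(relaxed_smarts(argv[2]))
    else:
        raise SystemExit("unknown task: %r" % task)


if __name__ == "__main__":
    main(sys.argv)
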