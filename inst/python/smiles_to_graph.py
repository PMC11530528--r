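"""Convert a SMILES string to a JSON atom/bond graph (rdkit backend).

Usage: python smiles_to_graph.py "<smiles>"
Prints a JSON object {atoms: [...], bonds: [[u, v, order_class], ...]} with
0-based atom indices for the hydrogen-suppressed molecular graph, or exits
with status 1 and an error message on stderr for unparseable input.
"""
import json
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")

ORDER_CLASS = {
    Chem.BondType.SINGLE: 0,
    Chem.BondType.DOUBLE: 1,
    Chem.BondType.TRIPLE: 2,
    Chem.BondType.AROMATIC: 3,
}


def main() -> int:
    smiles = sys.argv[1]
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        sys.stderr.write("unparseable SMILES\n")
        return 1
    atoms = [
        {
            "symbol": a.GetSymbol(),
            "degree": a.GetDegree(),
            "formal_charge": a.GetFormalCharge(),
            "aromatic": int(a.GetIsAromatic()),
        }
        for a in mol.GetAtoms()
    ]
    bonds = [
        [b.GetBeginAtomIdx(), b.GetEndAtomIdx(), ORDER_CLASS.get(b.GetBondType(), 0)]
        for b in mol.GetBonds()
    ]
    json.dump({"atoms": atoms, "bonds": bonds}, sys.stdout)
    return 0


if __name__ == "__main__":
    sys.exit(main())
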