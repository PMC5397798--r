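"""Solve min c'x s.t. A x <= b, x >= 0 with scipy/HiGHS.

Reads a problem directory written by the R side: meta.json plus raw
little-endian arrays ai/aj (int32 triplet indices, 0-based), av (float64
values), b.bin, c.bin. Writes x.bin (float64 solution) and result.json.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import linprog


def main(d):
    with open(f"{d}/meta.json") as fh:
        meta = json.load(fh)
    n_rows, n_cols, nnz = meta["n_rows"], meta["n_cols"], meta["nnz"]
    ai = np.fromfile(f"{d}/ai.bin", dtype="<i4", count=nnz)
    aj = np.fromfile(f"{d}/aj.bin", dtype="<i4", count=nnz)
    av = np.fromfile(f"{d}/av.bin", dtype="<f8", count=nnz)
    b = np.fromfile(f"{d}/b.bin", dtype="<f8", count=n_rows)
    c = np.fromfile(f"{d}/c.bin", dtype="<f8", count=n_cols)
    A = sparse.csr_matrix((av, (ai, aj)), shape=(n_rows, n_cols))
    res = linprog(c, A_ub=A, b_ub=b, bounds=(0, None), method="highs")
    if res.x is not None:
        np.asarray(res.x, dtype="<f8").tofile(f"{d}/x.bin")
    with open(f"{d}/result.json", "w") as fh:
        json.dump({"status": int(res.status), "fun": float(res.fun)
                   if res.fun is not None else None,
                   "message": str(res.message)}, fh)


if __name__ == "__main__":
    main(sys.argv[1])
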