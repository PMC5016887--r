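"""Binary-program driver for the 'highs' solver backend.

Reads a JSON problem spec {n, obj, cover_rows, [card]} and writes a JSON
result {status, success, x, objective}. Each cover row lists the 0-based
variable indices whose sum must be >= 1 (a closed-neighbourhood domination
constraint); 'card' pins sum(x) to an exact cardinality. mip_rel_gap is set
to 0 so the returned solution is proven optimal.
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import csr_matrix


def main(spec_path, out_path):
    with open(spec_path) as fh:
        spec = json.load(fh)
    n = int(spec["n"])
    rows = spec["cover_rows"]
    indptr = [0]
    indices = []
    for row in rows:
        if isinstance(row, int):  # JSON scalar for a single-entry row
            row = [row]
        indices.extend(int(i) for i in row)
        indptr.append(len(indices))
    A = csr_matrix(
        (np.ones(len(indices)), np.asarray(indices), np.asarray(indptr)),
        shape=(len(rows), n),
    )
    constraints = [LinearConstraint(A, lb=1, ub=np.inf)]
    card = spec.get("card")
    if card is not None:
        constraints.append(
            LinearConstraint(np.ones((1, n)), lb=card, ub=card)
        )
    res = milp(
        c=np.asarray(spec["obj"], dtype=float),
        integrality=np.ones(n),
        bounds=Bounds(0, 1),
        constraints=constraints,
        options={"mip_rel_gap": 0},
    )
    out = {
        "status": int(res.status),
        "success": bool(res.success),
        "x": None if res.x is None else [int(round(v)) for v in res.x],
        "objective": None if res.fun is None else float(res.fun),
    }
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
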