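"""Solve a batch of 0/1 integer linear programs with HiGHS via scipy.

Reads {models: [{obj, nvar, nrow, a_row, a_col, a_val, row_lb, row_ub,
time_limit}]} from argv[1]; bounds with |value| >= 1e29 mean infinity.
Writes [{status, success, x, objective}] to argv[2].
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import csr_matrix


def solve_one(m):
    nvar = int(m["nvar"])
    obj = np.asarray(m["obj"], dtype=float)
    lb = np.asarray(m["row_lb"], dtype=float)
    ub = np.asarray(m["row_ub"], dtype=float)
    lb[lb <= -1e29] = -np.inf
    ub[ub >= 1e29] = np.inf
    A = csr_matrix(
        (
            np.asarray(m["a_val"], dtype=float),
            (np.asarray(m["a_row"], dtype=int) - 1, np.asarray(m["a_col"], dtype=int) - 1),
        ),
        shape=(int(m["nrow"]), nvar),
    )
    # presolve is disabled: HiGHS's MIP presolve has been observed to return
    # suboptimal "optimal" solutions on these cut-linearized models, and the
    # reduced instances are small enough to solve without it
    options = {"presolve": False, "mip_rel_gap": 0.0}
    tl = m.get("time_limit")
    if tl is not None and np.isfinite(tl):
        options["time_limit"] = float(tl)
    res = milp(
        c=obj,
        constraints=[LinearConstraint(A, lb, ub)],
        integrality=np.ones(nvar),
        bounds=Bounds(0, 1),
        options=options,
    )
    out = {"status": int(res.status), "success": bool(res.success)}
    if res.x is not None:
        out["x"] = [float(v) for v in np.round(res.x)]
        out["objective"] = float(res.fun)
    return out


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    results = [solve_one(m) for m in payload["models"]]
    with open(sys.argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
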