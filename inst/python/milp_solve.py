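"""Run one MILP through HiGHS (scipy.optimize.milp).

Input: a JSON spec naming a MatrixMarket constraint matrix and carrying
objective, bounds, integrality, row bounds, time limit and relative gap.
Magnitudes >= 1e30 encode +/- infinity. Output: a JSON result with
status, objective, gap, wall time and the solution vector.
"""
import json
import sys
import time

import numpy as np
from scipy.io import mmread
from scipy.optimize import Bounds, LinearConstraint, milp


def uncap(a):
    a = np.asarray(a, dtype=float)
    a[a >= 1e30] = np.inf
    a[a <= -1e30] = -np.inf
    return a


def main(spec_path):
    with open(spec_path) as fh:
        spec = json.load(fh)
    c = np.asarray(spec["obj"], dtype=float)
    lb = uncap(spec["lb"])
    ub = uncap(spec["ub"])
    integrality = np.asarray(spec["integrality"], dtype=int)
    constraints = None
    if spec["nrows"] > 0:
        A = mmread(spec["matrix"]).tocsc()
        constraints = LinearConstraint(A, uncap(spec["row_lb"]),
                                       uncap(spec["row_ub"]))
    t0 = time.time()
    res = milp(c, constraints=constraints, integrality=integrality,
               bounds=Bounds(lb, ub),
               options={"disp": False,
                        "time_limit": float(spec["time_limit"]),
                        "mip_rel_gap": float(spec["mip_rel_gap"])})
    wall = time.time() - t0
    if res.status == 0:
        status = "optimal"
    elif res.status == 1:
        status = "feasible" if res.x is not None else "time_limit"
    elif res.status == 2:
        status = "infeasible"
    else:
        status = "error"
    out = {"status": status, "wall_time": wall,
           "message": str(res.message)}
    if res.x is not None:
        out["objective"] = float(res.fun)
        out["x"] = [float(v) for v in res.x]
        gap = getattr(res, "mip_gap", None)
        out["gap"] = float(gap) if gap is not None else 0.0
    with open(spec["out"], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1])
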