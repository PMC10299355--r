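"""Independent transportation-problem oracle.

Reads a JSON list of instances from a path argument (or stdin) and prints
a JSON list of optimal costs computed with scipy.optimize.linprog (HiGHS).

Two instance forms are accepted:
  {"cost": [[...]], "supply": [...], "demand": [...]}
      a bare transportation problem, or
  {"x": [...], "y": [...], "counts": [...]}
      a SADIE distance-to-regularity instance: supplies are counts above
      the mean, demands counts below it, costs Euclidean distances.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve_tp(c, s, d):
    m, n = c.shape
    A_eq = []
    for i in range(m):
        row = np.zeros(m * n)
        row[i * n:(i + 1) * n] = 1.0
        A_eq.append(row)
    for j in range(n):
        row = np.zeros(m * n)
        row[j::n] = 1.0
        A_eq.append(row)
    b_eq = np.concatenate([s, d * s.sum() / d.sum()])
    res = linprog(c.ravel(), A_eq=np.asarray(A_eq), b_eq=b_eq,
                  bounds=(0, None), method="highs")
    if not res.success:
        raise RuntimeError("LP failed: " + res.message)
    return float(res.fun)


def solve(inst):
    if "cost" in inst:
        return solve_tp(np.asarray(inst["cost"], dtype=float),
                        np.asarray(inst["supply"], dtype=float),
                        np.asarray(inst["demand"], dtype=float))
    x = np.asarray(inst["x"], dtype=float)
    y = np.asarray(inst["y"], dtype=float)
    counts = np.asarray(inst["counts"], dtype=float)
    mean = counts.mean()
    donors = np.where(counts > mean)[0]
    receivers = np.where(counts < mean)[0]
    if donors.size == 0 or receivers.size == 0:
        return 0.0
    c = np.hypot(x[donors, None] - x[None, receivers],
                 y[donors, None] - y[None, receivers])
    return solve_tp(c, counts[donors] - mean, mean - counts[receivers])


def main():
    if len(sys.argv) > 1:
        with open(sys.argv[1]) as fh:
            instances = json.load(fh)
    else:
        instances = json.load(sys.stdin)
    print(json.dumps([solve(inst) for inst in instances]))


if __name__ == "__main__":
    main()
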