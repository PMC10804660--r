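"""LP-relaxation oracle for bipartite matching instances.

Reads JSON from stdin: a list of instances, each
    {"left": [...], "right": [...], "inc_left": [...], "inc_right": [...]}
where inc_left[t]/inc_right[t] name the endpoints of incidence t. Solves
    max sum_t x_t   s.t.  sum_{t: left} x_t <= 1 per left node,
                          sum_{t: right} x_t <= 1 per right node,  x >= 0
with HiGHS via scipy.optimize.linprog and writes the list of LP optima as
JSON to stdout. Used only as an independent test oracle.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve(instance):
    inc_l = instance["inc_left"]
    inc_r = instance["inc_right"]
    n = len(inc_l)
    if n == 0:
        return 0.0
    left = sorted(set(inc_l))
    right = sorted(set(inc_r))
    rows = []
    for v in left:
        rows.append([1.0 if g == v else 0.0 for g in inc_l])
    for u in right:
        rows.append([1.0 if e == u else 0.0 for e in inc_r])
    A = np.array(rows)
    b = np.ones(A.shape[0])
    res = linprog(c=-np.ones(n), A_ub=A, b_ub=b, bounds=(0, None),
                  method="highs")
    if not res.success:
        raise RuntimeError(res.message)
    return float(-res.fun)


def main():
    instances = json.load(sys.stdin)
    json.dump([solve(inst) for inst in instances], sys.stdout)


if __name__ == "__main__":
    main()
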