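"""Independent solvers for the combined l1/l2-norm SVM test instances.

Usage: python oracle_socp.py <slsqp|lp> <in.json> <out.json>

slsqp: generic nonlinear solve of the cone formulation (epigraph variables
       for |w_i| and ||w||_2, linear objective, smooth constraints).
lp:    linear program for the pure-l1 case (gamma = 1), solved with HiGHS.

Reported objective values are recomputed from (w, theta) with the exact
nonsmooth formula, so solver-internal auxiliaries cannot bias them.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog, minimize


def true_objective(w, th, X, y, lam, al, ga):
    marg = y * (X @ w - th)
    slack = np.maximum(0.0, 1.0 - marg)
    cw = (1 - lam) * np.where(y > 0, al, 1 - al)
    return float(cw @ slack + lam * (ga * np.abs(w).sum()
                                     + (1 - ga) * np.linalg.norm(w)))


def solve_slsqp(X, y, lam, al, ga):
    k, s = X.shape
    cw = (1 - lam) * np.where(y > 0, al, 1 - al)

    def unpack(v):
        return v[:s], v[s], v[s + 1:s + 1 + k], v[s + 1 + k:s + 1 + k + s], v[-1]

    def f(v):
        w, th, xi, t, tau = unpack(v)
        return float(cw @ xi + lam * (ga * t.sum() + (1 - ga) * tau))

    cons = [
        {"type": "ineq",
         "fun": lambda v: y * (X @ unpack(v)[0] - unpack(v)[1]) + unpack(v)[2] - 1},
        {"type": "ineq", "fun": lambda v: unpack(v)[2]},
        {"type": "ineq", "fun": lambda v: unpack(v)[3] - unpack(v)[0]},
        {"type": "ineq", "fun": lambda v: unpack(v)[3] + unpack(v)[0]},
        {"type": "ineq",
         "fun": lambda v: np.array([unpack(v)[4] ** 2 - (unpack(v)[0] ** 2).sum()])},
        {"type": "ineq", "fun": lambda v: np.array([unpack(v)[4]])},
    ]
    v0 = np.concatenate([np.zeros(s), [0.0], np.ones(k), np.zeros(s), [0.1]])
    r = minimize(f, v0, constraints=cons, method="SLSQP",
                 options={"maxiter": 3000, "ftol": 1e-14})
    w, th, *_ = unpack(r.x)
    return true_objective(w, th, X, y, lam, al, ga), int(r.status)


def solve_lp(X, y, lam, al):
    # gamma = 1: variables [w+, w-, theta, xi]; minimize
    # cw.xi + lam * sum(w+ + w-) subject to margin constraints.
    k, s = X.shape
    cw = (1 - lam) * np.where(y > 0, al, 1 - al)
    nv = 2 * s + 1 + k
    c = np.concatenate([np.full(2 * s, lam), [0.0], cw])
    A = np.zeros((k, nv))
    Yx = X * y[:, None]
    A[:, :s] = -Yx
    A[:, s:2 * s] = Yx
    A[:, 2 * s] = y
    A[:, 2 * s + 1:] = -np.eye(k)
    b = -np.ones(k)
    bounds = [(0, None)] * (2 * s) + [(None, None)] + [(0, None)] * k
    r = linprog(c, A_ub=A, b_ub=b, bounds=bounds, method="highs")
    w = r.x[:s] - r.x[s:2 * s]
    th = r.x[2 * s]
    return true_objective(w, th, X, y, lam, al, 1.0), int(r.status)


def main():
    mode, infile, outfile = sys.argv[1], sys.argv[2], sys.argv[3]
    instances = json.load(open(infile))
    out = []
    for z in instances:
        X = np.asarray(z["X"], dtype=float)
        y = np.asarray(z["y"], dtype=float)
        lam, al, ga = z["lambda"], z["alpha"], z["gamma"]
        if mode == "lp":
            obj, status = solve_lp(X, y, lam, al)
        else:
            obj, status = solve_slsqp(X, y, lam, al, ga)
        out.append({"objective": obj, "status": status})
    json.dump(out, open(outfile, "w"))


if __name__ == "__main__":
    main()
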