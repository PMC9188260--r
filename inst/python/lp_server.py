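#!/usr/bin/env python
"""LP/MILP solving helper backed by HiGHS (scipy.optimize).

Two modes:
  lp_server.py --serve            start a localhost TCP server; prints
                                  "PORT <n> TOKEN <t>" on stdout, then answers
                                  newline-delimited JSON requests.
  lp_server.py --oneshot IN OUT   solve a single JSON request file.

Request: {"token": str (server mode), "problems": [problem, ...]}
Problem: {"obj": [...], "lb": [...], "ub": [...],
          "A_eq": [[...]], "b_eq": [...], "A_ub": [[...]], "b_ub": [...],
          "integrality": [...], "maximize": bool}
Bounds with magnitude >= 1e29 are treated as infinite.
Response: {"results": [{"status": str, "objective": num|None, "x": [...]}]}
"""
import json
import secrets
import socket
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, linprog, milp

BIG = 1e29
IDLE_TIMEOUT = 1800.0

_LP_STATUS = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
              3: "unbounded", 4: "error"}
_MILP_STATUS = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
                3: "unbounded", 4: "error"}


def _inf(arr):
    a = np.asarray(arr, dtype=float)
    a = a.copy()
    a[a >= BIG] = np.inf
    a[a <= -BIG] = -np.inf
    return a


def solve_one(p):
    c = np.asarray(p["obj"], dtype=float)
    n = c.size
    sign = -1.0 if p.get("maximize", False) else 1.0
    lb = _inf(p.get("lb", np.full(n, -np.inf)))
    ub = _inf(p.get("ub", np.full(n, np.inf)))
    A_eq = p.get("A_eq")
    b_eq = p.get("b_eq")
    A_ub = p.get("A_ub")
    b_ub = p.get("b_ub")
    integrality = np.asarray(p.get("integrality", np.zeros(n)), dtype=int)

    if A_eq is not None:
        A_eq = np.asarray(A_eq, dtype=float).reshape(-1, n)
        b_eq = np.asarray(b_eq, dtype=float)
    if A_ub is not None:
        A_ub = np.asarray(A_ub, dtype=float).reshape(-1, n)
        b_ub = np.asarray(b_ub, dtype=float)

    try:
        if integrality.any():
            cons = []
            if A_eq is not None and A_eq.shape[0]:
                cons.append(LinearConstraint(A_eq, b_eq, b_eq))
            if A_ub is not None and A_ub.shape[0]:
                cons.append(LinearConstraint(A_ub, -np.inf, b_ub))
            res = milp(sign * c, constraints=cons, bounds=Bounds(lb, ub),
                       integrality=integrality,
                       options={"presolve": True})
            status = _MILP_STATUS.get(res.status, "error")
            if res.x is None and status == "optimal":
                status = "error"
        else:
            res = linprog(sign * c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq,
                          b_eq=b_eq, bounds=np.column_stack([lb, ub]),
                          method="highs")
            status = _LP_STATUS.get(res.status, "error")
    except Exception as exc:  # noqa: BLE001 - report, never crash the server
        return {"status": "error", "objective": None, "x": None,
                "message": str(exc)}

    if status == "optimal" and res.x is not None:
        return {"status": "optimal", "objective": sign * float(res.fun),
                "x": [float(v) for v in res.x]}
    return {"status": status, "objective": None, "x": None,
            "message": getattr(res, "message", "")}


def handle(request, token=None):
    if token is not None and request.get("token") != token:
        return {"error": "bad token"}
    return {"results": [solve_one(p) for p in request.get("problems", [])]}


def serve():
    token = secrets.token_hex(16)
    srv = socket.socket(socket.AF_INET, socket.SOCK_STREAM)
    srv.setsockopt(socket.SOL_SOCKET, socket.SO_REUSEADDR, 1)
    srv.bind(("127.0.0.1", 0))
    srv.listen(1)
    port = srv.getsockname()[1]
    sys.stdout.write("PORT %d TOKEN %s\n" % (port, token))
    sys.stdout.flush()
    srv.settimeout(IDLE_TIMEOUT)
    try:
        conn, _ = srv.accept()
    except socket.timeout:
        return
    conn.settimeout(IDLE_TIMEOUT)
    buf = b""
    while True:
        try:
            chunk = conn.recv(1 << 20)
        except socket.timeout:
            break
        if not chunk:
            break
        buf += chunk
        while b"\n" in buf:
            line, buf = buf.split(b"\n", 1)
            if not line.strip():
                continue
            try:
                req = json.loads(line)
            except json.JSONDecodeError:
                conn.sendall(b'{"error": "bad json"}\n')
                continue
            if req.get("quit"):
                conn.close()
                return
            out = json.dumps(handle(req, token)) + "\n"
            conn.sendall(out.encode())
    conn.close()


def oneshot(path_in, path_out):
    with open(path_in) as fh:
        req = json.load(fh)
    with open(path_out, "w") as fh:
        json.dump(handle(req), fh)


if __name__ == "__main__":
    if len(sys.argv) >= 2 and sys.argv[1] == "--serve":
        serve()
    elif len(sys.argv) >= 4 and sys.argv[1] == "--oneshot":
        oneshot(sys.argv[2], sys.argv[3])
    else:
        sys.stderr.write(__doc__)
        sys.exit(2)
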