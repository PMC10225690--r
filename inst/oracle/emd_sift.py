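"""Independent reference implementation of EMD sifting.

Reads a single-column CSV of samples, performs plain empirical mode
decomposition (natural cubic spline envelopes through local extrema,
two-extrema mirror boundary, S-number stopping), and writes the IMFs as
columns of an output CSV.  Written and maintained separately from the R
package as a cross-check; shares no code with it.

Usage: python emd_sift.py <in.csv> <out.csv> [s_number] [max_imfs]
"""
import sys

import numpy as np
from scipy.interpolate import CubicSpline


def local_extrema(x):
    dx = np.diff(x)
    maxima, minima = [], []
    for i in range(1, len(x) - 1):
        if x[i] > x[i - 1] and x[i] > x[i + 1]:
            maxima.append(i)
        elif x[i] < x[i - 1] and x[i] < x[i + 1]:
            minima.append(i)
    return np.array(maxima, dtype=int), np.array(minima, dtype=int)


def zero_crossings(x):
    s = np.sign(x)
    s = s[s != 0]
    if len(s) < 2:
        return 0
    return int(np.sum(np.diff(s) != 0))


def envelope(idx, val, n):
    left_t = -idx[:2][::-1]
    left_v = val[:2][::-1]
    right_t = 2 * (n - 1) - idx[-2:][::-1]
    right_v = val[-2:][::-1]
    t = np.concatenate([left_t, idx, right_t])
    v = np.concatenate([left_v, val, right_v])
    t, keep = np.unique(t, return_index=True)
    cs = CubicSpline(t, v[keep], bc_type="natural")
    return cs(np.arange(n))


def sift(x, s_number=2, max_iter=100):
    h = x.copy()
    n = len(h)
    streak, prev = 0, None
    for _ in range(max_iter):
        mx, mn = local_extrema(h)
        if len(mx) < 2 or len(mn) < 2:
            break
        m = (envelope(mx, h[mx], n) + envelope(mn, h[mn], n)) / 2.0
        if streak >= s_number and np.max(np.abs(m)) <= 0.05 * np.max(np.abs(h)):
            break
        h = h - m
        mx, mn = local_extrema(h)
        ne, nz = len(mx) + len(mn), zero_crossings(h)
        if abs(ne - nz) <= 1 and prev is not None and (ne, nz) == prev:
            streak += 1
        else:
            streak = 0
        prev = (ne, nz)
    return h


def decompose(x, s_number=2, max_imfs=12):
    imfs = []
    resid = x.copy()
    while len(imfs) < max_imfs:
        mx, mn = local_extrema(resid)
        if len(mx) < 2 or len(mn) < 2 or len(mx) + len(mn) < 3:
            break
        imf = sift(resid, s_number=s_number)
        if np.allclose(imf, 0):
            break
        imfs.append(imf)
        resid = resid - imf
    return imfs, resid


def main():
    x = np.loadtxt(sys.argv[1], delimiter=",")
    s_number = int(sys.argv[3]) if len(sys.argv) > 3 else 2
    max_imfs = int(sys.argv[4]) if len(sys.argv) > 4 else 12
    imfs, resid = decompose(x, s_number=s_number, max_imfs=max_imfs)
    out = np.column_stack(imfs + [resid]) if imfs else resid[:, None]
    np.savetxt(sys.argv[2], out, delimiter=",")


if __name__ == "__main__":
    main()
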