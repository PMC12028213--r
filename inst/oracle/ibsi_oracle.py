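#!/usr/bin/env python
"""Independent IBSI-style radiomic feature reference implementation.

Reads a JSON file: a list of cases, each with
  dims      [nx, ny, nz]          (grid shape, column-major / Fortran order)
  spacing   [sx, sy, sz]          (mm)
  bin_width float
  values    flat list of map values (column-major), arbitrary outside mask
  mask      flat list of 0/1      (column-major)

Writes CSV `case,feature,value` with the 93 features per case:
18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM.

Conventions (must match the package under test): fixed-bin-width
discretisation anchored at the ROI minimum; symmetric GLCM / GLRLM over the
13 unique 3D directions, features averaged over directions with at least one
pair/run; 26-connectivity zones (GLSZM) and neighbourhoods (GLDM, NGTDM);
GLDM dependence size includes the center voxel; entropies in bits.
"""
import json
import sys

import numpy as np
from scipy import ndimage

DIRS = [(1, 0, 0), (0, 1, 0), (0, 0, 1),
        (1, 1, 0), (1, -1, 0), (1, 0, 1), (1, 0, -1), (0, 1, 1), (0, 1, -1),
        (1, 1, 1), (1, 1, -1), (1, -1, 1), (1, -1, -1)]


def entropy(p):
    p = p[p > 0]
    return float(-np.sum(p * np.log2(p)))


def first_order(vals, bin_width, voxel_volume):
    n = vals.size
    lev = np.floor((vals - vals.min()) / bin_width).astype(int) + 1
    p = np.bincount(lev)[1:] / n
    q10, q25, q50, q75, q90 = np.percentile(vals, [10, 25, 50, 75, 90])
    mu = vals.mean()
    m2 = np.mean((vals - mu) ** 2)
    m3 = np.mean((vals - mu) ** 3)
    m4 = np.mean((vals - mu) ** 4)
    inr = vals[(vals >= q10) & (vals <= q90)]
    return {
        "Energy": float(np.sum(vals ** 2)),
        "TotalEnergy": float(voxel_volume * np.sum(vals ** 2)),
        "Entropy": entropy(p),
        "Minimum": float(vals.min()),
        "10Percentile": float(q10),
        "90Percentile": float(q90),
        "Maximum": float(vals.max()),
        "Mean": float(mu),
        "Median": float(q50),
        "InterquartileRange": float(q75 - q25),
        "Range": float(vals.max() - vals.min()),
        "MeanAbsoluteDeviation": float(np.mean(np.abs(vals - mu))),
        "RobustMeanAbsoluteDeviation":
            float(np.mean(np.abs(inr - inr.mean()))) if inr.size else 0.0,
        "RootMeanSquared": float(np.sqrt(np.mean(vals ** 2))),
        "Skewness": float(m3 / m2 ** 1.5) if m2 > 0 else 0.0,
        "Kurtosis": float(m4 / m2 ** 2) if m2 > 0 else 0.0,
        "Variance": float(m2),
        "Uniformity": float(np.sum(p ** 2)),
    }


def glcm_one(C):
    P = C / C.sum()
    ng = P.shape[0]
    iv = np.arange(1, ng + 1)
    i = iv[:, None] * np.ones((1, ng))
    j = i.T
    px = P.sum(axis=1)
    py = P.sum(axis=0)
    Ng = int(np.sum((px + py) > 0))
    mux = float((i * P).sum())
    muy = float((j * P).sum())
    sigx = np.sqrt(((i - mux) ** 2 * P).sum())
    sigy = np.sqrt(((j - muy) ** 2 * P).sum())
    kd = np.arange(0, ng)
    pxy_d = np.array([P[np.abs(i - j) == k].sum() for k in kd])
    ks = np.arange(2, 2 * ng + 1)
    pxy_s = np.array([P[(i + j) == k].sum() for k in ks])
    da = float((kd * pxy_d).sum())
    hx, hy = entropy(px), entropy(py)
    hxy = entropy(P.ravel())
    pp = np.outer(px, py)
    sel = (P > 0) & (pp > 0)
    hxy1 = float(-np.sum(P[sel] * np.log2(pp[sel])))
    hxy2 = entropy(pp.ravel())
    imc1 = (hxy - hxy1) / max(hx, hy) if max(hx, hy) > 0 else 0.0
    imc2 = (np.sqrt(max(1 - np.exp(-2 * (hxy2 - hxy)), 0.0))
            if hxy2 >= hxy else 0.0)
    pres = np.where(px + py > 0)[0]
    if len(pres) == 1:
        mcc = 1.0
    else:
        Pp = P[np.ix_(pres, pres)]
        pxp, pyp = px[pres], py[pres]
        m = len(pres)
        Q = np.zeros((m, m))
        for k in range(m):
            denom = pxp * pyp[k]
            ok = denom > 0
            Q[ok, :] += np.outer(Pp[ok, k] / denom[ok], Pp[:, k])
        ev = np.sort(np.real(np.linalg.eigvals(Q)))[::-1]
        mcc = float(np.sqrt(max(ev[min(1, len(ev) - 1)], 0.0)))
    off = np.abs(i - j) > 0
    return {
        "Autocorrelation": float((P * i * j).sum()),
        "JointAverage": mux,
        "ClusterProminence": float((P * (i + j - mux - muy) ** 4).sum()),
        "ClusterShade": float((P * (i + j - mux - muy) ** 3).sum()),
        "ClusterTendency": float((P * (i + j - mux - muy) ** 2).sum()),
        "Contrast": float((P * (i - j) ** 2).sum()),
        "Correlation": (float(((P * i * j).sum() - mux * muy) / (sigx * sigy))
                        if sigx * sigy > 0 else 1.0),
        "DifferenceAverage": da,
        "DifferenceEntropy": entropy(pxy_d),
        "DifferenceVariance": float((pxy_d * (kd - da) ** 2).sum()),
        "Id": float((P / (1 + np.abs(i - j))).sum()),
        "Idm": float((P / (1 + (i - j) ** 2)).sum()),
        "Idmn": float((P / (1 + (i - j) ** 2 / Ng ** 2)).sum()),
        "Idn": float((P / (1 + np.abs(i - j) / Ng)).sum()),
        "Imc1": float(imc1),
        "Imc2": float(imc2),
        "InverseVariance": float((P[off] / (i - j)[off] ** 2).sum()),
        "JointEnergy": float((P ** 2).sum()),
        "JointEntropy": hxy,
        "MCC": mcc,
        "MaximumProbability": float(P.max()),
        "SumAverage": float((ks * pxy_s).sum()),
        "SumEntropy": entropy(pxy_s),
        "SumSquares": float((P * (i - mux) ** 2).sum()),
    }


def glcm(larr, nlev):
    feats = []
    for d in DIRS:
        C = np.zeros((nlev, nlev))
        a = larr
        b = np.roll(larr, tuple(-np.array(d)), axis=(0, 1, 2))
        # mask out wrapped positions
        valid = np.ones(larr.shape, bool)
        for ax, dd in enumerate(d):
            if dd == 1:
                sl = [slice(None)] * 3
                sl[ax] = slice(-1, None)
                valid[tuple(sl)] = False
            elif dd == -1:
                sl = [slice(None)] * 3
                sl[ax] = slice(0, 1)
                valid[tuple(sl)] = False
        ok = valid & (a > 0) & (b > 0)
        if not ok.any():
            continue
        np.add.at(C, (a[ok] - 1, b[ok] - 1), 1.0)
        C = C + C.T
        feats.append(glcm_one(C))
    if not feats:
        raise ValueError("degenerate ROI for GLCM")
    return {k: float(np.mean([f[k] for f in feats])) for k in feats[0]}


def rl_style(P, np_vox, names):
    nr = P.sum()
    ng, nl = P.shape
    i = np.arange(1, ng + 1)[:, None] * np.ones((1, nl))
    j = np.ones((ng, 1)) * np.arange(1, nl + 1)[None, :]
    p = P / nr
    ri = P.sum(axis=1)
    rj = P.sum(axis=0)
    mui = (p * i).sum()
    muj = (p * j).sum()
    vals = [
        float((P / j ** 2).sum() / nr),
        float((P * j ** 2).sum() / nr),
        float((ri ** 2).sum() / nr),
        float((ri ** 2).sum() / nr ** 2),
        float((rj ** 2).sum() / nr),
        float((rj ** 2).sum() / nr ** 2),
        float(nr / np_vox),
        float((p * (i - mui) ** 2).sum()),
        float((p * (j - muj) ** 2).sum()),
        entropy(p.ravel()),
        float((P / i ** 2).sum() / nr),
        float((P * i ** 2).sum() / nr),
        float((P / (i ** 2 * j ** 2)).sum() / nr),
        float((P * i ** 2 / j ** 2).sum() / nr),
        float((P * j ** 2 / i ** 2).sum() / nr),
        float((P * i ** 2 * j ** 2).sum() / nr),
    ]
    return dict(zip(names, vals))


GLRLM_NAMES = ["ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
               "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
               "RunLengthNonUniformityNormalized", "RunPercentage",
               "GrayLevelVariance", "RunVariance", "RunEntropy",
               "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
               "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
               "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"]

GLSZM_NAMES = ["SmallAreaEmphasis", "LargeAreaEmphasis",
               "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
               "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
               "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
               "ZoneEntropy", "LowGrayLevelZoneEmphasis",
               "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
               "SmallAreaHighGrayLevelEmphasis",
               "LargeAreaLowGrayLevelEmphasis",
               "LargeAreaHighGrayLevelEmphasis"]


def glrlm(larr, nlev, np_vox):
    maxlen = max(larr.shape)
    feats = []
    for d in DIRS:
        P = np.zeros((nlev, maxlen))
        # walk every voxel; count runs starting at voxels whose predecessor
        # differs
        nz = np.argwhere(larr > 0)
        dx, dy, dz = d
        shape = larr.shape

        def level(x, y, z):
            if 0 <= x < shape[0] and 0 <= y < shape[1] and 0 <= z < shape[2]:
                return larr[x, y, z]
            return 0

        for x, y, z in nz:
            a = larr[x, y, z]
            if level(x - dx, y - dy, z - dz) == a:
                continue
            ln = 1
            cx, cy, cz = x + dx, y + dy, z + dz
            while level(cx, cy, cz) == a:
                ln += 1
                cx += dx
                cy += dy
                cz += dz
            P[a - 1, min(ln, maxlen) - 1] += 1
        if P.sum() == 0:
            continue
        feats.append(rl_style(P, np_vox, GLRLM_NAMES))
    return {k: float(np.mean([f[k] for f in feats])) for k in feats[0]}


def glszm(larr, nlev, np_vox):
    struct = np.ones((3, 3, 3), int)
    zones = []
    for lev in range(1, nlev + 1):
        lab, n = ndimage.label(larr == lev, structure=struct)
        if n:
            sizes = np.bincount(lab.ravel())[1:]
            zones.extend((lev, s) for s in sizes)
    maxsize = max(s for _, s in zones)
    P = np.zeros((nlev, maxsize))
    for lev, s in zones:
        P[lev - 1, s - 1] += 1
    return rl_style(P, np_vox, GLSZM_NAMES)


def neighbour_iter(larr):
    """Yield (center_level, list of neighbour levels inside ROI)."""
    shape = larr.shape
    for x, y, z in np.argwhere(larr > 0):
        a = larr[x, y, z]
        nb = []
        for dx in (-1, 0, 1):
            for dy in (-1, 0, 1):
                for dz in (-1, 0, 1):
                    if dx == dy == dz == 0:
                        continue
                    X, Y, Z = x + dx, y + dy, z + dz
                    if (0 <= X < shape[0] and 0 <= Y < shape[1]
                            and 0 <= Z < shape[2] and larr[X, Y, Z] > 0):
                        nb.append(int(larr[X, Y, Z]))
        yield int(a), nb


def gldm(larr, nlev, alpha=0):
    P = np.zeros((nlev, 27))
    for a, nb in neighbour_iter(larr):
        dep = 1 + sum(1 for b in nb if abs(b - a) <= alpha)
        P[a - 1, dep - 1] += 1
    nz = P.sum()
    ng, nd = P.shape
    i = np.arange(1, ng + 1)[:, None] * np.ones((1, nd))
    j = np.ones((ng, 1)) * np.arange(1, nd + 1)[None, :]
    p = P / nz
    ri = P.sum(axis=1)
    rj = P.sum(axis=0)
    mui = (p * i).sum()
    muj = (p * j).sum()
    return {
        "SmallDependenceEmphasis": float((P / j ** 2).sum() / nz),
        "LargeDependenceEmphasis": float((P * j ** 2).sum() / nz),
        "GrayLevelNonUniformity": float((ri ** 2).sum() / nz),
        "DependenceNonUniformity": float((rj ** 2).sum() / nz),
        "DependenceNonUniformityNormalized": float((rj ** 2).sum() / nz ** 2),
        "GrayLevelVariance": float((p * (i - mui) ** 2).sum()),
        "DependenceVariance": float((p * (j - muj) ** 2).sum()),
        "DependenceEntropy": entropy(p.ravel()),
        "LowGrayLevelEmphasis": float((P / i ** 2).sum() / nz),
        "HighGrayLevelEmphasis": float((P * i ** 2).sum() / nz),
        "SmallDependenceLowGrayLevelEmphasis":
            float((P / (i ** 2 * j ** 2)).sum() / nz),
        "SmallDependenceHighGrayLevelEmphasis":
            float((P * i ** 2 / j ** 2).sum() / nz),
        "LargeDependenceLowGrayLevelEmphasis":
            float((P * j ** 2 / i ** 2).sum() / nz),
        "LargeDependenceHighGrayLevelEmphasis":
            float((P * i ** 2 * j ** 2).sum() / nz),
    }


def ngtdm(larr, nlev):
    ni = np.zeros(nlev)
    si = np.zeros(nlev)
    for a, nb in neighbour_iter(larr):
        if nb:
            ni[a - 1] += 1
            si[a - 1] += abs(a - np.mean(nb))
    nvp = ni.sum()
    if nvp == 0:
        raise ValueError("degenerate ROI for NGTDM")
    p = ni / nvp
    lv = np.arange(1, nlev + 1)
    pres = np.where(p > 0)[0]
    ngp = len(pres)
    den = float((p * si).sum())
    coarseness = 1 / den if den > 0 else 1e6
    if ngp > 1:
        pij = np.outer(p[pres], p[pres])
        dij = np.subtract.outer(lv[pres], lv[pres]).astype(float)
        contrast = (pij * dij ** 2).sum() / (ngp * (ngp - 1)) * si.sum() / nvp
        ip = lv[pres] * p[pres]
        bden = np.abs(np.subtract.outer(ip, ip)).sum()
        busyness = den / bden if bden > 0 else 0.0
        num = np.add.outer(p[pres] * si[pres], p[pres] * si[pres])
        complexity = (np.abs(dij) * num / np.add.outer(p[pres], p[pres])
                      ).sum() / nvp
        strength = ((np.add.outer(p[pres], p[pres]) * dij ** 2).sum()
                    / si.sum() if si.sum() > 0 else 0.0)
    else:
        contrast = busyness = complexity = strength = 0.0
    return {"Coarseness": float(coarseness), "Contrast": float(contrast),
            "Busyness": float(busyness), "Complexity": float(complexity),
            "Strength": float(strength)}


def scalar(x):
    return x[0] if isinstance(x, list) else x


def run_case(case):
    dims = case["dims"]
    vals = np.asarray(case["values"], float).reshape(dims, order="F")
    mask = np.asarray(case["mask"], int).reshape(dims, order="F") > 0
    bw = float(scalar(case["bin_width"]))
    spacing = case.get("spacing", [1.0, 1.0, 1.0])
    sel = mask & np.isfinite(vals)
    v = vals[sel]
    lev = np.floor((v - v.min()) / bw).astype(int) + 1
    nlev = int(lev.max())
    larr = np.zeros(dims, int)
    larr[sel] = lev
    np_vox = int(sel.sum())
    out = {}
    for k, x in first_order(v, bw, float(np.prod(spacing))).items():
        out["firstorder_" + k] = x
    for k, x in glcm(larr, nlev).items():
        out["glcm_" + k] = x
    for k, x in glrlm(larr, nlev, np_vox).items():
        out["glrlm_" + k] = x
    for k, x in glszm(larr, nlev, np_vox).items():
        out["glszm_" + k] = x
    for k, x in ngtdm(larr, nlev).items():
        out["ngtdm_" + k] = x
    for k, x in gldm(larr, nlev).items():
        out["gldm_" + k] = x
    assert len(out) == 93, len(out)
    return out


def main():
    infile, outfile = sys.argv[1], sys.argv[2]
    with open(infile) as fh:
        cases = json.load(fh)
    with open(outfile, "w") as fh:
        fh.write("case,feature,value\n")
        for idx, case in enumerate(cases):
            for k, x in run_case(case).items():
                fh.write("%d,%s,%.17g\n" % (idx, k, x))


if __name__ == "__main__":
    main()
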