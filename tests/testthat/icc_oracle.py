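"""Independent ICC oracle.

Reads a long-format CSV (table, subject, rater, value) from argv[1] and
writes per-table ICC(2,1)/(3,1)/(3,k) estimates and exact F-based 95%
confidence intervals to argv[2], at full float precision. The estimates are
additionally cross-checked against pingouin's intraclass_corr (whose CI
output is rounded to 2 decimals, so only estimates are compared there).

The decomposition and interval formulas are coded here directly from the
Shrout & Fleiss / McGraw & Wong two-way ANOVA derivations, independent of
the R implementation under test.
"""
import sys

import numpy as np
import pandas as pd
import pingouin as pg
from scipy.stats import f as fdist

ALPHA = 0.05


def mean_squares(tab):
    n, k = tab.shape
    gm = tab.mean()
    rm = tab.mean(axis=1)
    cm = tab.mean(axis=0)
    ssr = k * ((rm - gm) ** 2).sum()
    ssc = n * ((cm - gm) ** 2).sum()
    sst = ((tab - gm) ** 2).sum()
    sse = sst - ssr - ssc
    return ssr / (n - 1), ssc / (k - 1), sse / ((n - 1) * (k - 1))


def icc_all(tab):
    n, k = tab.shape
    msr, msc, mse = mean_squares(tab)
    icc21 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    icc31 = (msr - mse) / (msr + (k - 1) * mse)
    icc3k = (msr - mse) / msr

    df1, df2 = n - 1, (n - 1) * (k - 1)
    f0 = msr / mse
    fl = f0 / fdist.ppf(1 - ALPHA / 2, df1, df2)
    fu = f0 * fdist.ppf(1 - ALPHA / 2, df2, df1)
    l31 = (fl - 1) / (fl + k - 1)
    u31 = (fu - 1) / (fu + k - 1)
    l3k = 1 - 1 / fl
    u3k = 1 - 1 / fu

    fj = msc / mse
    vn = df2 * (k * icc21 * fj + n * (1 + (k - 1) * icc21) - k * icc21) ** 2
    vd = df1 * k**2 * icc21**2 * fj**2 + (
        n * (1 + (k - 1) * icc21) - k * icc21
    ) ** 2
    v = vn / vd
    f2u = fdist.ppf(1 - ALPHA / 2, df1, v)
    f2l = fdist.ppf(1 - ALPHA / 2, v, df1)
    l21 = n * (msr - f2u * mse) / (
        f2u * (k * msc + (k * n - k - n) * mse) + n * msr
    )
    u21 = n * (f2l * msr - mse) / (
        k * msc + (k * n - k - n) * mse + n * f2l * msr
    )
    return {
        "icc21": icc21, "icc21_lo": l21, "icc21_hi": u21,
        "icc31": icc31, "icc31_lo": l31, "icc31_hi": u31,
        "icc3k": icc3k, "icc3k_lo": l3k, "icc3k_hi": u3k,
    }


def pingouin_estimates(tab):
    n, k = tab.shape
    df = pd.DataFrame({
        "subject": np.repeat(np.arange(n), k),
        "rater": np.tile(np.arange(k), n),
        "value": tab.ravel(),
    })
    res = pg.intraclass_corr(df, targets="subject", raters="rater",
                             ratings="value")
    res = res.set_index("Type")
    return {
        "pg_icc21": res.at["ICC(A,1)", "ICC"],
        "pg_icc31": res.at["ICC(C,1)", "ICC"],
        "pg_icc3k": res.at["ICC(C,k)", "ICC"],
        "pg_icc21_lo": res.at["ICC(A,1)", "CI95"][0],
        "pg_icc21_hi": res.at["ICC(A,1)", "CI95"][1],
        "pg_icc31_lo": res.at["ICC(C,1)", "CI95"][0],
        "pg_icc31_hi": res.at["ICC(C,1)", "CI95"][1],
        "pg_icc3k_lo": res.at["ICC(C,k)", "CI95"][0],
        "pg_icc3k_hi": res.at["ICC(C,k)", "CI95"][1],
    }


def main():
    long = pd.read_csv(sys.argv[1])
    rows = []
    for tid, grp in long.groupby("table", sort=True):
        tab = grp.pivot(index="subject", columns="rater",
                        values="value").to_numpy()
        row = {"table": tid}
        row.update(icc_all(tab))
        row.update(pingouin_estimates(tab))
        rows.append(row)
    pd.DataFrame(rows).to_csv(sys.argv[2], index=False,
                              float_format="%.17g")


if __name__ == "__main__":
    main()
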