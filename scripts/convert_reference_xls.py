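#!/usr/bin/env python
"""One-off converter: multi-sheet Excel feature workbook -> silacqc CSV.

The package core reads only CSV/TSV in the schema of
silacqc::psm_schema(). Reference feature tables are distributed as a
four-sheet spreadsheet (one sheet per mix ratio, e.g. sheet "1_1" for
the 1:1 sample); this script extracts one sheet and renames/assembles
its columns into that schema.

Because published column headers vary, the mapping from source headers
to schema names is supplied as a two-column CSV (source,target). Any
schema column absent from the mapping is written empty (= missing).
Multiple noise-peak source columns may map to the single target
`noise_peaks`; they are joined with ';'.

Requires: pandas plus an Excel engine (xlrd for .xls, openpyxl for
.xlsx). Run once, offline use of the output thereafter:

    python scripts/convert_reference_xls.py workbook.xls 1_1 \
        colmap.csv inst/extdata/additional2_1_1.csv
"""

import sys

import pandas as pd

SCHEMA = (
    ["spectrum_id", "peptide", "protein_id", "charge", "M_t", "M_e",
     "asap_ratio"]
    + [f"EP_L{i}" for i in range(4)]
    + [f"EP_H{i}" for i in range(4)]
    + ["M_pp", "noise_peaks"]
    + [f"L1_{i}" for i in range(3)]
    + [f"L2_{i}" for i in range(3)]
    + [f"H1_{i}" for i in range(3)]
    + [f"H2_{i}" for i in range(3)]
)


def main(xls_path, sheet, colmap_path, out_path):
    colmap = pd.read_csv(colmap_path)
    raw = pd.read_excel(xls_path, sheet_name=sheet)
    out = pd.DataFrame()
    for target in SCHEMA:
        sources = colmap.loc[colmap["target"] == target, "source"].tolist()
        missing = [s for s in sources if s not in raw.columns]
        if missing:
            sys.exit(f"source column(s) not in sheet {sheet!r}: {missing}")
        if not sources:
            out[target] = ""
        elif target == "noise_peaks":
            out[target] = raw[sources].apply(
                lambda row: ";".join(str(v) for v in row.dropna()), axis=1)
        else:
            out[target] = raw[sources[0]]
    if out["spectrum_id"].eq("").all():
        out["spectrum_id"] = [f"row{i + 1}" for i in range(len(out))]
    out.to_csv(out_path, index=False)
    print(f"wrote {out_path}: {len(out)} records from sheet {sheet!r}")


if __name__ == "__main__":
    if len(sys.argv) != 5:
        sys.exit(__doc__)
    main(*sys.argv[1:])
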