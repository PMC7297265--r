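"""Delaunay tetrahedralization helper.

Reads N*3 float64 coordinates from the input file, computes the Delaunay
tetrahedralization (Qhull via scipy), and writes int32 output: the number of
tetrahedra followed by the 0-based vertex indices (row major, 4 per tet).
Exit code 3 flags globally degenerate input (all points coplanar).
"""
import sys

import numpy as np
from scipy.spatial import Delaunay
from scipy.spatial import QhullError

def main():
    fin, fout = sys.argv[1], sys.argv[2]
    pts = np.fromfile(fin, dtype=np.float64).reshape(-1, 3)
    try:
        tri = Delaunay(pts)
    except QhullError:
        sys.exit(3)
    s = np.ascontiguousarray(tri.simplices.astype(np.int32))
    with open(fout, "wb") as f:
        np.array([s.shape[0]], dtype=np.int32).tofile(f)
        s.tofile(f)

if __name__ == "__main__":
    main()
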