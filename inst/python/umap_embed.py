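"""Joint 2D UMAP embedding of flattened signals.

Usage: python umap_embed.py in.csv out.csv n_neighbors min_dist seed
Reads a headerless CSV (one flattened signal per row), writes a
headerless CSV of 2D coordinates in the same row order.
"""
import sys

import numpy as np
import umap


def main():
    fin, fout, n_neighbors, min_dist, seed = sys.argv[1:6]
    X = np.loadtxt(fin, delimiter=",", ndmin=2)
    emb = umap.UMAP(
        n_neighbors=int(n_neighbors),
        min_dist=float(min_dist),
        n_components=2,
        random_state=int(seed),
    ).fit_transform(X)
    np.savetxt(fout, emb, delimiter=",")


if __name__ == "__main__":
    main()
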