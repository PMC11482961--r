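"""2-D UMAP embedding of a precomputed distance matrix.

Usage: python umap_embed.py DIST_TSV OUT_TSV N_NEIGHBORS MIN_DIST SEED

DIST_TSV: square symmetric distance matrix, tab-separated, no header.
Writes an n x 2 tab-separated coordinate matrix to OUT_TSV.
"""
import sys
import warnings

import numpy as np


def main(argv):
    dist_path, out_path = argv[0], argv[1]
    n_neighbors = int(argv[2])
    min_dist = float(argv[3])
    seed = int(argv[4])
    # umap's disconnected-components fallback draws from the global numpy
    # RNG, so random_state alone does not make it reproducible
    np.random.seed(seed)
    with warnings.catch_warnings():
        warnings.simplefilter("ignore")
        import umap
        D = np.loadtxt(dist_path, delimiter="\t", ndmin=2)
        # seeded random init: the spectral initialisation of graphs with
        # several connected components is not reproducible across
        # interpreter sessions
        emb = umap.UMAP(
            n_components=2,
            metric="precomputed",
            n_neighbors=n_neighbors,
            min_dist=min_dist,
            random_state=seed,
            init="random",
        ).fit_transform(D)
    np.savetxt(out_path, emb, delimiter="\t")


if __name__ == "__main__":
    main(sys.argv[1:])
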