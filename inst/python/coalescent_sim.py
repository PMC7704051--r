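"""Coalescent haplotype simulation backend.

Simulates a single-population sample under an exponential-growth demography
(present size --n0 shrinking back at rate --growth until the ancestral size
--ne-ancestral, constant before that) with msprime, drops non-biallelic and
duplicate-position sites, and writes:

  <out>.pos   one 1-based integer physical position per line
  <out>.mat   raw uint8 genotype matrix, site-major: for each site in order,
              n_haplotypes bytes (0/1)

Invoked by the R package; not a user-facing tool.
"""
import argparse
import math
import sys

import msprime
import numpy as np


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--n-samples", type=int, required=True,
                    help="diploid sample count")
    ap.add_argument("--region-bp", type=float, required=True)
    ap.add_argument("--mu", type=float, default=1.25e-8)
    ap.add_argument("--rec", type=float, default=1e-8)
    ap.add_argument("--ne-ancestral", type=float, default=10000)
    ap.add_argument("--n0", type=float, default=4e6)
    ap.add_argument("--growth", type=float, default=0.05)
    ap.add_argument("--seed", type=int, required=True)
    ap.add_argument("--out", required=True)
    args = ap.parse_args()

    dem = msprime.Demography()
    if args.growth > 0 and args.n0 > args.ne_ancestral:
        dem.add_population(name="A", initial_size=args.n0,
                           growth_rate=args.growth)
        T = math.log(args.n0 / args.ne_ancestral) / args.growth
        dem.add_population_parameters_change(
            time=T, population="A", initial_size=args.ne_ancestral,
            growth_rate=0)
    else:
        dem.add_population(name="A", initial_size=args.ne_ancestral)

    ts = msprime.sim_ancestry(
        samples=args.n_samples, demography=dem,
        sequence_length=args.region_bp, recombination_rate=args.rec,
        random_seed=args.seed)
    ts = msprime.sim_mutations(
        ts, rate=args.mu, random_seed=args.seed + 1,
        model=msprime.BinaryMutationModel())

    n_hap = 2 * args.n_samples
    positions = []
    last_pos = 0
    n_written = 0
    with open(args.out + ".mat", "wb") as mat:
        for v in ts.variants():
            if len(v.alleles) != 2:
                continue
            ipos = int(v.site.position) + 1
            if ipos <= last_pos:
                continue  # collapse to unique integer positions
            g = v.genotypes
            if g.min() == g.max():
                continue
            positions.append(ipos)
            last_pos = ipos
            mat.write(g.astype(np.uint8).tobytes())
            n_written += 1
    with open(args.out + ".pos", "w") as f:
        f.write("\n".join(str(p) for p in positions))
        f.write("\n")
    sys.stdout.write(f"sites={n_written} haplotypes={n_hap}\n")


if __name__ == "__main__":
    main()
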