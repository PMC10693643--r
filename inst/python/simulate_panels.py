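"""Coalescent simulation worker.

Reads a JSON job list describing clean-split (or single-population control)
demographies and writes, per job, a small binary panel file:

    float64 n_sites, float64 n_haps,
    float64 positions[n_sites],
    uint8 haplotypes[n_sites * n_haps]   (site-major, 0/1)

Only biallelic segregating sites are emitted. A manifest.json listing the
completed jobs is written last so the caller can detect partial runs.

Usage: python simulate_panels.py jobs.json out_dir
"""

import json
import math
import os
import sys

import msprime
import numpy as np


def as_list(x):
    return x if isinstance(x, list) else [x]


def build_demography(spec):
    dem = msprime.Demography()
    if spec["type"] == "split":
        dem.add_population(name="CAB", initial_size=spec["n_cab"],
                           growth_rate=spec["alpha_cab"])
        dem.add_population(name="MOZ", initial_size=spec["n_moz"],
                           growth_rate=spec["alpha_moz"])
        dem.add_population(name="ANC", initial_size=spec["n_anc_merge"])
        dem.add_population_split(time=spec["gen_split"],
                                 derived=["CAB", "MOZ"], ancestral="ANC")
        dem.add_population_parameters_change(
            time=spec["gen_anc"], population="ANC",
            initial_size=spec["n_anc_fixed"], growth_rate=0)
        ss = as_list(spec["samples"])
        samples = {"CAB": ss[0], "MOZ": ss[1]}
    elif spec["type"] == "constant":
        dem.add_population(name="POP", initial_size=spec["n"])
        samples = {"POP": as_list(spec["samples"])[0]}
    else:
        raise ValueError("unknown demography type: %r" % spec["type"])
    return dem, samples


def rate_map(spec, L):
    if spec["type"] == "uniform":
        return spec["rate"]
    pos = np.atleast_1d(np.asarray(spec["positions"], dtype=float))
    rates = np.atleast_1d(np.asarray(spec["rates"], dtype=float))
    return msprime.RateMap(position=pos, rate=rates)


def run_job(job, out_dir):
    dem, samples = build_demography(job["demography"])
    L = float(job["sequence_length"])
    ts = msprime.sim_ancestry(
        samples=samples, demography=dem, sequence_length=L,
        recombination_rate=rate_map(job["recombination"], L),
        random_seed=int(job["seed"]))
    mts = msprime.sim_mutations(ts, rate=float(job["mutation_rate"]),
                                random_seed=int(job["seed"]) + 1)
    keep = np.array([len(s.alleles) == 2 for s in mts.sites()], dtype=bool)
    G = mts.genotype_matrix()
    pos = mts.tables.sites.position
    if keep.size:
        G = G[keep]
        pos = pos[keep]
    # clip any >1 allele index (cannot occur for biallelic rows, kept for safety)
    G = np.minimum(G, 1).astype(np.uint8)
    seg = (G.sum(axis=1) > 0) & (G.sum(axis=1) < G.shape[1])
    G = G[seg]
    pos = pos[seg]
    path = os.path.join(out_dir, "panel_%s.bin" % job["id"])
    with open(path, "wb") as fh:
        np.array([G.shape[0], G.shape[1]], dtype="<f8").tofile(fh)
        pos.astype("<f8").tofile(fh)
        G.tofile(fh)
    return {"id": job["id"], "file": os.path.basename(path),
            "n_sites": int(G.shape[0]), "n_haps": int(G.shape[1])}


def main(argv):
    jobs_path, out_dir = argv[1], argv[2]
    with open(jobs_path) as fh:
        jobs = json.load(fh)["jobs"]
    os.makedirs(out_dir, exist_ok=True)
    manifest = [run_job(job, out_dir) for job in jobs]
    with open(os.path.join(out_dir, "manifest.json"), "w") as fh:
        json.dump(manifest, fh)


if __name__ == "__main__":
    main(sys.argv)
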