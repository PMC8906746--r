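"""Coalescent panel simulation backend.

Reads a JSON demography/sampling config (path given as argv[1]), simulates each
chromosome with msprime, and writes one whitespace-delimited table per
chromosome into the output directory: column 1 is the 1-based integer site
position, the remaining columns are 0/1 alleles for each haplotype (two
consecutive columns-rows per diploid, in the sample order recorded in
samples.txt). The ancestral allele is always 0. Only segregating sites are
emitted.

Config keys:
  populations: [{name, size}]            diploid sizes
  splits:      [{time, derived, ancestral}]   backwards-in-time merges
  pulses:      [{time, source, recipient, fraction}]  forward-in-time pulse:
               `recipient` receives `fraction` of its ancestry from `source`
  bottlenecks: [{population, time, intensity}]  intensity in coalescent units;
               msprime strength = 2 * N_population * intensity
  samples:     {population: n_diploids}
  chromosomes: {name: length_bp}
  mutation_rate, recombination_rate (per bp per generation), seed, out_dir
"""

import json
import os
import sys

import msprime
import numpy as np


def build_demography(cfg):
    dem = msprime.Demography()
    sizes = {}
    for pop in cfg["populations"]:
        dem.add_population(name=pop["name"], initial_size=pop["size"])
        sizes[pop["name"]] = pop["size"]
    for b in cfg.get("bottlenecks", []):
        dem.add_instantaneous_bottleneck(
            time=b["time"],
            strength=2.0 * sizes[b["population"]] * b["intensity"],
            population=b["population"],
        )
    for p in cfg.get("pulses", []):
        # Backwards in time: lineages now in the recipient trace back to the
        # source with probability `fraction`.
        dem.add_mass_migration(
            time=p["time"], source=p["recipient"], dest=p["source"],
            proportion=p["fraction"],
        )
    for s in cfg.get("splits", []):
        dem.add_population_split(
            time=s["time"], derived=[s["derived"]], ancestral=s["ancestral"]
        )
    dem.sort_events()
    return dem


def main():
    with open(sys.argv[1]) as fh:
        cfg = json.load(fh)
    out_dir = cfg["out_dir"]
    os.makedirs(out_dir, exist_ok=True)

    dem = build_demography(cfg)
    sample_sets = [
        msprime.SampleSet(int(n), population=pop)
        for pop, n in cfg["samples"].items()
        if int(n) > 0
    ]

    ids, pops = [], []
    for pop, n in cfg["samples"].items():
        for i in range(int(n)):
            ids.append("%s_%d" % (pop, i + 1))
            pops.append(pop)
    with open(os.path.join(out_dir, "samples.txt"), "w") as fh:
        for sid, pop in zip(ids, pops):
            fh.write("%s\t%s\n" % (sid, pop))

    base_seed = int(cfg["seed"])
    for idx, (chrom, length) in enumerate(cfg["chromosomes"].items()):
        ts = msprime.sim_ancestry(
            samples=sample_sets,
            demography=dem,
            sequence_length=float(length),
            recombination_rate=float(cfg["recombination_rate"]),
            random_seed=base_seed + 2 * idx + 1,
        )
        ts = msprime.sim_mutations(
            ts,
            rate=float(cfg["mutation_rate"]),
            random_seed=base_seed + 2 * idx + 2,
            model=msprime.BinaryMutationModel(),
        )
        if ts.num_sites:
            geno = ts.genotype_matrix()  # sites x haplotypes
            pos = np.array([s.position for s in ts.sites()], dtype=np.int64) + 1
            seg = (geno.max(axis=1) > 0) & (geno.min(axis=1) == 0)
            geno, pos = geno[seg], pos[seg]
        else:
            geno = np.zeros((0, 2 * len(ids)), dtype=np.int32)
            pos = np.zeros(0, dtype=np.int64)
        out = np.column_stack([pos, geno.astype(np.int64)])
        np.savetxt(os.path.join(out_dir, chrom + ".tsv"), out, fmt="%d")
    with open(os.path.join(out_dir, "DONE"), "w") as fh:
        fh.write("ok\n")


if __name__ == "__main__":
    main()
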