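"""msprime driver for stratsim.

Subcommands:
  simulate  -- simulate a cohort over independent chromosomes; store tree
               sequences, per-variant derived counts, and the sample table.
  export    -- extract a (filtered) dosage or haplotype matrix for one
               chromosome as a Feather file.
  ibd       -- exact pairwise IBD sharing (MRCA segments >= min span) summed
               over all chromosomes, from the stored genealogies.
  genes     -- simulate independent gene replicates (exons/introns) and export
               per-gene variant tables plus sparse carrier lists.

All stochastic steps derive their seeds from the single --config seed.
"""

import argparse
import json
import os
import sys

import msprime
import numpy as np
import pyarrow as pa
import pyarrow.feather as feather


# ---------------------------------------------------------------- demography

def build_demography(spec):
    """Construct an msprime Demography from the JSON spec written by R.

    Forward-time migration entries (proportion of a deme replaced per
    generation) map to msprime's backward-time rates; for a symmetric matrix
    the numerical values coincide.
    """
    kind = spec["kind"]
    deme_ids = list(spec["deme_ids"])
    n = len(deme_ids)
    mig = np.asarray(spec["migration"], dtype=float)
    dem = msprime.Demography()
    for d in deme_ids:
        dem.add_population(name=d, initial_size=float(spec["deme_Ne"]))
    for i in range(n):
        for j in range(i + 1, n):
            if mig[i, j] > 0:
                dem.set_symmetric_migration_rate([deme_ids[i], deme_ids[j]],
                                                 float(mig[i, j]))
    if kind == "recent":
        dem.add_population(name="anc", initial_size=float(spec["ancestral_Ne"]))
        dem.add_population_split(time=float(spec["collapse_time"]),
                                 derived=deme_ids, ancestral="anc")
    elif kind == "perpetual":
        horizon = spec.get("perpetual_horizon")
        if horizon is not None:
            # strong-migration closure: beyond the horizon the stepping-stone
            # system is replaced by one panmictic population of the total size
            dem.add_population(name="meta", initial_size=float(spec["deme_Ne"]) * n)
            dem.add_population_split(time=float(horizon),
                                     derived=deme_ids, ancestral="meta")
    elif kind == "complex":
        adm = spec["admixture"]
        t_adm = float(adm["admixture_time"])
        dem.add_population(name="srcA", initial_size=float(spec["ancestral_Ne"]))
        dem.add_population(name="srcB", initial_size=float(spec["ancestral_Ne"]))
        for d in deme_ids:
            f = float(adm["fractions"][d])
            f = min(max(f, 0.0), 1.0)
            dem.add_admixture(time=t_adm, derived=d, ancestral=["srcA", "srcB"],
                              proportions=[f, 1.0 - f])
        if float(adm["m1"]) > 0:
            dem.set_symmetric_migration_rate(["srcA", "srcB"], float(adm["m1"]))
        layers = adm.get("ancient_layers")
        if layers:
            for p in layers.get("populations", []):
                dem.add_population(name=p["name"], initial_size=float(p["size"]))
            for ev in layers.get("events", []):
                if ev["type"] == "split":
                    dem.add_population_split(time=float(ev["time"]),
                                             derived=list(ev["derived"]),
                                             ancestral=ev["ancestral"])
                elif ev["type"] == "admixture":
                    dem.add_admixture(time=float(ev["time"]), derived=ev["derived"],
                                      ancestral=list(ev["ancestral"]),
                                      proportions=[float(x) for x in ev["proportions"]])
                else:
                    raise ValueError("unknown ancient layer event: %r" % ev["type"])
        else:
            dem.add_population(name="anc", initial_size=float(spec["ancestral_Ne"]))
            dem.add_population_split(time=float(adm["source_split_time"]),
                                     derived=["srcA", "srcB"], ancestral="anc")
    else:
        raise ValueError("unknown model kind: %r" % kind)
    dem.sort_events()
    return dem


def chromosome_seeds(seed, n, streams=2):
    ss = np.random.SeedSequence(int(seed))
    state = ss.generate_state(n * streams, dtype=np.uint32)
    # msprime seeds must be in [1, 2^32 - 1]
    return (state.astype(np.uint64) % (2**31 - 1) + 1).astype(np.int64).reshape(n, streams)


def sample_sets(spec, samples_cfg):
    """samples_cfg: int (per deme) or {deme: count}."""
    deme_ids = list(spec["deme_ids"])
    if isinstance(samples_cfg, dict):
        counts = {d: int(samples_cfg.get(d, 0)) for d in deme_ids}
    else:
        counts = {d: int(samples_cfg) for d in deme_ids}
    return counts


def derived_counts(ts):
    out = np.empty(ts.num_sites, dtype=np.int32)
    for i, v in enumerate(ts.variants()):
        out[i] = int(v.genotypes.sum())
    return out


# ----------------------------------------------------------------- simulate

def cmd_simulate(args):
    cfg = json.load(open(args.config))
    spec = cfg["demography"]
    genome = cfg["genome"]
    outdir = args.out
    os.makedirs(outdir, exist_ok=True)
    dem = build_demography(spec)
    counts = sample_sets(spec, cfg["samples"])
    nchrom = int(genome["n_chromosomes"])
    L = float(genome["chromosome_length"])
    mu = float(genome["mutation_rate"])
    rr = float(genome["recombination_rate"])
    seeds = chromosome_seeds(cfg["seed"], nchrom)

    # sample table (individuals ordered by deme, matching msprime sample order)
    rows = []
    k = 0
    for d in spec["deme_ids"]:
        for _ in range(counts[d]):
            rows.append((f"s{k}", d))
            k += 1
    with open(os.path.join(outdir, "samples.tsv"), "w") as fh:
        fh.write("id\tdeme\n")
        for sid, d in rows:
            fh.write(f"{sid}\t{d}\n")

    nsites = []
    for c in range(nchrom):
        ts = msprime.sim_ancestry(
            samples=counts, demography=dem, sequence_length=L,
            recombination_rate=rr, random_seed=int(seeds[c, 0]))
        ts = msprime.sim_mutations(ts, rate=mu, random_seed=int(seeds[c, 1]),
                                   discrete_genome=False)
        ts.dump(os.path.join(outdir, f"chr{c + 1}.trees"))
        pos = np.array([s.position for s in ts.sites()], dtype=float)
        nhap = ts.num_samples
        nind = nhap // 2
        # one pass: derived counts plus dosage rows for the two classes every
        # analysis needs (common MAF > 0.05; minor allele count 2-4)
        dc = np.empty(ts.num_sites, dtype=np.int32)
        com_rows, com_idx = [], []
        rare_rows, rare_idx = [], []
        for i, v in enumerate(ts.variants()):
            g = v.genotypes
            d = int(g.sum())
            dc[i] = d
            mac = min(d, nhap - d)
            if mac / nhap > 0.05:
                com_idx.append(i)
                com_rows.append((g[0::2] + g[1::2]).astype(np.int8))
            if 2 <= mac <= 4:
                rare_idx.append(i)
                rare_rows.append((g[0::2] + g[1::2]).astype(np.int8))
        tab = pa.table({"pos": pos, "dcount": dc})
        feather.write_feather(tab, os.path.join(outdir, f"variants_chr{c + 1}.feather"))
        for tag, idx, rws in (("common", com_idx, com_rows),
                              ("raremac", rare_idx, rare_rows)):
            idx = np.asarray(idx, dtype=np.int64)
            mat = (np.vstack(rws) if len(rws)
                   else np.empty((0, nind), dtype=np.int8))
            cols = {"vidx": pa.array(idx + 1, type=pa.int64()),
                    "pos": pa.array(pos[idx] if len(idx) else []),
                    "dcount": pa.array(dc[idx] if len(idx) else [],
                                       type=pa.int32())}
            for j in range(nind):
                cols[f"g{j}"] = pa.array(mat[:, j], type=pa.int8())
            feather.write_feather(pa.table(cols),
                                  os.path.join(outdir, f"pre_{tag}_chr{c + 1}.feather"))
        nsites.append(int(ts.num_sites))
        print(f"chr{c + 1}: {ts.num_sites} sites", file=sys.stderr, flush=True)

    meta = {"config": cfg, "n_individuals": k, "n_sites": nsites,
            "engine": {"msprime": msprime.__version__}}
    json.dump(meta, open(os.path.join(outdir, "meta.json"), "w"), indent=1)


# ------------------------------------------------------------------- export

def select_indices(dc, nhap, args):
    keep = np.ones(len(dc), dtype=bool)
    freq = dc / float(nhap)
    mac = np.minimum(dc, nhap - dc)
    if args.dmin is not None:
        keep &= dc >= args.dmin
    if args.dmax is not None:
        keep &= dc <= args.dmax
    if args.macmin is not None:
        keep &= mac >= args.macmin
    if args.macmax is not None:
        keep &= mac <= args.macmax
    if args.mafmin is not None:
        keep &= np.minimum(freq, 1 - freq) > args.mafmin
    idx = np.flatnonzero(keep)
    if args.max_variants is not None and len(idx) > args.max_variants:
        rng = np.random.default_rng(int(args.subsample_seed or 1))
        idx = np.sort(rng.choice(idx, size=int(args.max_variants), replace=False))
    return idx


def cmd_export(args):
    ts = msprime.load(os.path.join(args.dir, f"chr{args.chrom}.trees"))
    nhap = ts.num_samples
    tab = feather.read_table(os.path.join(args.dir, f"variants_chr{args.chrom}.feather"))
    dc = tab["dcount"].to_numpy()
    pos = tab["pos"].to_numpy()
    if args.indices:
        idx = np.loadtxt(args.indices, dtype=np.int64, ndmin=1)
    else:
        idx = select_indices(dc, nhap, args)
    wanted = set(int(i) for i in idx)
    K = len(idx)
    if args.what == "dosage":
        ncol = nhap // 2
        out = np.empty((K, ncol), dtype=np.int8)
    else:
        ncol = nhap
        out = np.empty((K, ncol), dtype=np.int8)
    row_of = {int(v): r for r, v in enumerate(idx)}
    for i, v in enumerate(ts.variants()):
        if i in wanted:
            g = v.genotypes
            if args.what == "dosage":
                out[row_of[i]] = (g[0::2] + g[1::2]).astype(np.int8)
            else:
                out[row_of[i]] = g.astype(np.int8)
    cols = {"vidx": pa.array(idx + 1, type=pa.int64()),  # 1-based row in variant table
            "pos": pa.array(pos[idx]),
            "dcount": pa.array(dc[idx], type=pa.int32())}
    prefix = "g" if args.what == "dosage" else "h"
    for j in range(ncol):
        cols[f"{prefix}{j}"] = pa.array(out[:, j], type=pa.int8())
    feather.write_feather(pa.table(cols), args.out)


# --------------------------------------------------------------------- ibd

def cmd_ibd(args):
    meta = json.load(open(os.path.join(args.dir, "meta.json")))
    nchrom = int(meta["config"]["genome"]["n_chromosomes"])
    totals = {}
    for c in range(1, nchrom + 1):
        ts = msprime.load(os.path.join(args.dir, f"chr{c}.trees"))
        res = ts.ibd_segments(min_span=float(args.min_span), store_pairs=True)
        for a, b in res.pairs:
            ia, ib = a // 2, b // 2
            if ia == ib:
                continue
            key = (min(ia, ib), max(ia, ib))
            totals[key] = totals.get(key, 0.0) + float(res[(a, b)].total_span)
    with open(args.out, "w") as fh:
        fh.write("i\tj\tspan\n")
        for (ia, ib), s in sorted(totals.items()):
            fh.write(f"{ia}\t{ib}\t{s:.3f}\n")


# ------------------------------------------------------------------- genes

def cmd_genes(args):
    cfg = json.load(open(args.config))
    spec = cfg["demography"]
    outdir = args.out
    os.makedirs(outdir, exist_ok=True)
    dem = build_demography(spec)
    counts = sample_sets(spec, cfg["samples"])
    n_genes = int(cfg["n_genes"])
    n_exons = int(cfg.get("n_exons", 8))
    exon_len = int(cfg.get("exon_length", 160))
    intron_len = int(cfg.get("intron_length", 6938))
    recomb = bool(cfg.get("recombination", False))
    mu = float(cfg.get("mutation_rate", 1e-8))
    rr = float(cfg.get("recombination_rate", 1e-8))
    seeds = chromosome_seeds(cfg["seed"], n_genes)

    if recomb:
        L = n_exons * exon_len + (n_exons - 1) * intron_len
        exon_starts = np.arange(n_exons) * (exon_len + intron_len)
    else:
        L = n_exons * exon_len
        exon_starts = np.arange(n_exons) * exon_len
    exon_ends = exon_starts + exon_len

    nhap = 2 * sum(counts.values())
    dmax = int(cfg.get("export_dmax", max(1, int(0.005 * nhap))))

    reps = msprime.sim_ancestry(
        samples=counts, demography=dem, sequence_length=float(L),
        recombination_rate=rr if recomb else 0.0,
        random_seed=int(chromosome_seeds(cfg["seed"], 1)[0, 0]),
        num_replicates=n_genes)

    v_gene, v_pos, v_dc, v_exonic = [], [], [], []
    c_gene, c_vrow, c_ind, c_dos = [], [], [], []
    for g, ts in enumerate(reps):
        ts = msprime.sim_mutations(ts, rate=mu, random_seed=int(seeds[g, 1]),
                                   discrete_genome=False)
        vrow = 0
        for v in ts.variants():
            p = v.site.position
            exonic = bool(np.any((p >= exon_starts) & (p < exon_ends)))
            geno = v.genotypes
            d = int(geno.sum())
            v_gene.append(g + 1)
            v_pos.append(p)
            v_dc.append(d)
            v_exonic.append(exonic)
            vrow += 1
            if exonic and 0 < d <= dmax:
                dos = geno[0::2] + geno[1::2]
                nz = np.flatnonzero(dos)
                for i in nz:
                    c_gene.append(g + 1)
                    c_vrow.append(vrow)  # 1-based row within gene variant table
                    c_ind.append(int(i) + 1)
                    c_dos.append(int(dos[i]))
        if (g + 1) % 200 == 0:
            print(f"gene {g + 1}/{n_genes}", file=sys.stderr, flush=True)

    feather.write_feather(pa.table({
        "gene": pa.array(v_gene, type=pa.int32()),
        "pos": pa.array(v_pos, type=pa.float64()),
        "dcount": pa.array(v_dc, type=pa.int32()),
        "exonic": pa.array(v_exonic, type=pa.bool_())}),
        os.path.join(outdir, "gene_variants.feather"))
    feather.write_feather(pa.table({
        "gene": pa.array(c_gene, type=pa.int32()),
        "vrow": pa.array(c_vrow, type=pa.int32()),
        "ind": pa.array(c_ind, type=pa.int32()),
        "dosage": pa.array(c_dos, type=pa.int8())}),
        os.path.join(outdir, "gene_carriers.feather"))
    with open(os.path.join(outdir, "samples.tsv"), "w") as fh:
        fh.write("id\tdeme\n")
        k = 0
        for d in spec["deme_ids"]:
            for _ in range(counts[d]):
                fh.write(f"s{k}\t{d}\n")
                k += 1
    json.dump({"config": cfg, "n_haplotypes": nhap, "export_dmax": dmax,
               "exon_starts": exon_starts.tolist(), "length": int(L)},
              open(os.path.join(outdir, "meta.json"), "w"), indent=1)


def main():
    ap = argparse.ArgumentParser()
    sub = ap.add_subparsers(dest="cmd", required=True)

    p = sub.add_parser("simulate")
    p.add_argument("--config", required=True)
    p.add_argument("--out", required=True)
    p.set_defaults(func=cmd_simulate)

    p = sub.add_parser("export")
    p.add_argument("--dir", required=True)
    p.add_argument("--chrom", type=int, required=True)
    p.add_argument("--what", choices=["dosage", "haplotype"], default="dosage")
    p.add_argument("--out", required=True)
    p.add_argument("--dmin", type=int)
    p.add_argument("--dmax", type=int)
    p.add_argument("--macmin", type=int)
    p.add_argument("--macmax", type=int)
    p.add_argument("--mafmin", type=float)
    p.add_argument("--indices")
    p.add_argument("--max-variants", type=int, dest="max_variants")
    p.add_argument("--subsample-seed", type=int, dest="subsample_seed")
    p.set_defaults(func=cmd_export)

    p = sub.add_parser("ibd")
    p.add_argument("--dir", required=True)
    p.add_argument("--min-span", type=float, required=True, dest="min_span")
    p.add_argument("--out", required=True)
    p.set_defaults(func=cmd_ibd)

    p = sub.add_parser("genes")
    p.add_argument("--config", required=True)
    p.add_argument("--out", required=True)
    p.set_defaults(func=cmd_genes)

    args = ap.parse_args()
    args.func(args)


if __name__ == "__main__":
    main()
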