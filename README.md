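# mixmod

Mixed-modularity module detection in two-class heterogeneous networks
(2-HNs).

Chemical–gene systems — a drug–target network, or the molecular system of a
multicomponent herbal formula — couple two node classes through three edge
channels built from different data sources: chemical structural similarity
(A–A), chemical–gene interaction (A–B) and gene–gene interaction (B–B).
The channels differ in density and weight scale, so single-graph community
detection lets whichever channel is densest dominate. `mixmod` scores a
partition with **mixed modularity**,

```
mQ = (1/3) * sum_c { [l_Ac/m_A - (d_Ac/2m_A)^2]
                   + [l_Pic/m_Pi - k_Pic*d_Pic/m_Pi^2]
                   + [l_Bc/m_B - (d_Bc/2m_B)^2] }
```

— the mean of Newman–Girvan modularity on each within-class channel and
Barber bipartite modularity on the cross-class channel, each normalized by
its own channel total — and maximizes it with a Louvain-style two-phase
search whose aggregation step keeps the coarse network a valid 2-HN
(class-pure supernodes). Because every channel is normalized by its own
total weight, rescaling any one channel changes neither the score nor the
detected partition.

The package also provides:

* a labeled benchmark generator with planted mixed modules (LFR-style
  subnetworks per class, grouped into mixed modules and coupled by a
  tunable bipartite channel, with an optional weighted variant),
* partition metrics: normalized mutual information and classification
  accuracy (optimal one-to-one module matching),
* application-network construction from fingerprints and interaction
  tables (Tanimoto similarity edges at an inclusive 0.7 threshold,
  database-count gene weights), a similarity–interaction correlation test
  and a label permutation test,
* a sweep harness (`run_sweep()`) and a command-line wrapper
  (`inst/cli/mixmod.R`).

## Worked example

Generate a benchmark 2-HN with planted mixed modules, detect, evaluate:

```r
library(mixmod)

spec  <- benchmark_spec(muA = 0.2, muB = 0.2, p = 0.7, seed = 5L)
bench <- generate_benchmark(spec)
bench$net
#> <hetnet> 1000 nodes (400 A, 600 B); edges AA=805 AB=1600 BB=3430

res <- mixmod_detect(bench$net, detect_config(seed = 5L))
res
#> <mixmod_result> 12 modules (12 mixed), mQ = 0.6604, 4 level(s)

evaluate_partition(bench$labels, res$partition, bench$net)
#>   n_modules_found n_mixed_found       nmi    ca
#> 1              12            12 0.9906933 0.996
```

The detector recovers the 12 planted mixed modules; NMI 0.99 means the
found partition carries almost all the information of the planted one, and
CA 0.996 means 99.6% of nodes fall in the overlaps of the best one-to-one
module matching. `res$partition` maps each node to its module and
`classify_modules()` tags modules as mixed or single-class;
`export_module_network()` writes the module-level (supernode) network.

The same workflow runs from a shell:

```sh
Rscript inst/cli/mixmod.R generate --mua 0.2 --p 0.7 --seed 5 --out-prefix bench
Rscript inst/cli/mixmod.R detect --nodes bench_nodes.tsv --edges bench_edges.tsv \
    --seed 5 --out partition.tsv
#> detect: 12 modules (12 mixed), mQ 0.660369 [0.10s]
```

For a real system, build the network from data tables instead:

```r
net <- build_2hn(similarity_edges(read_fingerprints("fps.tsv"), 0.7),
                 chem_gene_edges = read.delim("chem_gene.tsv"),
                 gg_edges = gene_edges(read.delim("gene_gene.tsv")))
res <- mixmod_detect(net, detect_config(seed = 1L))
```

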