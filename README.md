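# polyexpress

Homoeolog expression bias, temporal expression shifts and co-expression
asymmetry in allopolyploid transcriptomes.

## The problem

Allotetraploid cotton carries two ancestral genomes side by side: every
gene tends to exist as a homoeologous pair with one copy on the A
subgenome (At) and one on the D subgenome (Dt).  During fiber
development — initiation (0–3 days post-anthesis, DPA), elongation
(3–20 DPA) and secondary-cell-wall (SCW) biosynthesis (15–40 DPA) — the
two copies are not used equally, and the two cultivated species
(*Gossypium hirsutum*, upland cotton, e.g. TM-1; *G. barbadense*,
extra-long-staple cotton, e.g. Hai7124) deploy them on different
schedules.  `polyexpress` implements the three analyses used to expose
these patterns from gene-level RNA-seq counts of fiber time courses, for
anyone comparing homoeolog usage across cultivars, species and
developmental stages:

1. **Subgenome bias calling.** For each homoeolog pair in each
   (cultivar, stage) group, replicate read counts are pooled and the At
   count is compared with the Dt count by Fisher's exact test against
   the rest-of-library margins.  P-values are Benjamini–Hochberg
   adjusted within the group, and a pair is called biased when
   additionally its group-mean FPKM ratio passes a 2-fold gate:

   call = At-biased  iff  FPKM_A / FPKM_D ≥ 2 and q < 0.05 (Dt symmetric).

   Per-cultivar summaries report the biased percentage and an exact
   binomial test of the At : Dt split against 0.5.  Strict cross-cultivar
   consensus patterns (biased the same way in *every* cultivar of a
   species) feed an 8-category interspecific classification.

2. **Temporal soft clustering and postponed expression.** Stage-course
   profiles (z-scored log2(FPKM+1) over 0–25 DPA) are soft-clustered by
   fuzzy c-means (membership u_ij = 1 / Σ_k (d_ij/d_ik)^(2/(m−1)),
   fuzzifier m = 1.25).  Each gene inherits the peak stage of its
   cluster; ortholog pairs whose peak moves to a later stage in
   *G. barbadense* (10→20, 10→25, 20→25 DPA) are classified as
   temporally postponed.

3. **Co-expression networks.** Per species, an unsigned weighted network
   a_ij = |cor(x_i, x_j)|^β (β chosen by scale-free topology fit) is
   summarised by the topological overlap matrix, modules are cut from
   the 1−TOM dendrogram, merged by eigengene correlation and cleaned by
   a kME sweep; module eigengenes are correlated with stages and the
   top-3 kME genes per module are reported as hubs, together with
   top-weight edge lists.

A negative-binomial simulator (`simulate_dataset()`) generates the full
seven-cultivar study design with planted bias, planted peak-stage shifts
and planted modules, so every stage of the pipeline is verifiable
against known truth without any sequencing data.

## Worked example

```r
library(polyexpress)

sim <- simulate_dataset(sim_config(n_pairs = 1000, seed = 42))
#> sim_dataset: 4000 genes x 72 samples; 2000 homoeolog pairs (seed 42)

res <- run_bias(sim$counts, sim$sheet, sim$pairs)
head(subset(transform(res$summary, pct_biased = round(pct_biased, 2),
                      direction_p = signif(direction_p, 3)),
            stage_dpa == 10), 4)
#>   species cultivar stage_dpa total_expressed total_biased n_a_biased n_d_biased
#> 1      Gb     3-79        10            1000           81         40         41
#> 2      Gb  Hai7124       10            1000           82         41         41
#> 3      Gb     R4-4        10            1000           86         43         43
#> 7      Gh     4005        10            1000           82         42         40
#>   pct_biased direction_p direction
#> 1        8.1       1.000      none
#> 2        8.2       1.000      none
#> 3        8.6       1.000      none
#> 7        8.2       0.912      none
```

Each row mirrors the per-cultivar bias summary: 1000 expressed pairs,
~8% called biased (10% planted, minus pairs silenced at this stage by
their temporal profile), an even At : Dt split (the simulator plants
50:50), hence `direction = none`.  Recovery against the planted truth:

```r
ev <- evaluate_bias_recovery(res$calls, sim$truth$bias)
unlist(ev[c("sensitivity", "empirical_fdr", "direction_accuracy")])
#>        sensitivity      empirical_fdr direction_accuracy
#>         0.95966387         0.01805675         1.00000000
```

So 96% of planted-biased, testable pairs are recovered, 1.8% of biased
calls are false, and every recovered call points in the planted
direction.  The interspecific classification at 10 DPA:

```r
res$interspecific_counts[["10"]]$by_category
#> A:none    A:D    A:A D:none    D:A    D:D none:A none:D
#>     34      2      4     36      2      0     33     38
```

`A:none` counts pairs At-biased in all four *G. hirsutum* cultivars but
unbiased in all three *G. barbadense* cultivars; `A:D` counts pairs with
opposite bias in the two species, and so on.  The temporal and network
stages run the same way via `run_temporal()` and `run_network()`, and a
thin command-line wrapper over these functions is installed at
`inst/scripts/polyexpress.R`.

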