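# mpaconnect

Biophysical larval-dispersal modelling and connectivity analysis for
networks of marine protected areas (MPAs).

Many coastal fishes are sedentary as adults and disperse only as pelagic
larvae drifting with ocean currents for a few weeks. Whether a system of
MPAs functions as a *network* — exchanging recruits, reseeding fished areas,
letting genes flow between reserves — is therefore a question about larval
transport. `mpaconnect` is for marine ecologists and conservation planners
who want to answer it with the standard biophysical chain:

1. **Lagrangian tracking** of virtual larvae in gridded daily current fields
   (NetCDF): tri-linear velocity interpolation, explicit Euler advection on
   the sphere, random-walk horizontal diffusion with the Monin–Ozmidov
   coefficient K_h = ε^(1/3) ℓ^(4/3), open-boundary loss, surface
   reflection, coastal standstill, and optional diel vertical migration
   (surface at night, 50 m by day).
2. **Connectivity matrix**: the probability c(i,j) that a larva released in
   MPA *j* ends its pelagic larval duration (PLD) inside MPA *i*
   (point-in-polygon on the final positions), with connectance, local
   retention c(i,i), self-recruitment c(i,i)/Σ_j c(i,j) and subsidy
   recruitment.
3. **Graph analysis** of the directed MPA network: upstream/downstream
   neighborhoods, strongly and weakly connected clusters, and betweenness
   centrality b(i) = Σ_{k≠i≠l} σ_kl(i)/σ_kl over hop-count shortest paths —
   the metric that singles out gateway MPAs.
4. **Larval export**: gridded abundance maps of final positions, shelf
   (< 200 m) retention, and the area-weighted fraction of shelf that
   receives no larvae.
5. **Sensitivity analyses**: replicated scenario runs over PLD (20–40 d),
   vertical migration and spawning month, summarised with OLS regressions
   on PLD, Student's t tests and one-way ANOVA.

A synthetic-domain module generates divergence-free current fields
(uniform, solid rotation, time-periodic double gyre, reversing boundary
jet), coastlines, bathymetry and MPA polygons, so the full pipeline runs
and is tested without downloading any ocean model output. Defaults follow
a dusky-grouper-like design: 10 release events every 3 days, 1000 larvae
per event per MPA at 0.2 m depth, a 7200 s time step, PLD 30 d.

## Worked example

```r
library(mpaconnect)

dom  <- gyre_jet_domain(n_days = 70, seed = 1)   # reference synthetic basin
cfg  <- sim_config(pld_days = 30, larvae_per_event = 100, seed = 42)
traj <- run_simulation(dom$field, dom$grid, dom$mpas, cfg)
traj
#> trajectory_record: 12000 larvae (0 lost, 216 standstill), PLD 30 d, K_h 164.88 m2/s

st <- assign_settlement(traj, dom$mpas)
cm <- connectivity_matrix(st$counts, st$released)
cm
#> connectivity_matrix: 12 MPAs, connectance 0.2292, detection floor 0.001

head(recruitment_stats(cm), 4)
#>   mpa    lr         sr   subsidy
#> 1   1 0.003 1.00000000 0.0000000
#> 2   2 0.004 0.04761905 0.9523810
#> 3   3 0.017 0.07555556 0.9244444
#> 4   4 0.031 0.11969112 0.8803089

g <- build_graph(cm)
head(rank_nodes(g), 2)
#>   rank mpa betweenness betweenness_norm downstream upstream strong_cluster ...
#> 1    1   5        28.0        0.2545455          3        2              3
#> 2    2   4        24.0        0.2181818          2        3              2

export_summary(traj, dom$grid, dom$mpas)
#> shelf_export_summary: 85.6% on shelf, 14.4% open sea, 12.0% in MPAs, 10.5% of shelf unseeded

round(dispersal_distances(traj)$pooled, 1)
#> median    q25    q75
#>   74.1   45.0  111.1
```

Reading the output: of 12,000 larvae released across the 12 MPAs, none left
the closed basin; 23% of the 144 possible MPA-to-MPA connections carry at
least one larva at the 10⁻³ detection floor; MPA 1 is a pure
self-recruiter while its neighbors are subsidised; MPAs 4 and 5 — the
eastern edge of the first MPA group — are the main gateways between groups
(highest betweenness); the network resolves into 8 strongly connected
clusters; and the median larva settles 74 km from its release point, with
10.5% of the continental shelf receiving no larvae at all.

Scenario analysis uses the same pieces:

```r
plan <- data.frame(pld = c(20, 30, 40))
res  <- run_scenarios(dom$field, dom$grid, dom$mpas, cfg, plan,
                      replicates = 10, base_seed = 100)
pld_regression(res, "connectance")   # slope per PLD day, SE, adj-R2, p
```

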