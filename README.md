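# schoolphi

Integrated-information analysis of collective states in small fish
schools (and other 2-6 individual animal groups).

## What it does, and for whom

For researchers in collective animal behaviour who want to quantify how
*integrated* a small group is — whether the school acts as an irreducible
causal unit or as independent / feed-forward-coupled individuals —
schoolphi implements the full pipeline:

1. **Binarize** 2-D trajectories (120 fps, mm) into N-bit collective
   states s(t) ∈ {0,1}^N under either
   *local* thresholds (ON = distance ∧ visual-field ∧ turning-rate
   conditions: ξ_D, ξ_VF, ξ_TR) or *global* thresholds (ON = aligned with
   the mean direction ∧ near the centre of mass: Ξ_AD, Ξ_CM), at a chosen
   timescale Δt = dt_frames / fps.
2. **Estimate** the state-by-node transition probability matrix
   P(x_i(t) = 1 | X(t−Δt)) under conditional independence (2^N × N).
3. **Compute integrated information** Φ (IIT 3.0) per collective state:
   Φ = min over unidirectional system cuts P→ of the extended earth
   mover's distance D(C(S), C(S_P→)) between the intact and cut
   conceptual structures, with the cut-one approximation (2N cuts) and
   main-complex search.  Small φ, concepts, MIPs and repertoires follow
   the IIT 3.0 conventions exactly; all transport problems are solved
   exactly in C++.
4. **Summarise**: ⟨Φ(N)⟩ and σ²(Φ(N)) over all 2^N states on threshold
   grids, Fano factors σ²/⟨Φ⟩ and their correlation with ⟨Φ⟩, normalized
   surfaces and weighted peak positions, top-k peak comparison of local
   vs global integrity across timescales, positional-leader and MIP-cut
   match rates for single-OFF states, and cohesion rates.

Because no trajectory data are deposited with the source analysis, a
first-class synthetic module generates Boids-style schools,
leader-follower chains, independent walkers (null model) and random
homogeneous Markov TPMs, seeded and reproducible.

## Worked example

```r
library(schoolphi)

cfg  <- generator_config(n_fish = 3, n_steps = 20000, seed = 1)
traj <- leader_follower_chain(cfg)          # fish 1 leads, 2 chases 1, 3 chases 2
rep_ <- match_report(traj, local_thresholds(400, 1.2 * pi, 0.001),
                     dt_frames = 10)        # timescale 10/120 s
print(rep_)
```

prints (exactly, for this seed):

```
Match report (N = 3, dt = 10 frames, scope = main_complex)
  single-OFF events:    1970 
  PL match rate:        100.0% 
  MIP-cut match rate:   100.0% 
  cohesion rate:        100.0% (100.0% at 700 mm)
```

Reading it: at the 10-frame timescale this synthetic school produced 1970
time steps in which exactly one fish was OFF (out of the Boids-like
interaction state).  In 100% of them the OFF fish was the positional
leader (the fish furthest forward along the mean swimming direction), and
in 100% of them the minimum-information partition of the estimated
network separated exactly that fish from the rest — the IIT signature of
leadership: an asymmetric, one-to-many causal relation between the front
fish and its followers.  The group stayed cohesive (all pairwise
distances ≤ 400 mm) throughout.

Per-state Φ by number of ON bits (`rep_$phi_by_on_count`, same run):

```
     0      1      2      3 
0.1242 0.2196 0.1468 0.2184
```

Lower-level entry points: `local_collective_state()`,
`global_collective_state()`, `estimate_tpm()`, `big_phi()`,
`main_complex()`, `phi_per_state()`, `phi_surface()`,
`local_global_difference()`, `phi_fano_correlation()`.

A command-line interface covers the same pipeline:

```sh
Rscript -e 'schoolphi::cli_main()' fixtures --out fixtures --seed 1
Rscript -e 'schoolphi::cli_main()' encode --input fixtures/boids_school.csv \
    --dt 20 --xi-d 400 --xi-vf 6.28 --xi-tr 0 --out states.csv
Rscript -e 'schoolphi::cli_main()' tpm --input states.csv --out tpm.txt
Rscript -e 'schoolphi::cli_main()' phi --tpm tpm.txt --state 7 --out phi.json
```

## Documentation

The methods vignette (`vignettes/group-integrity-methods.Rmd`) documents
the model stage by stage: the encoding conventions and their flags, the
TPM estimation choices, the IIT 3.0 conventions (repertoires, partitions,
extended EMD, tie-breaking, tolerances), what the synthetic world does
and does not emulate, and known limitations.
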