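# gullteb — time-energy budgets of GPS/accelerometer-tracked herring gulls

Breeding herring gulls (*Larus argentatus*) choose between foraging
habitats with very different prey: high-caloric anthropogenic food
(fishery discards at sea, refuse in urban areas) versus low-caloric
intertidal bivalves and terrestrial invertebrates. `gullteb` asks what
each strategy *costs*, by building per-trip time-energy budgets from
bird-borne GPS trackers with tri-axial accelerometers, and testing
whether hourly energy expenditure differs between habitat strategies.

The pipeline, for each bird:

1. **Trip segmentation** — a foraging trip runs from the last fix
   within 100 m of the nest before an excursion to the first fix back;
   each fix gets a *centered duration* (mean of backward and forward
   inter-fix intervals, halved at trip edges, so weights telescope to
   the elapsed trip time). QC drops trips with away-gaps > 20 min or
   burst coverage < 80%.
2. **Behavior classification** — 20 Hz × 1 s acceleration bursts →
   features (per-axis moments, dynamic body acceleration, dominant
   heave frequency) → random forest → 11 fine behaviors → 4 energetic
   classes: inactive, terrestrial movement, soaring flight, flapping
   flight.
3. **Movement modes** — expectation-maximization binary clustering of
   speed and turning angle into HL/HH/LL/LH; HL (fast, straight) =
   commuting, excluded from habitat use.
4. **Habitat assignment** — polygon membership with a 50 m tidal-edge
   buffer and a behavior-conditional mudflat rule; a trip takes the
   habitat holding ≥ 50% of its non-commuting fixes, else `mixed`.
5. **Energetics** — BMR (kJ/day) = 2.3 · W_g^0.774;
   RMR = 1.7 × BMR; class rates per hour: inactive = RMR, terrestrial
   movement = 2 × BMR, soaring = 2 × RMR, flapping = 7 × RMR. Trip
   energy = Σ centered duration × class rate.
6. **Inference** — linear mixed models of log duration, √ flapping
   hours and log hourly rate on habitat category (bird as random
   intercept), LRT vs the null, ΔAICc, Tukey letter groups, marginal
   and conditional R².
7. **Scenarios** — daily budgets, assimilation-corrected gross intake
   and flatfish equivalents, hypothetical-trip costs.

A synthetic-data module generates gull-days with known ground truth
(true behaviors, commuting legs, habitats, and independently computed
trip energies), so every stage is testable without any field data. See
the methods vignette (`vignettes/time-energy-budgets.Rmd`) for the
model details and design decisions.

## Worked example

```r
library(gullteb)

energetic_profile(1000)
#> Energetic profile: mass 1000 g, BMR 20.11 kJ/h, RMR 34.20 kJ/h
#> Behavior rates (kJ/h):
#>             inactive terrestrial_movement       soaring_flight
#>                34.20                40.23                68.39
#>      flapping_flight
#>               239.37
```

A gull spending 14 h/day at the colony at 33 kJ/h and 10 h/day on
discard-foraging trips at 100 kJ/h:

```r
sp <- scenario_spec(hours_colony = 14, rate_colony = 33,
                    hours_away = 10, rate_away = 100)
daily_cost(sp)
#> [1] 1462
prey_equivalents(daily_cost(sp), sp)
#> $gross_kJ
#> [1] 1949
#> $n_prey
#> [1] 23
extra_prey(1462, 1162, sp)
#> $extra_gross_kJ
#> [1] 400
#> $extra_items
#> [1] 5
```

So a discard specialist needs 1462 kJ/day net; at 75% assimilation
that is 1949 kJ gross, i.e. 23 discarded flatfish (84 kJ each) — 5 fish
per day more than a bird foraging in cheap habitats (1162 kJ/day).

End to end on synthetic data:

```r
cfg <- sim_config(seed = 1)
sim <- simulate_bird_days(cfg, n_birds = 17, n_days = 3)

# train the burst classifier on labeled synthetic bursts
feats <- list(); labs <- character()
set.seed(1)
for (b in fine_behaviors()) for (i in 1:40) {
  feats[[length(feats) + 1]] <- extract_features(simulate_acc_burst(b, cfg))
  labs <- c(labs, b)
}
features <- do.call(rbind, feats)
features$bird_id <- "train"; features$t <- seq_len(nrow(features))
clf <- train_classifier(features, labs, seed = 1)

res <- run_teb_pipeline(sim$fixes, sim$bursts, sim$landscape,
                        masses = sim$birds[, c("bird_id", "mass_g")],
                        classifier = clf)
round(category_rates(res), 1)     # mean kJ/h per habitat category
#>  intertidal      marine terrestrial       urban
#>        71.5        95.2        71.4        95.5
habitat_rate_contrast(category_rates(res))
#> [1] 33.49
```

The simulator builds urban/marine trips flight-heavy (flapping fraction
0.30 of away-time) and intertidal/terrestrial trips ground-heavy
(0.17), so hourly expenditure comes out ~34% higher for the
high-caloric strategies — the pipeline recovers the planted contrast.

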