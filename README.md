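# coastflight

Departure and routing decisions of coastal songbird migrants from
automated radio-telemetry.

Nocturnally migrating thrushes (blackbirds, redwings, song thrushes)
stopping over on a coastline that borders an open bight face a choice each
autumn night: stay, follow the coast (*alongshore*), or cross the open
water (*offshore*). `coastflight` implements the full analysis pipeline
for studying those decisions with a Motus-style automated receiver
network, and a synthetic-data module that generates the whole study with
known ground truth so every stage can be validated end to end:

1. **Detection QC** — score each detection run's probability of being a
   false positive from its signal features (burst slop, frequency sd,
   slop, run length, receiver-hour and tag-level short-run statistics,
   ±25-min context) with a per-network logistic filter; keep runs with
   P(false positive) strictly below 0.8.
2. **Flight segmentation** — chain filtered runs while inter-detection
   gaps stay under 7 h; accept chains spanning ≥ 35 km or touching ≥ 3
   receivers; keep each bird's first flight.
3. **Route classification** — offshore iff the flight starts above
   54.135° N and ends below 8.08° E, or touches an offshore island /
   platform receiver; alongshore otherwise.
4. **Weather annotation** — trilinear interpolation of gridded u/v wind,
   humidity, pressure and temperature to sunset at the decision location;
   12–18 UTC block means for precipitation and cloud; species-level
   z-transforms; VIF collinearity screening.
5. **Departure model** — time-dependent Cox proportional hazards in
   counting-process `(start, stop]` form on the stopover clock,

   `h(t | x) = h0(t) · exp(β_v z(v-wind) + β_cloud z(cloud) + …)`,

   clustered per individual (robust sandwich variance), with Schoenfeld
   PH diagnostics, species × stopover-period interaction terms (cuts at
   10 and 21 days), all-subsets AIC selection, and flight-probability
   prediction curves (`1 − S(t)`).
6. **Route model** — binomial GLM
   `logit P(offshore) = α + β_u z(u-wind) + β_stop z(stopover) + …`
   with all-subsets AIC selection and Nagelkerke pseudo-R².

All user-facing functions take data frames first and return tibbles, so
stages chain with the pipe; fitted models support `tidy()`, `glance()`
and `autoplot()`.

## Worked example

A complete synthetic study — two autumn tagging seasons, 152 birds,
weather-driven behaviour — pushed through the same pipeline a field
dataset would use:

```r
library(coastflight)
library(dplyr)

study <- simulate_departure_study(n_birds = 152, seed = 2017)
net   <- generate_network(n_coastal = 20, n_offshore = 4, seed = 2018)
runs  <- simulate_detections(study$truth, net, noise_params(), seed = 2019)

feats <- compute_run_features(runs)
filter_model <- fit_filter_model(feats, feats$truth, seed = 1,
                                 network_id = "bight")
glance(filter_model)
#> # A tibble: 1 × 4
#>       n n_false_positive auroc network_id
#>   <int>            <int> <dbl> <chr>
#> 1  6309             4859     1 bight

kept <- score_and_filter(runs, filter_model, threshold = 0.8)$kept

flights <- segment_flights(kept, net) |>
  first_flights() |>
  classify_route(route_rule(offshore_station_ids =
                              net$station_id[net$offshore_flag])) |>
  stopover_metrics(study$deployments)
count(flights, route)
#> # A tibble: 2 × 2
#>   route          n
#>   <chr>      <int>
#> 1 alongshore   100
#> 2 offshore      44
mean(flights$min_stopover_days)
#> [1] 15.5
```

The filter separates the injected false positives perfectly (AUROC 1 —
synthetic noise is cleanly separable; field data will be harder), 144 of
152 birds yield a first flight, about 30% head offshore, and the mean
minimum stopover is 15.5 days.

```r
dep_fit <- fit_departure_cox(study$rows, ~ v_wind_z + total_cloud_z)
tidy(dep_fit)
#> # A tibble: 2 × 7
#>   term          estimate exp_estimate std_error robust_se statistic  p_value
#> 1 v_wind_z        -1.22         0.296    0.127     0.134      -9.06 1.26e-19
#> 2 total_cloud_z   -0.570        0.566    0.0873    0.0852     -6.69 2.27e-11

test_ph(dep_fit)
#> # A tibble: 3 × 5
#>   term          correlation   chisq    df p_value
#> 1 v_wind_z         -0.00501 0.00667     1   0.935
#> 2 total_cloud_z    -0.00406 0.00517     1   0.943
#> 3 GLOBAL           NA       0.0120      2   0.994
```

Negative coefficients mean birds depart under southward (tailwind) v-wind
components and clear skies; the fitted −1.22 and −0.57 (robust SEs 0.13
and 0.09) bracket the generating values −1.03 and −0.54, and the
Schoenfeld test finds no proportional-hazards violation, as expected for
a time-constant simulated effect.

```r
route_rows <- simulate_route_study(n_birds = 500, seed = 2020)
route_fit  <- fit_route_glm(route_rows, ~ u_wind_z + min_stopover_days_z)
tidy(route_fit)
#> # A tibble: 3 × 5
#>   term                estimate std_error statistic  p_value
#> 1 (Intercept)           -0.771     0.113     -6.85 7.40e-12
#> 2 u_wind_z              -1.30      0.173     -7.51 5.76e-14
#> 3 min_stopover_days_z    0.705     0.115      6.15 7.98e-10

glance(route_fit)$r2_nagelkerke
#> [1] 0.254
```

Westward winds (negative u) and longer stopovers favour the offshore
crossing, again bracketing the generating coefficients (−1.21 and 0.90).

See `vignettes/coastflight-methods.Rmd` for the models, defaults, and the
design of the synthetic study.

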