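# egmb

Mass-balance estimation of per-taxon net growth rates in semi-continuously
fed anaerobic fermenters, from 16S rRNA gene relative-abundance tables and
reactor operating parameters.

## Who this is for

Reactors fed with waste activated sludge (WAS) receive a constant influx of
upstream microorganisms, so the DNA detected in the reactor mixes organisms
that actually grow there with feed-borne biomass that is merely being
decomposed. Relative abundance cannot tell these apart. If you run (or
simulate) a well-mixed reactor on a discard-and-refill schedule and have
feed and reactor community profiles plus VSS measurements, this package
turns them into per-taxon net growth rates and guild assignments
(syntrophs, methanogens, fermenters, WAS-associated populations).

## The model

For taxon *x* in a completely mixed reactor of working volume `Vc` [mL],
exchanging `v` mL of mixed liquor every `τ` days (volumetric rate
`Q = v/τ`), with VSS concentrations `Cf` (feed) and `Cc` (reactor) and
relative abundances `p_f` and `p_c`, the steady-state mass balance gives

```
SRT  = Vc · τ / v
μ_x  = 1/SRT − (Q · Cf · p_f) / (Vc · Cc · p_c)      [1/d]
```

Every estimated rate is capped at `1/SRT`, with equality exactly for taxa
absent from the feed. A taxon present in the feed but undetected in the
reactor is reported as washed out (no pseudocounts, no sentinel rates).
Remaining taxa are classified by lineage keywords (known syntrophs and
methanogens) or, failing that, by the sign of `μ_x`: positive → fermenter,
negative → WAS-associated. A synthetic reactor simulator with known
ground-truth rates makes the whole pipeline testable end to end.

## Worked example

```r
library(egmb)

# 150 mL reactor, 3 mL exchanged every 2 d, feed VSS 6.2 g/L, reactor VSS 10 g/L
cfg <- reactor_config(Vc = 150, exchange_volume = 3, exchange_interval = 2,
                      Cf = 6.2, Cc = 10)
compute_srt(cfg)
#> [1] 100

# A taxon absent from the feed sits exactly at the washout ceiling 1/SRT:
compute_growth_rate(p_reactor = 0.01, p_feed = 0, cfg)$mu
#> [1] 0.01

# A taxon at 5% of the feed but only 1% of the reactor is being decomposed:
compute_growth_rate(p_reactor = 0.01, p_feed = 0.05, cfg)$mu
#> [1] -0.021
```

`0.01 /d` is the fastest net growth the 100-day-SRT schedule can sustain at
steady state; `-0.021 /d` means that taxon's standing stock is maintained
only by immigration while it decays inside the reactor.

The numbered scripts under `analysis/` run the full workflow on simulated
communities (simulate → growth rates → guilds → performance → report),
writing tables under `results/`. With the shipped seed, the guild summary of
`analysis/05_report.R` shows the expected SRT response — growers track the
rising ceiling while decayers sink faster at short SRT:

```
         guild mean_mu_control mean_mu_srt37.5 mean_mu_srt2.34375
     fermenter          0.0064          0.0173             0.2619
    methanogen          0.0049          0.0134             0.2047
      syntroph          0.0071          0.0189             0.2809
was_associated         -0.0360         -0.0976            -2.0707
```

and `analysis/03_classify_guilds.R` reports every estimated OTU consistent
with the simulator's ground truth (`truth-consistent: 30/30` per reactor).

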