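---
title: "Mass-balance growth rates in semi-continuous fermenters: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-balance growth rates in semi-continuous fermenters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A sludge fermenter fed with waste activated sludge (WAS) receives a massive,
continuous immigration of microorganisms from the upstream aerobic process.
A 16S rRNA gene survey of such a reactor therefore mixes two very different
kinds of populations: organisms that actually grow in the fermenter
(fermenters, syntrophs, methanogens) and feed-borne organisms that are being
decomposed while still contributing DNA. Relative abundance alone cannot
separate them. This package separates them by mass balance: given how much
of a taxon flows in with the feed, how much stands in the reactor, and how
fast solids leave, its net growth rate inside the reactor is determined.

## The steady-state estimator

Consider one taxon $x$ in a well-mixed reactor of working volume $V_c$ [mL]
operated semi-continuously: every $\tau$ days a volume $v$ [mL] of mixed
liquor is discarded and replaced by feed sludge. Biomass is tracked through
volatile suspended solids (VSS), with concentrations $C_f$ (feed), $C_c$
(reactor) and $C_d$ (discard) in g/L, and the taxon's share of each
community is its relative abundance $p_{x,f}$, $p_{x,c}$, $p_{x,d}$.
Writing $Q = v/\tau$ [mL/d] for the volumetric exchange rate, the balance
on the taxon's standing stock $N_x = V_c C_c p_{x,c}$ is

$$\frac{\Delta N_x}{\Delta t} = Q C_f p_{x,f} - Q C_d p_{x,d} + \mu_x N_x ,$$

with $\mu_x$ the first-order net growth rate (growth minus decay). Because
the reactor is completely mixed, the discard stream has the reactor's own
composition ($C_d = C_c$, $p_{x,d} = p_{x,c}$), so the outflow term reduces
to $N_x \, Q/V_c = N_x/\mathrm{SRT}$ with
$\mathrm{SRT} = V_c \tau / v$ the solids retention time. At steady state
$\Delta N_x/\Delta t = 0$ and

$$\mu_x = \frac{1}{\mathrm{SRT}} - \frac{Q C_f\, p_{x,f}}{V_c C_c\, p_{x,c}}.$$

Both numerator and denominator carry mL·g/L = mg, so the unit factor
cancels and $\mu_x$ is in 1/d. Three structural facts follow and are
tested as invariants:

* $\mu_x \le 1/\mathrm{SRT}$, with equality exactly when the taxon is
  absent from the feed — a purely resident taxon at steady state must grow
  exactly as fast as it is washed out;
* $\mu_x$ is strictly decreasing in $p_{x,f}$ and strictly increasing in
  $p_{x,c}$;
* scaling the feed term $Q C_f$ and the standing-stock term $V_c C_c$ by a
  common factor leaves $\mu_x$ unchanged.

A taxon detected in the feed but not in the reactor satisfies no finite
balance: it has been washed out. `compute_growth_rate()` reports it with an
explicit `washed_out` status instead of a pseudocount-backed large negative
number — any pseudocount choice would manufacture an arbitrarily negative
rate, so none is used anywhere by default.

## Guild classification

Taxa are binned into four guilds. Known syntrophs and known methanogens are
recognized from their lineage strings (case-insensitive substring match at
any rank, against the editable keyword file in `extdata/guild_rules.txt`);
taxonomy takes precedence over the rate sign so that, e.g., an acetoclastic
methanogen with a slightly negative rate is still reported as a methanogen.
Everything else splits on the sign of $\mu_x$: negative means the taxon is
decomposed faster than it grows (a WAS-associated population), positive
means a growing fermenter. Two boundary decisions were genuinely open and
are fixed as follows:

* $\mu_x = 0$ is binned as fermenter. The dichotomy is negative versus
  non-negative; an exact zero is a maintained population, and a separate
  bin for a measure-zero event would be noise.
* Syntroph keywords win over methanogen keywords (the lists are disjoint,
  so this matters only for pathological rule files), and archaeal lineages
  that match no methanogen keyword fall through to the sign rule with a
  warning, because no taxonomy rule is defined for non-methanogen archaea.

## Dominant-OTU screening

`filter_dominant()` supports two independently switchable criteria: keep an
OTU if its relative abundance exceeds 2% in any sample, or if its pooled
(equal-weight mean over samples) relative abundance exceeds 0.1%. Both are
on by default; either can be disabled with `NULL`, which reproduces the two
single-criterion screening conventions. Because the estimator needs
whole-community fractions, filtering never renormalizes the retained rows.
The pooled criterion is computed from the mean of per-sample fractions —
equivalent to pooling reads when sample depths are equal, and the only
well-defined reading once tables have been normalized per sample. In the
analysis drivers, screening is applied before replicate averaging; both
operations are linear in the fractions, so the order only affects which
OTUs sit near the threshold.

Replicate bottles are averaged on relative abundances, not raw counts, so
bottles with unequal sequencing depth contribute equally. 16S copy-number
correction is deliberately not applied; copy-number bias is a known
limitation of abundance-based rate estimates and should be handled upstream
if reference copy numbers are trusted.

## The synthetic reactor and what it does (not) emulate

`sim_config()`/`simulate_reactor()` generate communities with known ground
truth so that every stage of the pipeline is testable without sequencing
data. The state variable is per-taxon biomass in mg (standing in for cell
count, exactly as VSS stands in for it in the estimator). Semi-continuous
mode iterates the event cycle **grow → discard → feed**: over one interval
biomass multiplies by $e^{\mu \tau}$, the well-mixed discard scales every
taxon by $(V_c - v)/V_c$, and feeding adds $v\,C_f$ mg split by the feed
profile. One ordering convention had to be fixed; the discrete fixed point
used by the tests, $N^* = f / (1 - e^{\mu\tau}(V_c - v)/V_c)$ with
per-event feed mass $f$, is derived under the same ordering, so the oracle
and the simulator are order-consistent. Continuous mode integrates
$dN/dt = \mu N - N/\mathrm{SRT} + F$ by fixed-step Euler (default step
$\tau/50$) and has the closed-form fixed point $N^* = F/(D-\mu)$,
$D = 1/\mathrm{SRT}$ — the regime in which the estimator is algebraically
exact, which the tests verify to $10^{-9}$.

Sampling happens where a bench scientist samples: mixed liquor drawn at the
end of a growth phase, just before the next discard. This choice is not
cosmetic. At the pre-discard fixed point the estimator returns
$(1 - e^{-\mu\tau})/\tau$, i.e. a relative discretization error of order
$\mu\tau/2$, independent of the exchange fraction; sampling just after an
event would instead incur an error of order $\tau/\mathrm{SRT}$. Either
way the estimator is exact only in the continuous limit — the
semi-continuous bias is a documented, tested property, shrinking with the
exchange interval.

Measurement noise is deliberately minimal: sequencing is a single
multinomial draw at finite read depth (no overdispersion, no chimeras, no
copy-number variation), and VSS measurements get multiplicative lognormal
noise with mean 1 and a configurable CV (default 0.05, a typical
gravimetric repeatability). Real amplicon data are overdispersed and
compositionally biased, so a passing recovery test here demonstrates that
the estimator and its plumbing are correct under the model's own
assumptions — not that rates from real reactors carry 10% accuracy.

The stock community (`example_community()`) mirrors a WAS fermenter: ~20%
slow-growing syntrophs and methanogens plus a fermenter block, all with
positive true rates drawn between $0.2/\mathrm{SRT}$ and
$0.9/\mathrm{SRT}$ (growers must sit below the washout ceiling to have a
bounded steady state), and a 40% block of WAS-associated decayers with
rates between $-5/\mathrm{SRT}$ and $-2/\mathrm{SRT}$, matching the
observation that feed-associated taxa sit well below zero at the reactor's
rate scale. Decayers carry 70% of the immigrating feed biomass, as feed
sludge is dominated by upstream aerobic taxa.

## Performance metrics

Volatile fatty acid and alcohol concentrations are converted to COD
equivalents through theoretical oxygen demand computed from full-oxidation
stoichiometry ($\mathrm{C}_n\mathrm{H}_a\mathrm{O}_b + (n + a/4 - b/2)
\mathrm{O}_2 \to n\,\mathrm{CO}_2 + a/2\,\mathrm{H}_2\mathrm{O}$, nominal
atomic masses), not from hard-coded factors; acetate's factor is exactly
$64/60$. Bench sheets already in COD units pass through with
`as_cod = TRUE`. Solid removal is $(\mathrm{VSS_{in}} -
\mathrm{VSS_{out}})/\mathrm{VSS_{in}}$ — negative values (net solids
accumulation) are reported with a warning, not clipped. CH~4~ yield is
normalized by the volatile solids actually fed,
$\sum \text{events} \times v \times C_f$. No gas-law or headspace
conversion is included; inputs start at mmol.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `any_sample_threshold` | fraction | 0.02 | dominant-OTU screen, per-sample criterion |
| `total_threshold` | fraction | 0.001 | dominant-OTU screen, pooled criterion |
| `cv_threshold` (`assess_steady_state`) | — | 0.3 | flags OTUs still drifting over the final sampling days; CV above ~30% across 3–4 points is hard to reconcile with steady state |
| `read_depth` | reads | 1e5 | typical usable depth of a modern amplicon run |
| `vss_noise_cv` | fraction | 0.05 | gravimetric VSS repeatability |
| `euler_dt` | d | `exchange_interval/50` | keeps Euler error well below the semi-continuous discretization bias |

## Problem sizes used by the test-suite

Deterministic checks run on toy tables (≤ 60 OTUs). The stochastic
recovery study simulates 30-taxon communities at SRT 2.34375, 10 and
37.5 d with the exchange interval at SRT/50, read depth $10^5$, and 20
seeds per SRT — sizes at which the whole suite completes in seconds while
the multinomial noise is still the dominant error term. The recovery
criterion (median relative error ≤ 10% for rates of magnitude ≥ 0.01/d)
is evaluated over all seeds pooled.

## Known limitations

* The estimator assumes steady state; `assess_steady_state()` only flags
  violations, it does not correct for them. No dynamic (time-resolved)
  inference is provided.
* Relative abundances are copy-number biased; rates inherit that bias.
* `Cc` is a single measured number; its error moves all rates of a sample
  coherently by $(1/\mathrm{SRT} - \mu)\,\varepsilon$.
* The SRT arithmetic assumes perfect mixing. Settling or wall growth
  breaks the volume-fraction = solids-fraction identity and with it the
  $1/\mathrm{SRT}$ reduction. One legacy schedule label rounds the
  shortest sweep SRT to 2.5 d; the schedule arithmetic (150 mL, 32 mL
  every 0.5 d) gives 2.34375 d and computation always uses the schedule.
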