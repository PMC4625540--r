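# signcon

Sign consistency analysis of interaction graphs and perturbation profiles.

## The problem

Curated signaling and gene-regulatory networks (RegulonDB, KEGG, Reactome,
...) describe *who regulates whom and in which direction*, while
steady-state shift experiments (a perturbation, then a new steady state)
measure *which species went up or down*. `signcon` is for researchers who
want to confront the two: check whether a network topology can explain an
expression profile at all, predict the behavior of unmeasured species,
locate and repair inconsistencies, and quantify how much better than chance
the topology fits the data.

## The model

A network is an **interaction graph** (V, E, σ): a signed directed graph
where σ(j, i) = + (resp. −) means j tends to increase (decrease) i.
An experiment is an **experimental profile** (S, I, μ): measured species S,
perturbed/input species I, and discretized observations
μ : S → {−, ▽, 0, △, +}, obtained from real-valued log-ratios by four
thresholds t1 ≤ t2 < 0 < t3 ≤ t4 (▽/△, serialized `u-`/`u+`, are the
uncertain bands admitting two labels).

An admissible system behavior is a **total labeling** μᵗ : V → {+, 0, −}
subject to local and global constraints:

* **C1** — μᵗ respects the observations (uncertain ones admit two values);
* **C2** — a change at a non-input i is justified by some predecessor:
  μᵗ(i) = μᵗ(j)·σ(j, i) for some edge j → i;
* **C3** — a no-change at a non-input is justified: no nonzero incoming
  influence, or two opposing nonzero influences (strong propagation);
* **C4** — a change is *founded*: reachable from an input along a chain of
  sign-matching nonzero influences, which rules out self-justifying
  positive feedback loops.

Four consistency notions combine these: **WP** = {C1, C2}, **SP** =
{C1, C2, C3}, **FWP** = {C1, C2, C4}, **FSP** = {C1, C2, C3, C4}; an
instance is consistent when at least one total labeling satisfies every
constraint at every node. Over the set M of consistent labelings the
**prediction function** maps each node to `+`, `-`, `0` (same label in all
of M: strong), `w+` (never −), `w-` (never +), `chg` (never 0) (weak), or
`no`. When the instance is inconsistent, **minimal correction sets**
(MCoS) — minimum-cardinality sets of added signed artificial input
influences — restore consistency; predictions are then the statements that
hold under *every* minimal repair, and MCoS size divided by the number of
observations is the **inconsistency index**. **SCEN-FIT** instead reports
the minimum number of observations a propagation-consistent labeling must
contradict. For n unmeasured nodes with k strong, l weak and m absent
predictions the **information gain** is
(n·log3 − l·log2 − m·log3)/(n·log3).

## Worked example

A three-node fork: input C activates both A and B, but A is observed up
and B down — no single labeling of C explains both.

```r
library(signcon)
fx  <- toy_fixtures()
fit <- confront(fx$fork$graph, fx$fork$profile, notion = "FSP", scenfit = TRUE)
fit
#> Sign consistency fit (FSP): inconsistent; 1 correction(s) in 2 minimal set(s), index 0.5
#>   predictions: +:1 -:1 0:0 w+:0 w-:0 chg:1 no:0
fit$mcos
#> Minimal correction sets: size 1, 2 set(s), inconsistency index 0.5
#>   { A:+ }
#>   { B:- }
predict(fit)["C"]
#>     C
#> "chg"
```

One added influence suffices, either a positive one on A or a negative one
on B; under every minimal repair the input C must change (it drives A up
or B down), so its cautious prediction is `chg` even though network and
data disagree. The inconsistency index 0.5 is 1 correction per 2
observations.

On a consistent instance the notions sharpen predictions instead: the
bundled eight-node `feedback` fixture (a positive feedback loop E–F,
inputs A and D up, reporter H unchanged) admits 52 labelings under WP but
exactly one under FSP, turning weak predictions into strong ones:

```r
fb <- confront(fx$feedback$graph, fx$feedback$profile, notion = "FSP")
predict(fb)
#>   A   B   C   D   E   F   G   H
#> "+" "+" "+" "+" "+" "+" "0" "0"
```

Lower-level entry points: `is_consistent()`, `enumerate_labelings()`,
`predict_labels()`, `mcos()`, `scenfit()`, `crossval()`,
`null_distribution()`, `sample_instance()` (synthetic instances with a
known hidden labeling), and `read_network()` / `read_observations()` for
the tab-separated file formats. A command-line wrapper with subcommands
`check | predict | mcos | scenfit | crossval | null | synth` is installed
at `inst/cli/signcon`.

## Scope

The framework operates on single experiments. Multi-experiment topology
optimization, edge-deletion/sign-flip repairs, weighted or probabilistic
consistency, and per-gene adaptive discretization thresholds are out of
scope. See the methods vignette (`vignettes/sign-consistency.Rmd`) for the
model details, parameter choices, and known limitations.
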