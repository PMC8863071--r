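---
title: "Pyrophosphate stoichiometry of an atypical glycolysis: accounting, ledger, and cycle search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pyrophosphate stoichiometry of an atypical glycolysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiflux)
```

## The problem

*Clostridium thermocellum* runs an atypical glycolysis in which
pyrophosphate (PP~i~), not ATP, is the phosphoryl donor for
phosphofructokinase, and pyruvate formation goes through pyruvate
phosphate dikinase (Ppdk, consuming PP~i~) or the PP~i~-neutral malate
shunt. Because the organism lacks a soluble pyrophosphatase, something
must *supply* PP~i~ at glycolytic rates. This package implements the
stoichiometric reasoning needed to interrogate that question:

1. exact reaction algebra with folding of adenylate/guanylate currency
   into ATP equivalents;
2. reconstruction of the net glycolysis stoichiometry as a function of
   the Ppdk flux fraction $x \in [0,1]$, and the ATP yield under
   alternative PP~i~-supply scenarios;
3. a biosynthetic PP~i~ ledger over a macromolecular biomass
   composition, with break-even analysis and the anabolic coverage of
   the catabolic PP~i~ demand;
4. a minimal-total-flux (optStoic-style) search that enumerates
   candidate PP~i~-generating reaction cycles in a stoichiometric
   model, with an independent brute-force oracle and planted-mechanism
   toy networks for validation.

## Exact arithmetic

All stoichiometric coefficients are exact rationals (`rq` vectors:
integral numerators and denominators held in doubles, reduced after
every operation, aborting rather than overflowing past $2^{52}$).
Composition of lumped reactions therefore cancels without floating
residue, and identities such as the affine dependence of every
coefficient on $x$ hold exactly, not merely to tolerance. Doubles
appear only at the reporting layer.

Folding into energy equivalents treats ATP/GTP and ADP/GDP as
interchangeable pools (nucleoside-diphosphate kinase) and eliminates
AMP by applying adenylate kinase ($2\,\mathrm{ADP} \leftrightarrow
\mathrm{ATP} + \mathrm{AMP}$) at exactly the multiplier that zeroes the
AMP coefficient. The operation is idempotent and conserves the total
count of high-energy phosphoanhydride bonds (2 per NTP, 1 per NDP and
PP~i~), which the test suite asserts property-style over random maps.

## Glycolysis as a function of the Ppdk fraction

The shipped elementary-reaction fixture covers cellobiose uptake
(hydrolysis plus two GTP-hexokinase reactions by default, or
phosphorolysis), the PP~i~-dependent phosphofructokinase trunk, and the
PEP-to-pyruvate split: $4x$ Ppdk and $4(1-x)$ malate shunt per
cellobiose. Composing and folding gives, at $x = 1$:

```{r}
glycolysis_net(glycolysis_route(1))
```

i.e. cellobiose + 6 PP~i~ + 10 ADP~eq~ + 4 NAD^+^ → 4 pyruvate +
10 ATP~eq~ + 2 P~i~ + 4 NADH + 4 H^+^. The PP~i~ demand per glucose
equivalent is $1 + 2x$ and the ATP yield under a PP~i~-supply scenario
of cost $c$ (ATP~eq~ spent per PP~i~ supplied) is

$$Y_\mathrm{ATP}(x, c) = (3 + 2x) - (1 + 2x)\,c ,$$

which the package *derives* by composing the net stoichiometry with an
explicit supply conversion at the multiplier that zeroes PP~i~ — the
closed form above is only asserted in tests. The three named scenarios
are $c = 0$ (an unknown cost-free source; 5 ATP~eq~ per glucose
equivalent at $x=1$), $c = 1/2$ (membrane-bound H^+^-pumping
pyrophosphatase run synthetically: with 4 H^+^ per ATP at the ATPase
and 2 H^+^ per PP~i~ at the PPase, one ATP drives two PP~i~; yield
3.5), and $c = 1$ (glycogen cycling through ADP-glucose synthase;
yield 2).

Water is dropped from the reported net (the accounting tracks H^+^ but
not H~2~O); phosphorus and carbon balance are checked against declared
atom counts at every $x$ on a test grid.

Two smaller energy terms round out the bookkeeping. Cellodextrin
phosphorolysis spares $(n-1)/n$ ATP~eq~ per glucose equivalent for an
oligomer of length $n$ (0.5 at $n=2$, 0.83 at $n=6$). The specific
PP~i~ demand flux implied by growth parameters is
$(\mu / Y) / M \times 1000 \times s$ mmol g^-1^ h^-1^ for substrate
molar mass $M$ and $s$ mol PP~i~ per mol substrate; at
$\mu = 0.30\,\mathrm{h^{-1}}$, $Y = 0.18$ g/g and $s = 2$ (Pfk as the
only PP~i~ sink) this is ≈ 9.7.

## The biosynthetic ledger

Each macromolecule of the biomass composition carries an affine PP~i~
stoichiometry $a_i + b_i x$ (mmol PP~i~ per g biomass). The shipped
fixture is a transcription of published coefficients for a *B.
subtilis*-like composition; the package consumes it as data and does
not attempt to re-derive the coefficients from precursor demands
(their derivation needs precursor-level pathway data outside this
package's scope). Two transcription choices are documented in the fixture
file: component totals are authoritative where the published
biosynthesis/polymerization split disagrees with its own total by a
rounding digit, and the slope column keeps the component sum
($-7.266$) where the published per-column total prints $-7.264$.

```{r}
led <- ppi_ledger(ppi_fixtures()$biomass_composition)
led
```

Biosynthesis is a net PP~i~ producer only for
$x \le x^* = A/|B| \approx 0.155$; the package reports both the exact
fraction and the floored whole percent (15 %). Combining with the
catabolic context (biomass yield 0.15 g/g on cellobiose, 21 %
unaccounted carbon, 3.59 mmol/g anabolic demand):

```{r}
ctx <- ppi_fixtures()$growth_context
carbon_partition(ctx)
anabolic_coverage(ppi_fixtures()$biomass_composition, ctx, 0)
```

The same $x$ governs the anabolic ledger and the catabolic demand
($2 + 4x$ PP~i~ per cellobiose), so the coverage at $x = 0$ — the most
favourable case — is ≈ 4.8 %: biosynthesis cannot carry glycolysis.

### Robustness scheme

The composition is only borrowed from a related organism, so the
conclusion should not hinge on its exact numbers. `perturb_composition()`
multiplies each mass fraction by an independent uniform factor in
$[1-\delta, 1+\delta]$ (drawn on a 1/1000 grid so everything stays
exactly rational), lets the ash fraction absorb the change (damping all
fractions by a coarse rational factor in the rare draw where ash would
go negative), and scales each macromolecule's PP~i~ coefficients
proportionally to its mass-fraction change. Under $\delta = 0.10$ over
100 seeds the coverage at $x=0$ stays below 10 % and the break-even
below $x = 0.25$. The scheme perturbs *composition*, not the per-gram
coefficients themselves; correlated errors in the underlying pathway
stoichiometries are outside its scope.

### Glycogen accounting ambiguity

Charging one PP~i~ per glucosyl unit added to glycogen gives
1.54 mmol PP~i~ per g biomass at 25 % (w/w) glycogen; charging one
PP~i~ per chain of 10 units gives 0.15. Both modes are implemented and
reported side by side (`per_chain` is the default); the package flags
rather than resolves the discrepancy.

## The cycle search

`find_min_flux()` poses the optStoic-style minFlux problem: fluxes are
split into non-negative forward/reverse parts (reverse parts absent
for irreversible reactions), internal metabolites are balanced to
zero, the target conversion is imposed, and the total absolute flux is
minimized.

**Target semantics.** A qualifying PP~i~ supplier converts
ATP + P~i~ → ADP + PP~i~ *or better* — the membrane PPase yields two
PP~i~ per ATP and must be discoverable. A literal pin of all four
currency coefficients can never match such a mechanism, so the default
target pins PP~i~ production exactly, bounds the folded ATP~eq~ cost
by the target's cost, and lets ADP and P~i~ float. AMP, GTP and GDP
are balanced to zero inside the pathway: a steady-state cycle must
close its own nucleotide pools, which is exactly why adenylate kinase
and nucleoside-diphosphate kinase appear in the published cycles —
leaving them free would let the solver silently discard those
balancing reactions. NADH/NAD^+^ and NADPH/NADP^+^ may co-convert as
opposed pairs (the Ppdk–malate-shunt cycle transhydrogenates), and
H~2~O/H^+^/CO~2~ are unconstrained. `conversion_target(strict = TRUE)`
gives the literal fixed-conversion search.

**Enumeration.** After each solution $S$ the integer cut
$\sum_{j \in \mathrm{supp}(S)} y_j \le |\mathrm{supp}(S)| - 1$ is
added. No MILP solver is available to this package, so the cut is
applied *exactly* by disjunctive decomposition: "at least one support
member inactive" becomes an enumeration over which member of each
previous support is clamped to zero, taking the best LP over all
clamp combinations (ordered by objective, then lexicographic support
over model reaction order). For support sizes in the single digits and
a handful of solutions this is a few hundred tiny LPs. Note the
prescribed cut excludes supersets of a found support by construction,
which is what makes the enumerated supports an antichain.

**LP solver.** The LPs are solved by an in-package dense two-phase
primal simplex with Bland's anti-cycling rule (pivot tolerance
$10^{-9}$). These stoichiometric LPs are small but highly degenerate —
most right-hand sides are zero — which is the regime where naive
pivoting stalls; Bland's rule guarantees termination at the price of
speed, irrelevant at this scale. A presolve iteratively removes
reactions touching a balanced metabolite covered by only one reaction
(their flux is structurally zero), which eliminates dead-end decoy
chains before the LP sees them.

**Verification.** Solver output is snapped to rationals by
continued-fraction rounding with denominators at most 48 and
re-verified by exact substitution: balanced species vanish exactly,
pinned species hit their coefficients exactly, and the folded ATP~eq~
budget holds. If snapping fails the floating solution is returned with
`exact = FALSE` and a warning; on the toy scales exercised here it
never does. The big-M flux bound (default 100) is not added as LP rows
— the objective already bounds the optimum — but any active flux
within 1 % of it triggers a warning to raise the bound.

**Oracle.** `brute_force_oracle()` enumerates all reaction subsets up
to a size cap (guarded at $\binom{n}{k} \le 10^6$), tests each for
feasibility of the target, and returns the feasible subsets with no
feasible proper subset. It shares only the constraint semantics with
the search path, not the optimization machinery, and the test suite
requires the enumerated supports to equal the oracle's minimal
supports on the reference toys.

```{r}
toy <- build_reference_toy(n_decoys = 20, seed = 1)
sols <- enumerate_pathways(toy, conversion_target(),
                           search_config(max_solutions = 10))
for (s in sols) print(s)
```

The four planted mechanisms come out in flux order — membrane PPase
(total flux 1.5), glycogen cycle (3), acetate cycle (4, with adenylate
kinase), Ppdk–malate shunt (6, Ppdk in reverse, with AK and NDK) — and
decoys never enter a support. `filter_by_reactions()` reproduces the
successive-exclusion bookkeeping (dropping PPase- or Ags-containing
solutions leaves the acetate and Ppdk–malate-shunt cycles), and
`augmented_search()` implements the one-reaction-augmentation mode: a
pool of candidate reactions of which a solution may use at most
`max_added`, imposed exactly by enumerating admissible pool subsets.

## Toy networks

`build_reference_toy()` plants any subset of the four mechanisms with
their elementary reactions and proton compartments (`h_in`/`h_out`
are distinct species; the outside proton pool is reachable only
through the PPase and ATPase pumps, whose 2 H^+^/PP~i~ and 4 H^+^/ATP
stoichiometries are estimates, chosen to realise the 2 : 1 PP~i~ : ATP
variant). Every planted mechanism's folded net is asserted equal to
the qualifying conversion (or the 2 : 1 variant) at build time.
`add_decoys()` appends dead-end linear chains over fresh metabolites:
they are phosphorus-balanced, deterministic per seed, and provably
unable to carry steady-state flux, so planted-cycle recovery against
the oracle is a sharp test. Decoy chains do not emulate the dense
cycling of a genome-scale network; passing recovery tests here shows
correctness of the search machinery, not performance or solution
quality on genome-scale models, which additionally depend on
annotation quality and solver ordering.

## Problem sizes and costs

The test suite runs the full enumeration against the brute-force
oracle on the 14-reaction reference toy (subset cap 6, about $10^4$
feasibility LPs), planted-cycle recovery on ten 64-reaction
decoy-laden models, and 100-seed perturbation sweeps; the whole suite
completes in about a minute on one core. These sizes were chosen as
the smallest that exercise every code path with a meaningful safety
margin.

## Limitations

* Thermodynamics is out of scope: reversibility is a declared flag,
  not a ΔG calculation, and no thermodynamic filtering of cycles is
  attempted.
* Elemental balance checks cover phosphorus and carbon only.
* The biomass PP~i~ coefficients are consumed as a fixture; conditions
  or organisms with a different composition need a user-supplied
  table.
* The cycle finder is exact but enumerative in its cut handling;
  it is intended for models up to a few hundred reactions, not for
  genome-scale enumeration with hundreds of cuts.
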