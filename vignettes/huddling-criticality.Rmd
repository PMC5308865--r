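---
title: "Models and methods: thermoregulatory huddling and self-organised criticality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: thermoregulatory huddling and self-organised criticality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huddlesoc)
```

`huddlesoc` simulates thermoregulatory huddling in small endotherm groups
(rodent litters are the motivating system) at two levels of abstraction, and
analyses what happens when the thermal physiologies of the group are placed
under selection pressure. This vignette is the package's own account of the
models, the parameters that matter, the numerical choices, and the known
limitations.

## Shared thermal physiology

Both simulators rest on the same Newtonian heat balance. An individual
producing heat at rate $G$ (arbitrary heat units per time) and exposing a
fraction $A \in (0, 1]$ of its surface to an environment at ambient
temperature $T_A$ settles at the equilibrium body temperature

$$T_B = T_A + \frac{G}{A\,k_1},$$

where $k_1$ is the area-specific wet thermal conductance, a single lumped
rate constant standing in for fur, emittance, air movement and body
geometry. Huddling enters through $A$: the average exposed fraction
achievable in a group of $n$ bodies decays as $A = n^{-1/4}$, so groups are
warmer than singletons for any $G > 0$.

Selection acts on the fitness

$$F = -\bigl(\lvert \bar T_B - T_P \rvert + \alpha G\bigr),$$

where $\bar T_B$ is the individual's body temperature averaged over a whole
simulation, $T_P = 37\,^\circ$C is the preferred body temperature, and
$\alpha \ge 0$ prices thermogenesis. $F$ is never positive; its maximum is
reached only by perfect thermoregulation at zero metabolic cost. An isolated
individual with $G = 0$ at $T_A = 10\,^\circ$C scores exactly $-27$, which
serves as the cold-baseline reference in all evolution figures. The
absolute-value reading of the thermal term is forced by that baseline: a
signed reading would reward arbitrarily cold bodies.

Two conventions are worth stating because alternatives exist:

* The heat balance divides by $A k_1$ rather than multiplying. Only this
  reading makes the group-size dependence come out as $n^{+1/4}$ in the
  merge probability below, and only this reading makes the agent model's
  fully exposed fixed point coincide with the equation above.
* $\alpha$ defaults to 6.06 in the Monte Carlo evolution experiments and 3.0
  in the agent-based ones — in each case near the smallest value that stops
  metabolic rates collapsing immediately to zero, so that the costs of
  thermogenesis and of poor thermoregulation actually compete. Both are
  config-exposed.

## The Monte Carlo (aggregon) model

The first model is deliberately aspatial. Its state is a partition of $N$
individuals into disjoint groups ("aggregons"); the dynamics are Gibbs
sampling over merge/split decisions. Each iteration picks an individual $a$
uniformly (so a group is picked with probability proportional to its size
$n_i/N$) and a second individual $b$ uniformly among those outside $a$'s
group. The two groups merge with probability

$$p_1 = \Bigl(1 + \exp\bigl[(G_a n_a^{1/4} + G_b n_b^{1/4})/k_1
      - 2(T_P - T_A)\bigr]\Bigr)^{-1},$$

the logistic acceptance for the "temperature parameter"
$T = 2T_P - T_{B,a} - T_{B,b}$; otherwise $a$ is displaced into a singleton.
The colder the sampled pair relative to preference, the likelier the merge.
Two boundary rules close the chain: from a single all-in group a uniformly
chosen individual always splits off, and from $N$ singletons the sampled
pair always merges. Merged groups take a fresh label; labels are pure
bookkeeping. Displacing an individual that is already a singleton is a
no-op relabelling — the sampler does not exclude singletons as $a$.

Run metrics: the huddling order parameter $h = 1 - \tfrac1N\sum_i A_i$
(bounded by $1 - N^{-1/4} \approx 0.46$ for $N = 12$), the mean group
count, and *pup flow*, operationalised as the standard deviation of $h$
over iterations — the analog of heat capacity in a particle system. We use
the population (divide-by-$t$) standard deviation; at $t \ge 1000$ the
distinction from the sample convention is far below any reported precision,
but the choice is fixed. Sweeping the ambient temperature from 0 to
50 °C in 2 °C steps (26 values; metabolic rates redrawn
$G \sim U[0,5]$ per simulation, $k_1 = 0.3$, $t = 5000$ iterations from a
single-group start) reproduces a second-order phase transition: $h$ falls
from its cold plateau to nearly zero as $T_A$ approaches $T_P$, mean body
temperature plateaus near 37 °C across the intermediate range, and pup
flow peaks at the transition.

By default no burn-in is discarded — the figures of record average from the
single-group start — but every metric accepts a `burn_in`, and a sensitivity
test in the suite confirms the conclusions are unchanged when the first 10%
is dropped.

## The agent-based model

The second model makes the physical interactions explicit: $N$ circular
agents (radius 1, the model's length unit) move in a circular arena,
carrying thermal sensors around their circumference. Each timestep:

1. **Sense.** Each of 72 sensor points registers the body temperature of
   the nearest other agent whose body strictly contains the point, or else
   $T_A$. Left/right averages $T_L, T_R$ are mapped through
   $s = (1 + \exp(-\sigma (T_P - T_B) T_{side}))^{-1}$, so a cold agent
   rates warm directions above 0.5 and an overheated agent rates them below
   — the sign reversal is what makes turning homeostatic
   ("homeothermotaxis"). The exposed fraction $A$ is the share of sensors
   reading ambient, and $T_C$ the mean over contact sensors.
2. **Turn and move.** $\dot\theta = \arctan(v_2 (s_L - s_R)/(s_L + s_R))$,
   then straight motion at speed $v_1$; explicit Euler with step `dt`.
3. **Resolve.** Five sweeps of symmetric pairwise separation along centre
   lines push overlapping pairs back to a centre distance of
   $2r - \texttt{overlap\_tol}$, followed by radial projection to the wall.
   Headings are never touched by collisions; only thermotaxis steers.
4. **Exchange heat.** $\dot T_B = G - k_1 A (T_B - T_A)
   - k_2 (1 - A)(T_B - T_C)$: thermogenesis, Newtonian loss through the
   exposed surface, and contact exchange at the agent's own conductance
   $k_2$. The contact term is dropped when $A = 1$ (its prefactor vanishes
   and $T_C$ is undefined). With $A = 1$ the fixed point is exactly the
   shared equilibrium $T_A + G/k_1$, which ties the two models together;
   the test suite verifies the Euler solution tracks the closed form within
   1% at the default `dt` and converges at first order. Heat exchange is
   *not* symmetric between partners and total heat is not conserved — each
   agent relaxes toward its own contact average — so tests assert only
   boundedness.

Groups are the connected components of the contact graph (centre distance
below $2r(1 + 0.05)$); huddling is $1 - \langle A \rangle$ and pup flow the
time- and agent-averaged $|\Delta A|/\Delta t$.

### Parameter choices

The numeric settings of this model are design decisions, exposed in
`abm_config()`:

* `arena_radius = 6.5` for $N = 12$ (packing fraction ≈ 0.28): dense enough
  for frequent contact, sparse enough that dispersal above $T_P$ is visible.
* `sigma = 0.01` per degree²: keeps the logistic argument of order one for
  temperature products of order 100, avoiding all-or-nothing turning.
* `v1 = 1`, `v2 = 5`, `dt = 0.05`: an agent crosses the arena in roughly
  260 steps, so a 1000-step run allows several huddle reconfigurations.
* `overlap_tol = 0.5` (half a radius). This one deserves its paragraph: if
  collisions restored centre distances to exactly $2r$, a sensor point on
  one circle could never lie strictly inside the other, and touching agents
  would be thermally invisible to each other. Pups are soft-bodied; letting
  resolution tolerate a compression of half a radius gives a touching pair
  a contact arc of roughly 25°, which is what the sensors register. The
  containment and excluded-volume invariants are asserted with this
  tolerance in the suite.
* Initial body temperatures start at $T_P$ (agents are born thermoregulated;
  the relaxation time constant $1/k_1$ is about 20 steps, so the choice
  washes out quickly but avoids biasing early fitness against high-$G$
  physiologies). Initial positions are uniform non-overlapping placements,
  headings uniform.
* Sensors exactly on the heading axis are assigned alternately to the left
  and right pools (index order), fixing a tie that would otherwise bias
  turning.
* For temperature sweeps, physiologies are redrawn per simulation with
  $G \sim U[0,5]$, $k_2 \sim U[0,5]$ and $k_1 = 1$, matching the ranges the
  evolutionary experiments explore.

### What the agent model does and does not reproduce

With these settings the sweep reproduces: the huddling plateau at low
$T_A$ decaying to ≈ 0 above $T_P$ (in long runs the dispersal is complete),
the complementary group-count profile, and mean body temperatures held
*above* the isolated-agent baseline $T_A + G/k_1$ in the cold — the
signature of cooperative insulation.

One feature deserves a caveat: pup flow in this implementation is largest
at the *coldest* temperatures, with only a secondary bump at the
transition itself. Two mechanisms drive the cold-end flow. First, deeply
enclosed agents with small $k_2$ overheat (their only outlet is slow
contact exchange), leave the huddle, cool, and rejoin — continuous
convection, which is the biological pup-flow phenomenon itself, but
strongest when the environment is coldest. Second, the sensor product
$\sigma (T_P - T_B) T_{side}$ gives the largest left/right contrast when
ambient readings are near 0 °C, so turning — and with it
reconfiguration — is most vigorous there. We examined the sensor gain over
two orders of magnitude and the speed, arena and resolution settings
around their defaults without finding a regime in which the flow maximum
moves to the critical temperature while the other phenomena survive, and
kept the defaults rather than distort the model to rescue one diagnostic.
Under the shipped sweep protocol the flow maximum still falls inside the
80%–20% transition bracket — but only because the cold plateau of the
huddling curve is itself inflated by the slow condensation transient,
which stretches the bracket down to a few degrees; the reader should not
take that as a demonstration of a fluctuation peak at criticality in the
agent model. The Monte Carlo model shows the textbook version cleanly.

## Weakest-substitution evolution

Evolution couples either simulator to a selection rule in the spirit of
extremal (Bak–Sneppen-style) dynamics. Each generation runs a *fresh*
simulation (single group for the Monte Carlo model, random placement for
the agent model) for `per_gen_iterations` steps, computes every
individual's $F$ from its full-run $\bar T_B$ (no burn-in: the average is
over all iterations), and replaces the single least-fit individual —
lowest index on ties, making runs reproducible — with a new physiology
drawn uniformly: $G \sim U[0,5]$, and for the agent model also
$k_2 \sim U[0,5]$ with $k_1$ fixed at 1. Exactly one physiology changes
per generation, so any long-range structure in the dynamics must be
mediated by the huddling interactions; the suite asserts the Hamming-1
property along whole traces. Fresh per-generation initial states keep
generations exchangeable; nothing in the procedure is a genetic algorithm
(no recombination or mutation kernels), which is deliberate.

The trace records, per generation, the least-fit index and its metabolic
rate, and `g_min` — the largest metabolic rate among the *remainder* of the
group, the expected second-weakest. (Where the two readings of
"second-weakest" disagree the trace keeps full per-individual data, so the
alternative is computable.) Long stasis near zero punctuated by excursions
of `g_min` — avalanches, segmented as maximal runs above a threshold
defaulting to a tenth of the metabolic range, 0.5 — is the qualitative
signature; the quantitative one is the histogram of `g_min`.

## Criticality analysis

`gmin_histogram()` bins `g_min` into 30 equal-width bins over $(0, 5]$
(the sampling range; linear bins because the support is bounded, with a
log-binning alternative available — under log binning the fit should be
run on densities, `density = TRUE`, to keep the exponent's meaning).
`fit_power_law()` is an ordinary least-squares regression of
$\log H$ on $\log G_{\min}$ over non-empty bins — the model
$\log H = m \log G_{\min} + c$, i.e. a power law $H \propto G_{\min}^m$.
Empty bins are excluded (their log is undefined); fewer than three
non-empty bins refuses the fit outright, and `exponent_sweep()` flags a
temperature `fit_ok = FALSE` on refusal or when $r^2 < 0.8$ — the stand-in
for "could not be adequately fit", which is the behaviour expected at and
above $T_P$ where huddling no longer couples fitnesses. Sensitivity tests
assert the recovered exponent moves by less than 0.2 between 20 and 50
bins on synthetic power-law samples, and that exponents
$\mu \in [-3.5, -1.5]$ are recovered within $\pm 0.2$ from $10^4$ draws.
No maximum-likelihood tail estimation is offered: the histogram-plus-OLS
recipe *is* the method under study.

### Problem sizes

The full-scale evolution experiments run 10,000 generations of
1,000-iteration simulations. The Monte Carlo engine completes that in
about a minute, and the test suite runs it at full scale. For the
agent-based model a full-scale run is an overnight-class computation when
repeated across temperatures, so the shipped acceptance checks use
scaled-down runs — at least 2,000 generations per temperature in the test
suite and 4,000 in `scripts/acceptance.R` — at $T_A \in \{0, 10, 20\}$ °C.
Scaling down matters for the exponent: early generations still carry the
uniform founding population, whose erosion pads the histogram tail, and
the exponent steepens as the stationary stasis/avalanche statistics take
over. Scaled-down exponent estimates are therefore expected to be
shallower than full-scale ones, and the agent model's avalanches are rare
enough that the estimate carries substantial seed-to-seed variance.

## Known limitations

* The thermal model folds every conductance determinant into $k_1$; there
  is no distinction between shivering and non-shivering thermogenesis, no
  fur, no wind.
* The Monte Carlo model has no space: contact structure beyond group sizes,
  and any geometry of who can reach whom, is out of scope by construction.
* The agent model's sensor formula works in absolute degrees Celsius, so
  0 °C ambient is a "neutral" reading — a quirk inherited from the
  sensor map's product form, with the pup-flow consequence described above.
* Synthetic sweeps redraw physiologies per temperature; nothing is carried
  across sweep points, so sweep curves are independent samples, not a
  single litter tracked across environments.
* The evolutionary procedure is extremal selection with one substitution
  per generation, chosen to isolate huddling-mediated couplings. It is not
  a population-genetic model, and no claim about real inheritance follows
  from it.
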