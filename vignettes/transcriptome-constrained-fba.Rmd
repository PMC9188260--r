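---
title: "Transcriptome-constrained flux balance analysis with loop removal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-constrained flux balance analysis with loop removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

Flux balance analysis (FBA) predicts steady-state reaction fluxes $v$ of a
genome-scale metabolic model from stoichiometry alone: $S v = 0$ with
per-reaction bounds $lb \le v \le ub$. Stoichiometry rarely pins down the
flux state of interest, so additional data must be brought in. This package
embeds **continuous** gene-expression values into the FBA constraints,
avoiding the discretization into "on/off" reactions that threshold-based
integration methods require. The motivating application is inferring which
carbon source a microbe is consuming from its transcription profile alone —
useful exactly where isotope-tracer experiments are impractical, such as
intracellular pathogens.

## The linear expression-to-flux map

The model assumes that, over the conditions of a study, the flux through a
reaction varies linearly with the mean expression $\bar g_{ri,c}$ of its
coding genes. For each *fitted* reaction $ri$ (core set CR plus associated
set AR) the expression value is mapped affinely onto the reaction's feasible
flux range obtained from flux variability analysis (FVA):

$$
v^{fit}_{ri,c} \;=\; V^{min}_{ri} + \bigl(\bar g_{ri,c} - g^{min}_{ri}\bigr)
\frac{V^{max}_{ri} - V^{min}_{ri}}{g^{max}_{ri} - g^{min}_{ri}},
$$

where $g^{min/max}$ are the extremes of $\bar g_{ri,c}$ across all
conditions and $V^{min/max}$ the FVA flux range. The condition with the
lowest expression is thus assigned the smallest feasible flux and the
highest the largest. FVA is run once on the globally-bounded network, not
per condition, because the map uses a single per-reaction range;
condition-specific biomass floors are deliberately excluded from it.

Fluxes are then fitted per condition by the weighted L1 program

$$
\min \; \sum_{ri,c} w_{ri}\,\lvert v_{ri,c} - v^{fit}_{ri,c}\rvert
\;+\; \alpha \sum_{ro,c} \lvert v_{ro,c}\rvert
\quad \text{s.t. } S v_c = 0,\; lb \le v_c \le ub,\;
v_{biomass,c} \ge B_c ,
$$

with $w_{ri} = 1/V^{weight}_{ri}$ for core reactions and
$w_{ri} = 1/(V^{weight}_{ri} + 100)$ for associated ones, where
$V^{weight}_{ri} = \max(\lvert V^{max}_{ri}\rvert, \lvert
V^{min}_{ri}\rvert)$. The reciprocal weighting makes reactions with small
and large flux ranges count comparably; the $+100$ down-weights the
associated set. Fitted reactions whose FVA range is exactly $[0,0]$ cannot
carry flux and are discarded from the fit. The second term penalizes the
remaining ("RO") reactions' absolute fluxes; it is one of three loop
defences (below). Conditions share no variables, so each condition is an
independent LP; absolute values are linearized with split nonnegative
auxiliaries.

The **total model mapping discrepancy**
$d = \sum_{ri,c} \lvert v_{ri,c} - v^{fit}_{ri,c}\rvert$ (unweighted) is the
running quality score of the whole procedure.

### Choices the formulation leaves open

* **Degenerate expression range** ($g^{max} = g^{min}$, e.g. a single
  condition): the map is undefined; we assign the flux-range midpoint
  $(V^{min}+V^{max})/2$, the unbiased choice, and log the reactions
  concerned.
* **GPR logic**: AND/OR structure of gene–protein–reaction rules is not
  evaluated; the reaction expression is the plain arithmetic mean over all
  mapped genes. Genes without data are dropped with a warning; a reaction
  left without any measured gene is excluded from the fit.
* **Sign of the penalty term**: the penalty is taken on absolute fluxes
  $\sum \lvert v_{ro,c}\rvert$. A signed sum would be meaningless for
  reversible reactions (it could be driven to $-\infty$), so the absolute
  version is the only coherent reading.
* **Penalty scope**: the penalized set is everything *outside* CR ∪ AR,
  including exchanges and biomass; biomass floors protect required growth.

## Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.01 | – | strength of the L1 flux penalty; trades mapping discrepancy against summed non-fitted flux |
| exchange cap | user (e.g. 0.688) | mmol/gDW/h | total uptake budget over non-designated exchange reactions |
| TIL threshold | 0.01 | mmol/gDW/h | flux magnitude below which a loop is tolerated |
| IFFPR stability | 1e-4 over 10 steps | – | relative-spread window that ends bound reduction |
| feasibility tol | 1e-6 | – | post-solve validation of $\lvert Sv\rvert$ and bounds |

The default `alpha = 0.01` sits at the knee where the summed penalized flux
drops sharply while the discrepancy rises only moderately; the acceptance
script recomputes this trade-off (`penalty_sum_reduction_pct_alpha_0.01`).
The uptake cap mirrors the common experimental situation of a minimal
medium: designated carbon sources are opened simultaneously (so no prior
knowledge of the true source leaks in), everything else shares a small
budget.

## Three defences against thermodynamically infeasible loops

A thermodynamically infeasible loop (TIL) is an internal cycle carrying
nonzero net flux at steady state — stoichiometrically legal, but in
violation of the loop law. Expression fitting actively *recruits* loops,
because inflated FVA ranges map expression onto large targets that only
circulation can reach. Three mechanisms are combined:

**1. The L1 penalty** ($\alpha$ term) discourages gratuitous flux through
non-fitted reactions.

**2. Iterative feasible flux space reduction** (`run_iffpr()`): reactions
are ranked by their representative bound
$\max(\lvert V^{max}\rvert,\lvert V^{min}\rvert)$ and processed from the
top. Each step halves the range — both endpoints when they straddle zero,
otherwise only the endpoint away from zero, clamping rather than inverting
— re-maps $v^{fit}$ with the shrunken range and re-solves. A halving is kept
only if $d$ strictly decreases; otherwise the previous bounds are restored
(the reading of the procedure consistent with keeping the best $d$) and the
next reaction is taken. The accepted-$d$ sequence is therefore
non-increasing by construction. Termination is by list exhaustion or a
stability window (relative spread of $d$ below $10^{-4}$ across 10
consecutive outer steps — the procedure plateaus well before the list ends
because late-ranked reactions already have narrow ranges). IFFPR is a
training-phase tool: the reduced bounds are reused at prediction time.
Whether the acceptance test should use the weighted or the unweighted
deviation is not fixed by the procedure's description; we use the
unweighted $d$, the same score the stability window watches.

**3. Iterative loop removal** (`run_redtil()`): given a solution, the
*oriented support* is the set of internal reactions with
$\lvert v \rvert \ge$ threshold, their stoichiometric columns flipped to
point along the flux (circulations are direction-specific, so detection
must be too). A MILP finds a minimum-total-flux circulation within the
support: minimize $\sum_r \lambda_r$ subject to $S\lambda = 0$,
$\lambda_r \ge inFC_r$, $\sum_r inFC_r \ge 2$ (a loop needs at least two
reactions), $inFC$ binary, $0 \le \lambda \le 1000$ (any positive cap gives
the same membership, only scaled). If a loop is found it is excluded: each
member gets a binary indicator forced to 1 when its flux reaches the
threshold in the loop's direction (big-M rows with
$M = \max(\lvert lb\rvert,\lvert ub\rvert)+1$), and the cardinality cut
$\sum_{loop} inFC \le k-1$ makes at least one member drop below the
threshold. The fit is re-solved (now a MILP) and the support rebuilt from
the fresh solution before the next detection round. Cuts are
condition-specific. The procedure terminates because every cut excludes a
support pattern that was previously feasible; a repeated cut is a hard
error, and the objective can only degrade weakly as cuts accumulate.

Because the threshold tolerates sub-threshold circulation, the final
objective can sit *below* the strict loopless optimum by at most
$B \cdot \text{threshold}$, where $B$ is the net weight slope along the cut
loop — a quantifiable, documented slack (reported as
`redtil_vs_loopless_max_objective_gap`), not an approximation error.

### Validation oracles

Two independent certificates confirm looplessness of a solution
(`loopless_check()`): infeasibility of the detection MILP, and exhaustive
directed-cycle enumeration on the support graph followed by a stoichiometric
balance check of each cycle (positive nullspace vector). The two must agree;
disagreement is a hard error. The enumeration oracle is exact for networks
whose internal reactions convert one metabolite into one metabolite — true
for every generated fixture; multi-substrate reactions would require
hypergraph enumeration, which is out of scope.

A classical single-MILP loopless formulation (`full_loopless_reference()`)
— per-internal-reaction direction binaries, bounded pseudo-energy variables
of opposite sign, and null-space orthogonality — serves as the reference
implementation the iterative procedure is compared against (objective
agreement on fixtures, fitted-flux correlation across random networks). It
is guarded to ≤ 200 reactions; it exists for validation, not production.

## Carbon-source calling

For each designated transporter (an exchange reaction), the per-condition
uptake magnitude $u = \max(0, -v)$ is standardized across conditions with
the sample (n−1) SD. Standardizing per transporter lets weak but specific
transporters compete with strong ones. The top z-score per condition is the
primary carbon source call, the runner-up the secondary; exact ties break
lexicographically and carry a flag. Scoring uptake magnitude rather than
signed flux is deliberate: under the COBRA sign convention the strongest
uptake is the most negative flux, and $\lvert\min(v,0)\rvert$ removes the
sign trap; signed-flux scoring remains available via `use = "flux"` for
comparison. Transporters with zero SD across conditions carry no signal and
are excluded with a warning rather than silently ranked.

## What the synthetic generator emulates — and what it does not

`make_multicarbon_scenario()` mirrors a multi-condition carbon-source study:
parallel substrate routes, one designated source per condition running at
its full uptake bound, optional background routes with small varying
uptake, and expression generated per gene as $g = a + b\,v_{planted} +
\varepsilon$, $\varepsilon \sim N(0, \sigma)$ on the log2 scale with
per-gene $a, b > 0$ (two genes per transporter, so reaction-level averaging
is exercised). Defaults are 8 conditions and 8 transporters, matching a
typical eight-carbon-source design; $\sigma = 0.1$ log2 units is a
realistic microarray replicate noise level, and $\sigma = 0$ gives the
exact affine regime in which the mapping provably inverts to the planted
fluxes. Planted states are constructed so every fitted reaction attains its
feasible minimum and maximum across conditions — the regime in which the
linear map is exact. Real data differ in ways the generator deliberately
omits: flux not under transcriptional control, GPR boolean structure,
shared pathway intermediates, measurement bias. Passing the recovery tests
therefore validates the machinery under the model's own assumptions; it is
not evidence about any particular organism.

`make_loop_network()` plants a reversible internal cycle, detached (a pure
circulation whose FVA range spans the full bounds — the motivating
pathology) or attached to a linear chain. `make_random_til_scenario()`
draws small chain-plus-cycles networks with targets that deliberately tempt
the optimizer into circulation, used for the 100-network certification
suite and the 20-seed reference comparison.

## Numerical choices

* All LPs/MILPs are solved by HiGHS (via a bridged scientific-python
  process speaking JSON over a localhost socket; a one-shot subprocess is
  the automatic fallback). HiGHS is deterministic single-threaded, so
  identical inputs give bit-identical outputs; the pipeline's flux tables
  reproduce byte-for-byte under a fixed configuration and seed.
* Feasibility and optimality tolerances are $10^{-6}$; every solution is
  passed through a validator asserting $\lVert Sv\rVert_\infty \le 10^{-6}$
  and bound satisfaction before being returned.
* Degenerate alternate optima are accepted: tests assert constraint
  satisfaction and objective values, never vertex identity.
* Ranking ties in IFFPR break lexicographically on reaction id; loop-cut
  membership is read off the circulation variables ($\lambda > 10^{-6}$),
  which is well-defined because $\lambda$ must form a balanced cycle.
* Problem sizes throughout the test-suite are deliberately small (chains of
  3–4 metabolites, cycles of length 2–4, 8-condition scenarios, 100 random
  networks of ≤ 30 reactions); they exercise every code path while keeping
  the full suite around one to two minutes.

## Limitations

* The linear map needs at least two conditions with distinct expression to
  be informative; single-condition studies fall back to midpoint targets.
* The associated-reaction screen (`select_associated()`) implements only
  the differential-expression criterion; network-adjacency and
  key-metabolite filters are the caller's responsibility, as they encode
  biological judgement.
* The cycle-enumeration oracle assumes unimolecular internal conversions
  (see above).
* Runtime scales with the number of fitted reactions times IFFPR halvings
  times loop-removal rounds; genome-scale models are expected to take hours,
  as iterative loop removal trades per-iteration cost for fewer binaries.
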