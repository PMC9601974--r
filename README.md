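# ainlearn

Active information measures of learning and knowledge acquisition.

## The problem

Philosophers define knowledge as *justified true belief*: it is not enough
to end up believing a true proposition — the belief must concentrate on
the truth for the right reason.  `ainlearn` makes that distinction
computable for a rational agent whose beliefs are Bayes posteriors.  The
package is aimed at statisticians and quantitative epistemologists who
want to analyse when an inference procedure merely *learns* (raises belief
in a true proposition) versus when it *acquires knowledge* (concentrates
belief around the true state of the world) — with applications to
hypothesis testing, replication of studies, posterior consistency, and
causal inference under unmeasured confounding.

## The model

Worlds `x` in a space `X` are parameters of a statistical model; exactly
one, `x0`, is true.  A proposition `S` holds on its truth set
`A = {x : f(x) = 1}`.  A maximally ignorant person holds the
maximum-entropy uniform measure `P0`; the agent holds a posterior `P`
obtained through Bayes' rule, constrained by a *discernment* partition `G`
(within each cell of `G` the agent's beliefs must keep the baseline's
shape).  The central statistic is the **active information**

    I+(A) = log P(A) / P0(A),

bounded above by the functional information `-log P0(A)`.

* **Learning:** `I+(A) > 0` when `x0` is in `A`, `I+(A) < 0` when it is
  not.  Equivalently a hypothesis test that rejects "S is true" when
  `I+(A) <= I`, decision-identical to the Bayesian posterior-odds rule at
  `I = -log[P0(A)(1 + r)]`.
* **Knowledge:** learning, plus `P(B_eps(x0)) >= P0(B_eps(x0))` for every
  closed ball around the true world (strictly for some radius), with
  `P(B_eps(x0)) > 0`.  Full knowledge is the point mass at `x0`.
* **Processes:** strong (monotone `I+` chains), weak (final step), and
  asymptotic (tail diagnostics of `Pk(A)/P0(A)`), with posterior
  contraction at rate `1/sqrt(k)` and limiting variance `2/J(x0)` for a
  single posterior draw.

## Worked example

A teacher watches a student score 7/10 on a test.  Three worlds: the
student guesses (`x1`, scores Bin(10, 0.5)), knows the material (`x2`,
Bin(10, 0.8)), or gets help (`x3`, Bin(10, 0.8)).  The proposition "the
student scores well" holds on `A = {x2, x3}`; the true world is `x2`.

```r
library(ainlearn)
tr <- student_experiment(7)
active_info(tr$posteriors[[1]], uniform_prior(tr$space), tr$region)
#> I+ = 0.150018 nats  [P(A) = 0.77457, P0(A) = 0.666667]
```

Belief in `A` rose from 2/3 to 0.775, so the teacher learned `S`
(`I+ = 0.150 > 0`), and since the posterior also concentrates on balls
around the true world, the static knowledge verdict is positive:

```r
assess_knowledge(tr$posteriors[[1]], uniform_prior(tr$space), region = tr$region)
#> knowledge verdict (static, conditional): YES
#>   I_plus = 0.150018
#>   ...
#>   full_knowledge: FALSE
```

But no score alone can tell skill from help: `P(x2)` never exceeds 0.5
over all scores 0–10 (run `sweep_experiment(list(experiment = "student"),
"d1", 0:10)`).  A second step — the invigilator reports "no help"
(`z2 = 0`) — resolves it.  For the proposition "the student knows the
material" (`A = {x2}`) the two-step process is monotone all the way and
acquires knowledge in the strong sense:

```r
tr2 <- student_experiment(7, z2 = 0, proposition = "knows")
assess_strong(tr2)
#> knowledge verdict (strong, conditional): YES
#>   strong_learning: TRUE
#>   ball_chain_monotone: TRUE
#>   ...
```

Other experiments follow the same pattern: `coin_experiment()` (symmetric
coin, Beta posteriors), `dating_experiment()` (biased radiometric dating:
learning without knowledge), `camp_experiment()` (weather forecast plus a
possibly wrong prophet), `replication_experiment()` (replication
probability under partial information transfer), and
`confounding_experiment()` (exact enumeration of conditional and
counterfactual outcome predictions).  `run_experiment()` and
`sweep_experiment()` drive any of them from a JSON config and write
trajectory CSVs, verdict JSON and a re-runnable manifest;
`inst/cli/ainlearn.R` is a thin command-line wrapper.

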