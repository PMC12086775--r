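# cmcpmod

Confirmatory dose–response testing for parallel-group trials that compare
several doses of a treatment against a common control. The package embeds
model-based multiple contrast tests (the MCP part of MCP-Mod) in a closed
testing procedure, so a single trial yields, at full level α,

* a test for an overall dose–response signal (proof of concept), **and**
* multiplicity-adjusted p-values for every individual dose-versus-control
  comparison, with strong familywise error rate (FWER) control.

It is aimed at statisticians designing or analyzing Phase III dose–control
trials where a definite dose–response relationship has not been established
before, and at methodologists studying the operating characteristics of
many-to-one testing procedures.

## The method

For arms $i = 0$ (control), $1, \dots, k$ with means $\mu_i$ and normal
errors, the elementary one-sided hypotheses are
$H_i : \mu_i \le \mu_0$. A candidate set of standardized dose–response
shapes $f_m^0(d)$ (Emax, sigmoid Emax, …) with design-stage guesses of
their shape parameters defines, for each model $m$, the single contrast
test

$$T_m = \frac{\sum_i c_{mi}\,\bar Y_i}{S\sqrt{\sum_i c_{mi}^2/n_i}},$$

where $S^2$ is the pooled variance with $N - k - 1$ degrees of freedom and
the coefficients $c_{mi} \propto n_i\,(\mu^0_{mi} - \bar\mu^0_m)$ maximize
the test's noncentrality for the assumed shape (zero-sum, scaled to unit
norm). The maximum $\max_m T_m$ is referenced against the central
multivariate t distribution of the contrast statistics.

The closed procedure tests every nonempty intersection
$H_I = \cap_{i \in I} H_i$ with such a maxT test, re-optimizing the
contrasts on the control arm plus the doses in $I$, and rejects $H_i$ iff
every intersection containing $i$ is rejected. Because re-used "optimal"
contrasts can carry negative dose coefficients — which let a strongly
harmful dose masquerade as evidence *for* other doses — the default solver
maximizes the noncentrality under the constraint that every dose-vs-control
weight is nonnegative (exact support enumeration). With these constrained
contrasts the closure controls the FWER strongly without any monotonicity
assumption.

Also included:

* the competitor procedures used as benchmarks: single-step and step-down
  Dunnett, Hochberg, Bonferroni, fixed-sequence, unadjusted t-tests;
* a trial simulator and operating-characteristics study
  (`run_study()`: RAO, per-dose power, AVE/k, with common random numbers
  across procedures);
* a graphical extension for a primary and a secondary endpoint
  (`two_endpoint_graph()`, `closed_graphical_mcpmod()`): a weighted
  hypothesis graph assigns local levels to each of the $2^{2k}-1$
  intersections; endpoint groups are tested by constrained contrast tests
  with a Bonferroni split.

The tests are one-sided for a response **increase**; negate responses for
endpoints where a decrease is improvement (e.g. pain scores).

## Worked example

Four arms (doses 0, 0.1, 0.4, 1; 100 patients each, residual SD 1), the
default five-shape candidate set, and a simulated trial with a true Emax
(ED50 = 0.2) profile of maximum effect 0.3:

```r
library(cmcpmod)
design <- dose_design(c(0, 0.1, 0.4, 1), 100)
models <- default_candidate_set()
scen   <- scenario(design, candidate_model("emax", ed50 = 0.2),
                   effect = 0.3, seed = 42)
trial  <- simulate_trial(scen, 1)
closed_mcpmod(trial, design, models, constrained = TRUE, alpha = 0.025)
```

```
Closed model-based multiple contrast test (constrained contrasts, one-sided alpha = 0.025)

Adjusted p-values per intersection hypothesis and model:
 hypothesis  Emax1  Emax2  Emax3 sigEmax1 sigEmax2 p_value reject
   H{1,2,3} 0.0004 0.0002 0.0001   0.0002   0.0001  0.0001   TRUE
     H{1,2} 0.0122 0.0195 0.0195   0.0195   0.0195  0.0122   TRUE
     H{1,3} 0.0002 0.0001 0.0001   0.0001   0.0001  0.0001   TRUE
     H{2,3} 0.0004 0.0002 0.0001   0.0002   0.0001  0.0001   TRUE
       H{1} 0.0266 0.0266 0.0266   0.0266   0.0266  0.0266  FALSE
       H{2} 0.0153 0.0153 0.0153   0.0153   0.0153  0.0153   TRUE
       H{3} 0.0001 0.0001 0.0001   0.0001   0.0001  0.0001   TRUE

Dose-response signal (global intersection) p-value: 1e-04 

Elementary dose-versus-control hypotheses:
 hypothesis dose adjusted_p reject
         H1  0.1     0.0266  FALSE
         H2  0.4     0.0153   TRUE
         H3  1.0     0.0001   TRUE
```

Reading the output: each row is one intersection hypothesis; the five model
columns are maxT-adjusted p-values of the per-model contrast tests and the
row minimum is the intersection's p-value. A dose–response signal is
established (global p = 0.0001). Doses 0.4 and 1 are individually superior
to control at one-sided FWER 0.025; the closed-test adjusted p-value of the
lowest dose (0.0266, here its own two-sample t-test) just misses, so $H_1$
is retained. No extra multiplicity price was paid for the per-dose claims
beyond the proof-of-concept test.

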