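# Published reference contrasts for the four-arm case design (doses 0, 0.1,
# 0.4, 1; 100 patients per arm) and the five default candidate shapes,
# frozen at the printed 3-decimal precision. Keys are the active-dose index
# sets of the intersection hypotheses; singletons are covered separately by
# the analytic collapse property.

reference_contrasts_unconstrained <- list(
  "123" = list(Emax1 = c(-0.831, 0.053, 0.347, 0.431),
               Emax2 = c(-0.716, -0.195, 0.325, 0.586),
               Emax3 = c(-0.596, -0.319, 0.209, 0.706),
               sigEmax1 = c(-0.528, -0.46, 0.391, 0.597),
               sigEmax2 = c(-0.452, -0.407, 0.068, 0.791)),
  "12" = list(Emax1 = c(-0.793, 0.226, 0.566, 0),
              Emax2 = c(-0.707, 0, 0.707, 0),
              Emax3 = c(-0.623, -0.145, 0.768, 0),
              sigEmax1 = c(-0.455, -0.36, 0.815, 0),
              sigEmax2 = c(-0.463, -0.351, 0.814, 0)),
  "13" = list(Emax1 = c(-0.781, 0.184, 0, 0.597),
              Emax2 = c(-0.656, -0.094, 0, 0.749),
              Emax3 = c(-0.542, -0.257, 0, 0.8),
              sigEmax1 = c(-0.446, -0.369, 0, 0.815),
              sigEmax2 = c(-0.431, -0.385, 0, 0.816)),
  "23" = list(Emax1 = c(-0.815, 0, 0.365, 0.45),
              Emax2 = c(-0.802, 0, 0.267, 0.535),
              Emax3 = c(-0.756, 0, 0.11, 0.645),
              sigEmax1 = c(-0.804, 0, 0.28, 0.524),
              sigEmax2 = c(-0.666, 0, -0.077, 0.742))
)

reference_contrasts_constrained <- list(
  "123" = list(Emax1 = c(-0.831, 0.053, 0.347, 0.431),
               Emax2 = c(-0.802, 0, 0.267, 0.535),
               Emax3 = c(-0.756, 0, 0.11, 0.645),
               sigEmax1 = c(-0.804, 0, 0.28, 0.524),
               sigEmax2 = c(-0.707, 0, 0, 0.707)),
  "12" = list(Emax1 = c(-0.793, 0.226, 0.566, 0),
              Emax2 = c(-0.707, 0, 0.707, 0),
              Emax3 = c(-0.707, 0, 0.707, 0),
              sigEmax1 = c(-0.707, 0, 0.707, 0),
              sigEmax2 = c(-0.707, 0, 0.707, 0)),
  "13" = list(Emax1 = c(-0.781, 0.184, 0, 0.597),
              Emax2 = c(-0.707, 0, 0, 0.707),
              Emax3 = c(-0.707, 0, 0, 0.707),
              sigEmax1 = c(-0.707, 0, 0, 0.707),
              sigEmax2 = c(-0.707, 0, 0, 0.707)),
  "23" = list(Emax1 = c(-0.815, 0, 0.365, 0.45),
              Emax2 = c(-0.802, 0, 0.267, 0.535),
              Emax3 = c(-0.756, 0, 0.11, 0.645),
              sigEmax1 = c(-0.804, 0, 0.28, 0.524),
              sigEmax2 = c(-0.707, 0, 0, 0.707))
)

# compare every cell of a reference table against the requested solver;
# printed values are 3-decimal roundings, so agreement means the recomputed
# coefficient rounds to within half a unit in the last printed place
expect_reference_table <- function(expected, constrained) {
  d <- case_design()
  models <- default_candidate_set()
  fun <- if (constrained) constrained_contrast else optimal_contrast
  for (row in names(expected)) {
    I <- as.integer(strsplit(row, "")[[1]])
    for (lab in names(expected[[row]])) {
      cc <- fun(std_response(models[[lab]], d$doses), d, I)
      testthat::expect_true(
        max(abs(round(cc, 3) - expected[[row]][[lab]])) <= 5e-4 + 1e-12,
        info = sprintf("%s / I={%s} / %s",
                       if (constrained) "constrained" else "optimal",
                       row, lab))
    }
  }
}
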