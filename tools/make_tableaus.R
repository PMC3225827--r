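#!/usr/bin/env Rscript
# Build task: regenerate the shipped variance-bounded method coefficients
# (inst/extdata/tableaus/rk-tauleap-s{S}-eps{E}.yaml) from the optimizer.
# Run from the package root after installing the package.
library(tauleapRK)
dir.create(file.path("inst", "extdata", "tableaus"),
           recursive = TRUE, showWarnings = FALSE)
for (s in c(3L, 5L)) for (eps in c(0.1, 0.25, 0.5)) {
  res <- optimize_polynomial(s, eps)
  path <- file.path("inst", "extdata", "tableaus",
                    sprintf("rk-tauleap-s%d-eps%s.yaml", s, format(eps)))
  write_optimization_result(res, path)
  cat(sprintf("%s: l = %.5f\n", path, res$l))
}
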