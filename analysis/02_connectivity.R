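#!/usr/bin/env Rscript
# Stage 2: ROI time series -> Pearson correlation matrices.
#
# Band-pass 0.01-0.08 Hz at TR = 2 s, then the full correlation matrix with
# zeroed diagonal, one file per subject. The synthetic series carry no
# nuisance signals, so the regression step is a no-op here; with real data,
# pass motion/WM/CSF/global covariates to regress_nuisance() between the two
# steps.

library(smallworldnet)

in_dir <- "results/data"
out_dir <- "results/connectivity"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

for (grp in c("right", "left")) {
  set <- read_timeseries_set(in_dir, grp)
  for (s in seq_along(set$subjects)) {
    filtered <- bandpass_filter(set$subjects[[s]], set$tr_seconds, 0.01, 0.08)
    r <- correlation_matrix(filtered)
    write_matrix(r, file.path(out_dir, sprintf("%s_subject%02d_corr.tsv", grp, s)),
                 header = TRUE)
  }
  message(sprintf("group '%s': %d correlation matrices written", grp,
                  length(set$subjects)))
}
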