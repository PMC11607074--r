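#!/usr/bin/env Rscript
# Filter the simulated traces, convert to FRET efficiency, idealize each
# trace with the Gaussian-emission HMM, and write the decoded state
# sequences.  Requires 01_simulate.R to have been run.

library(rotafret)

for (preset in c("sin37", "tn3")) {
  traces <- read_traces(file.path("results", paste0(preset, "_traces.csv")))
  flt <- filter_traces(traces)
  message(sprintf("%s: kept %d / %d traces (%s)", preset, length(flt$kept),
                  length(traces),
                  paste(names(table(flt$rejected$reason)),
                        table(flt$rejected$reason), collapse = ", ")))
  rows <- list()
  for (id in names(flt$kept)) {
    f <- compute_fret(flt$kept[[id]])
    m <- prune_broad_states(fit_hmm(f, K = 4, seed = 7))
    vp <- merge_idealized_states(viterbi_path(m, f))
    rows[[id]] <- data.frame(trace_id = id, frame = vp$frame,
                             state = vp$state, level = vp$level)
  }
  ideal <- do.call(rbind, rows)
  write.csv(ideal, file.path("results", paste0(preset, "_idealized.csv")),
            row.names = FALSE)
  message(sprintf("%s: idealized %d traces, %d frames", preset,
                  length(rows), nrow(ideal)))
}
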