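# Small in-code fixtures shared across test files.

## Gaussian (count-free) expression set of rhythmic genes: direct control
## of phase/amplitude/noise without the NB sampling layer.
make_rhythm_es <- function(n_genes, phases, amp = 1, noise_sd = 0.1,
                           treatments = c("A", "B"), replicates = 2,
                           times = seq(24, 70, by = 2), period = 24,
                           phases2 = NULL, seed = 1) {
  diffpat:::with_seed(seed, {
    design <- expand.grid(time = times,
                          replicate = paste0("rep", seq_len(replicates)),
                          treatment = treatments,
                          stringsAsFactors = FALSE)
    design$sample <- sprintf("%s_t%02d_%s", design$treatment,
                             as.integer(design$time), design$replicate)
    design <- sample_design(design[c("sample", "treatment", "time",
                                     "replicate")])
    phases2 <- if (is.null(phases2)) phases else phases2
    mat <- matrix(0, n_genes, nrow(design))
    for (s in seq_len(nrow(design))) {
      ph <- if (design$treatment[s] == treatments[1]) phases else phases2
      mat[, s] <- amp * cos(2 * pi * (design$time[s] - ph) / period) +
        stats::rnorm(n_genes, 0, noise_sd)
    }
    rownames(mat) <- sprintf("g%04d", seq_len(n_genes))
    colnames(mat) <- design$sample
    expression_set(mat, design)
  })
}

## tiny deterministic count table for ingest tests
make_toy_counts <- function() {
  counts <- matrix(c(10, 20, 35, 50, 100,
                     12, 18, 40, 46, 110,
                     60, 40, 20, 250, 30),
                   nrow = 5, ncol = 3,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  count_table(counts, stats::setNames(c(1000, 2000, 500, 1500, 3000),
                                      paste0("g", 1:5)))
}
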