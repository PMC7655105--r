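test_that("TOM matches the hand formula and its invariants", {
  ## 4-gene adjacency, hand-computed topological overlap
  a <- matrix(c(0, .8, .2, .1,
                .8, 0, .4, .3,
                .2, .4, 0, .6,
                .1, .3, .6, 0), 4, 4)
  tom <- tom_similarity(a)
  k <- rowSums(a)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) { expect_equal(tom[i, j], 1); next }
    expect_equal(tom[i, j], (sum(a[i, -c(i, j)] * a[-c(i, j), j]) + a[i, j]) /
                   (min(k[i], k[j]) + 1 - a[i, j]))
  }
  expect_true(isSymmetric(tom))
  expect_true(all(tom >= 0 & tom <= 1))
  expect_error(tom_similarity(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("soft threshold selection follows the scale-free criterion", {
  set.seed(11)
  ## independent noise: no power reaches the fit -> default 12 + warning
  noise <- matrix(rnorm(100 * 30), 100, 30,
                  dimnames = list(sprintf("g%03d", 1:100),
                                  sprintf("s%02d", 1:30)))
  des <- sample_design(colnames(noise), treatment = "T",
                       time = seq_len(30) * 2, replicate = "r1")
  es_noise <- expression_set(noise, des)
  expect_warning(res <- pick_soft_threshold(es_noise, c(2, 4, 6)),
                 "default 12")
  expect_identical(res$power, 12L)
  expect_error(pick_soft_threshold(es_noise, integer(0)), "nonempty")
  ## strongly structured data with heterogeneous connectivity (gene-wise
  ## signal-to-noise spread gives the heavy-tailed degree distribution the
  ## criterion looks for): criterion satisfied by the chosen power
  es_mod <- diffpat:::with_seed(2, {
    n <- 300
    ph <- runif(n, 0, 24); ns <- runif(n, 0.1, 2)
    times <- seq(24, 70, 2)
    dd <- expand.grid(time = times, replicate = c("rep1", "rep2"),
                      treatment = c("A", "B"), stringsAsFactors = FALSE)
    dd$sample <- sprintf("%s_t%02d_%s", dd$treatment, as.integer(dd$time),
                         dd$replicate)
    dd <- sample_design(dd[c("sample", "treatment", "time", "replicate")])
    mat <- sapply(seq_len(nrow(dd)), function(s)
      cos(2 * pi * (dd$time[s] - ph) / 24) + rnorm(n, 0, ns))
    dimnames(mat) <- list(sprintf("g%04d", seq_len(n)), dd$sample)
    expression_set(mat, dd)
  })
  res2 <- pick_soft_threshold(es_mod, c(2, 4, 6, 8, 10))
  row <- res2$fit[res2$fit$power == res2$power, ]
  expect_gte(row$r2, 0.8)
  expect_lt(row$slope, 0)
  ## forced single candidate returned when it satisfies the criterion
  res3 <- pick_soft_threshold(es_mod, res2$power)
  expect_identical(res3$power, as.integer(res2$power))
})

test_that("planted phase modules are recovered up to label permutation", {
  phases <- rep(c(0, 8, 16), each = 50)
  es <- make_rhythm_es(150, phases = phases, noise_sd = 0.1, seed = 3)
  ms <- detect_modules(es, network_params(soft_power = 6,
                                          min_module_size = 20))
  expect_equal(nrow(ms$eigengenes), 3)
  assigned <- ms$assignment[ms$assignment > 0]
  expect_gte(length(assigned) / 150, 0.95)
  ## co-assignment agreement with the planted partition
  tab <- table(phases[match(names(assigned), rownames(es$matrix))], assigned)
  purity <- sum(apply(tab, 2, max)) / sum(tab)
  expect_gte(purity, 0.95)
  ## gene-order invariance: same partition after row permutation
  perm <- diffpat:::with_seed(9, sample(150))
  es_p <- expression_set(es$matrix[perm, ], es$design)
  ms_p <- detect_modules(es_p, network_params(soft_power = 6,
                                              min_module_size = 20))
  common <- intersect(names(ms$assignment), names(ms_p$assignment))
  cross <- table(ms$assignment[common], ms_p$assignment[common])
  expect_equal(sum(apply(cross, 1, function(r) sum(r > 0) == 1)),
               nrow(cross))
})

test_that("modules with near-identical eigengenes are merged", {
  ## two planted clusters sharing one phase, one distinct (8 h away, so
  ## the unsigned network keeps them apart)
  phases <- rep(c(2, 2, 10), each = 40)
  es <- make_rhythm_es(120, phases = phases, noise_sd = 0.05, seed = 5)
  ms <- detect_modules(es, network_params(soft_power = 6,
                                          min_module_size = 20,
                                          merge_corr = 0.9))
  ## the duplicated phase collapses into one module
  expect_equal(nrow(ms$eigengenes), 2)
})

test_that("eigengenes are standardized, sign-oriented first components", {
  es <- make_rhythm_es(40, phases = rep(c(0, 12), each = 20),
                       noise_sd = 0, seed = 6)
  assign <- setNames(rep(1:2, each = 20), rownames(es$matrix))
  eg <- module_eigengenes(es, assign)
  expect_equal(rowMeans(eg), c(M01 = 0, M02 = 0), tolerance = 1e-8)
  expect_equal(apply(eg, 1, var), c(M01 = 1, M02 = 1), tolerance = 1e-8)
  ## identical member genes: eigengene equals the standardized profile
  prof <- drop(scale(es$matrix[1, ]))
  expect_equal(abs(cor(eg["M01", ], prof)), 1, tolerance = 1e-10)
  expect_true(all(cor(t(es$matrix[1:20, ]), eg["M01", ]) > 0.999))
  ## 2-gene antiphase module: both members equally correlated in magnitude
  m2 <- es$matrix[c(1, 21), ]
  es2 <- expression_set(m2, es$design)
  eg2 <- module_eigengenes(es2, setNames(c(1, 1), rownames(m2)))
  cors <- cor(t(m2), eg2[1, ])
  expect_equal(abs(cors[1]), abs(cors[2]), tolerance = 1e-8)
  ## sign rule: mean member correlation non-negative for every module
  es3 <- make_rhythm_es(60, phases = rep(c(0, 9, 17), each = 20),
                        noise_sd = 0.3, seed = 7)
  a3 <- setNames(rep(1:3, each = 20), rownames(es3$matrix))
  eg3 <- module_eigengenes(es3, a3)
  for (m in 1:3)
    expect_gte(mean(cor(t(es3$matrix[a3 == m, ]), eg3[m, ])), 0)
  expect_error(module_eigengenes(es3, setNames(1, rownames(es3$matrix)[1])),
               "fewer than 2")
})

test_that("first component explains at least as much variance as random directions", {
  es <- make_rhythm_es(30, phases = runif(30, 0, 6), noise_sd = 0.5, seed = 8)
  a <- setNames(rep(1, 30), rownames(es$matrix))
  eg <- module_eigengenes(es, a)
  xs <- t(scale(t(es$matrix)))
  ve <- function(v) sum((xs %*% v / sqrt(sum(v^2)))^2)
  v_eig <- ve(drop(eg[1, ]))
  rand <- diffpat:::with_seed(10, replicate(1000, ve(rnorm(ncol(xs)))))
  expect_gte(v_eig, max(rand))
})

test_that("kME is the per-course Pearson correlation with the eigengene", {
  es <- make_rhythm_es(50, phases = runif(50, 0, 24), noise_sd = 0.3, seed = 12)
  ms <- detect_modules(es, network_params(soft_power = 4,
                                          min_module_size = 10))
  kme <- compute_kme(es, ms$eigengenes)
  expect_true(all(abs(kme$values) <= 1 + 1e-12, na.rm = TRUE))
  d <- es$design
  course <- paste(d$treatment, d$replicate, sep = ".")
  cols <- d$sample[course == "A.rep1"]
  direct <- cor(es$matrix["g0007", cols], ms$eigengenes[1, cols])
  expect_equal(unname(kme$values["g0007", 1, "A.rep1"]), direct,
               tolerance = 1e-12)
  ## gene equal (or opposite) to an eigengene gives kME +/- 1
  m <- rbind(ms$eigengenes[1, ], -ms$eigengenes[1, ])
  rownames(m) <- c("pos", "neg")
  kme2 <- compute_kme(expression_set(m, es$design), ms$eigengenes)
  expect_equal(unname(kme2$values["pos", 1, ]), rep(1, 4), tolerance = 1e-10)
  expect_equal(unname(kme2$values["neg", 1, ]), rep(-1, 4), tolerance = 1e-10)
  ## constant course flagged as missing
  m3 <- matrix(1, 1, ncol(es$matrix),
               dimnames = list("const", colnames(es$matrix)))
  expect_warning(expect_warning(expect_warning(expect_warning(
    kme3 <- compute_kme(expression_set(m3, es$design), ms$eigengenes),
    "constant"), "constant"), "constant"), "constant")
  expect_true(all(is.na(kme3$values)))
})

test_that("module overlap stats match a contingency-table oracle", {
  es <- make_rhythm_es(90, phases = rep(c(0, 8, 16), each = 30),
                       noise_sd = 0.15, seed = 13)
  ms <- detect_modules(es, network_params(soft_power = 6,
                                          min_module_size = 15))
  ## self-overlap: diagonal has module sizes and correlation 1
  self <- module_overlap_stats(ms, ms)
  diag_rows <- self[self$moduleA == self$moduleB, ]
  sizes <- table(ms$assignment[ms$assignment > 0])
  expect_equal(diag_rows$n_common,
               as.integer(sizes[as.character(diag_rows$moduleA)]))
  expect_equal(diag_rows$eigengene_corr, rep(1, nrow(diag_rows)),
               tolerance = 1e-10)
  ## against a second module set from noisier data: cross-tab oracle
  es2 <- make_rhythm_es(90, phases = rep(c(0, 8, 16), each = 30),
                        noise_sd = 0.4, seed = 14)
  rownames(es2$matrix) <- rownames(es$matrix)
  ms2 <- detect_modules(es2, network_params(soft_power = 6,
                                            min_module_size = 15))
  ov <- module_overlap_stats(ms, ms2)
  gA <- ms$assignment[ms$assignment > 0]
  gB <- ms2$assignment[ms2$assignment > 0]
  common <- intersect(names(gA), names(gB))
  tab <- table(gA[common], gB[common])
  for (r in seq_len(nrow(ov)))
    expect_identical(ov$n_common[r],
                     as.integer(tab[as.character(ov$moduleA[r]),
                                    as.character(ov$moduleB[r])]))
  expect_equal(sum(ov$n_common), length(common))
})

test_that("hypergeometric enrichment tails and signed score behave", {
  u <- paste0("g", 1:10)
  ## degenerate: module = flagged = universe
  deg <- hypergeometric_enrichment(u, u, u)
  expect_equal(deg$p_over, 1)
  expect_equal(deg$p_under, 1)
  ## N=10, K=4, n=5, k=4 against exhaustive enumeration
  res <- hypergeometric_enrichment(u[1:5], u[c(1:4)], u)
  enum <- hyper_enum_oracle(10, 4, 5, res$k)
  expect_equal(res$p_over, unname(enum["p_over"]), tolerance = 1e-12)
  expect_equal(res$p_under, unname(enum["p_under"]), tolerance = 1e-12)
  expect_gte(res$p_over + res$p_under, 1)
  ## at the expected count the signed score is as mild as possible
  u20 <- paste0("g", 1:20)
  base <- hypergeometric_enrichment(u20[1:10], u20[c(1:5, 16:20)], u20)
  expect_equal(base$k, 5)  # n*K/N = 10*10/20
  for (k in c(2, 8)) {
    other <- hypergeometric_enrichment(u20[1:10],
                                       u20[c(seq_len(k), 10 + seq_len(10 - k))],
                                       u20)
    expect_gte(abs(other$signed_log10), abs(base$signed_log10))
  }
  expect_error(hypergeometric_enrichment("a", "a", character(0)),
               "empty universe")
  expect_error(hypergeometric_enrichment("x", u[1], u), "subsets")
})
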