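test_that("forest-based inference recovers a planted edge and is seeded", {
  set.seed(60)
  n <- 40
  tfs <- sprintf("TF%02d", 1:11)
  mat <- matrix(rnorm(11 * n), 11, n, dimnames = list(tfs, NULL))
  target <- mat["TF01", ] + rnorm(n, 0, 0.1)  # copy of TF01 plus noise
  mat <- rbind(mat, tgt = target)
  colnames(mat) <- sprintf("s%02d", seq_len(n))
  des <- sample_design(colnames(mat), treatment = "T",
                       time = seq_len(n), replicate = "r")
  es <- expression_set(mat, des)
  net <- infer_grn(es, tfs, "tgt", n_trees = 300, seed = 7)
  w <- net$edges$weight
  expect_equal(net$edges$tf[which.max(w)], "TF01")
  expect_equal(sum(w), 1, tolerance = 1e-9)
  net2 <- infer_grn(es, tfs, "tgt", n_trees = 300, seed = 7)
  expect_identical(net$edges, net2$edges)
  expect_error(infer_grn(expression_set(mat[, 1:5], des[1:5, ]), tfs, "tgt"),
               ">= 8 samples")
})

test_that("permuted-network threshold separates signal and goes infinite on noise", {
  ## structureless data: the threshold is unattainable in most seeds
  inf_count <- 0
  for (s in 1:6) {
    g <- diffpat:::with_seed(s, {
      n <- 30
      tfs <- sprintf("TF%02d", 1:6)
      tgs <- sprintf("G%02d", 1:15)
      mat <- matrix(rnorm(21 * n), 21, n,
                    dimnames = list(c(tfs, tgs), sprintf("s%02d", 1:n)))
      des <- sample_design(colnames(mat), treatment = "T",
                           time = seq_len(n), replicate = "r")
      expression_set(mat, des)
    })
    net <- infer_grn(g, sprintf("TF%02d", 1:6), sprintf("G%02d", 1:15),
                     n_trees = 100, seed = s)
    th <- suppressWarnings(
      permuted_edge_threshold(g, sprintf("TF%02d", 1:6),
                              sprintf("G%02d", 1:15), net,
                              n_trees = 100, seed = s + 100))
    if (is.infinite(th$threshold)) inf_count <- inf_count + 1
    ## FDR estimate is monotone nonincreasing in the weight
    expect_true(all(diff(th$fdr_table$fdr_adj) <= 1e-12))
  }
  expect_gte(inf_count, 5)
  ## planted structure: finite threshold with real edges above it
  sim <- simulate_grn(n_tf = 8, n_targets = 40, edges_per_target = 1,
                      noise_sd = 0.2, seed = 61)
  net <- infer_grn(sim$es_a, sim$tf_a, sim$targets_a, n_trees = 200,
                   seed = 62)
  th <- permuted_edge_threshold(sim$es_a, sim$tf_a, sim$targets_a, net,
                                n_trees = 200, seed = 63)
  expect_true(is.finite(th$threshold))
  tn <- threshold_network(net, th$threshold)
  expect_gt(sum(lengths(tn$target_sets)), 0)
})

test_that("target overlap p-values: mapping, extremes and enumeration oracle", {
  map <- data.frame(br = paste0("br", 1:20), at = paste0("at", 1:20))
  univ <- paste0("at", 1:20)
  ## perfect mapping attains the minimal achievable p for the sizes
  res <- target_overlap_pvalue(paste0("br", 1:5), paste0("at", 1:5),
                               map, univ)
  expect_equal(res$k, 5)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  ## N=20, K=5, n=4, k=3 against exhaustive enumeration
  res2 <- target_overlap_pvalue(paste0("br", c(1, 2, 3, 10)),
                                paste0("at", 1:5), map, univ)
  enum <- hyper_enum_oracle(20, 5, 4, 3)
  expect_equal(res2$p, unname(enum["p_over"]), tolerance = 1e-12)
  ## ortholog collisions collapse before counting
  map2 <- data.frame(br = c("x1", "x2", "x3"), at = c("at1", "at1", "at2"))
  res3 <- target_overlap_pvalue(c("x1", "x2", "x3"), "at1", map2, univ)
  expect_equal(res3$n, 2)  # x1/x2 collapse to at1
  ## unmapped set flagged
  res4 <- target_overlap_pvalue("zz", "at1", map, univ)
  expect_true(res4$flagged)
  expect_true(is.na(res4$p))
  expect_error(target_overlap_pvalue("x", "at1",
                                     data.frame(br = c("x", "x"),
                                                at = c("at1", "at2")), univ),
               "at most one")
})

test_that("divergence permutation test: degeneracy, symmetry, calibration", {
  univ <- paste0("g", 1:200)
  setA <- paste0("g", 1:30)
  ## identical overlap p for both copies: delta 0, p = 1
  d0 <- divergence_permutation_test(0.02, 0.02, c(25, 25), setA, univ,
                                    n_perm = 500, seed = 3)
  expect_equal(d0$delta, 0)
  expect_equal(d0$p, 1)
  expect_true(is.na(d0$br1))
  ## symmetric under copy swap
  d1 <- divergence_permutation_test(1e-6, 0.4, c(20, 28), setA, univ,
                                    n_perm = 500, seed = 3)
  d2 <- divergence_permutation_test(0.4, 1e-6, c(28, 20), setA, univ,
                                    n_perm = 500, seed = 3)
  expect_equal(d1$p, d2$p)
  expect_equal(d1$delta, d2$delta)
  expect_equal(d1$br1, "copyA")
  expect_equal(d2$br1, "copyB")
  expect_warning(divergence_permutation_test(0.5, 0.5, c(5, 5), setA, univ,
                                             n_perm = 50, seed = 1),
                 "coarse")
})

test_that("CNS projection unions associated elements with set semantics", {
  net <- structure(list(edges = data.frame(tf = c("T1", "T1", "T2"),
                                           target = c("g1", "g2", "g3"),
                                           weight = c(0.5, 0.4, 0.9)),
                        tf_ids = c("T1", "T2"),
                        target_ids = c("g1", "g2", "g3"),
                        threshold = NA_real_, space = "gene",
                        target_sets = NULL),
                   class = "target_network")
  expect_error(project_targets_to_cns(net, data.frame()), "thresholded")
  tn <- threshold_network(net, 0.3)
  cns_map <- data.frame(cns = c("c1", "c2", "c2", "c9"),
                        gene = c("g1", "g1", "g2", "g9"))
  proj <- project_targets_to_cns(tn, cns_map)
  ## g1 has c1 and c2; g2 shares c2 which appears once (set semantics)
  expect_equal(proj$target_sets$T1, c("c1", "c2"))
  expect_equal(proj$space, "CNS")
  ## T2's target g3 has no CNS: empty set, flagged
  expect_length(proj$target_sets$T2, 0)
  expect_equal(attr(proj, "empty_tfs"), "T2")
})

test_that("CNS hit filtering applies score, coverage and multiplicity rules", {
  hits <- data.frame(
    qaccver = c("c1", "c1", "c2", "c2", "c2", "c2", "c3", "c3", "c4",
                "c5", "c5", "c5", "c5", "c5", "c6", "c6", "c7", "c8",
                "c8", "c9"),
    saccver = paste0("s", 1:20),
    bitscore = c(50, 28.2, 40, 45, 50, 41, 28.2, 28.2, 35,
                 60, 60, 60, 60, 60, 45, 27, 59.9, 30, 30, 28.3),
    qcovs = c(80, 90, 70, 60, 59, 65, 95, 99, 60,
              61, 62, 63, 64, 65, 100, 100, 59.99, 60, 61, 60))
  out <- filter_cns_hits(hits, species_cap = 3)
  oracle <- cns_filter_brute(hits, cap = 3)
  expect_equal(out, oracle)
  ## boundary behavior spelled out
  expect_false("s5" %in% out$saccver)   # qcovs 59 dropped
  expect_true("s4" %in% out$saccver)    # qcovs 60 kept
  expect_false("s2" %in% out$saccver)   # bitscore == 28.2 dropped
  expect_true("s20" %in% out$saccver)   # bitscore 28.3 kept
  expect_false(any(out$qaccver == "c5"))  # 5 surviving hits > cap 3
  ## cap 1 (diploid reference) also removes two-hit queries
  out1 <- filter_cns_hits(hits, species_cap = 1)
  expect_equal(out1, cns_filter_brute(hits, cap = 1))
  expect_false(any(out1$qaccver == "c2"))
  ## idempotent
  expect_equal(filter_cns_hits(out, species_cap = 3), out)
  expect_error(filter_cns_hits(hits[, -3], 3), "bitscore")
})

test_that("nearest same-strand gene with signed distances and ties", {
  genes <- data.frame(chrom = c("1", "1", "1", "2"),
                      start = c(100, 300, 600, 50),
                      end = c(200, 400, 700, 80),
                      name = c("gA", "gB", "gC", "gD"),
                      score = 0, strand = c("+", "+", "-", "+"))
  cns <- data.frame(chrom = "1",
                    start = c(150, 245, 500, 90),
                    end = c(160, 255, 510, 95),
                    name = c("inside", "between", "nearC", "before"),
                    score = 0, strand = c("+", "+", "-", "+"))
  res <- nearest_gene(cns, genes)
  ## intragenic: distance 0
  expect_equal(res$distance[res$cns == "inside"], 0)
  expect_equal(res$gene[res$cns == "inside"], "gA")
  ## equidistant between gA end (200) and gB start (300): both reported
  btw <- res[res$cns == "between", ]
  expect_setequal(btw$gene, c("gA", "gB"))
  expect_equal(sort(btw$distance), c(-46, 46))
  ## same-strand constraint: nearC only sees the minus-strand gC
  expect_equal(res$gene[res$cns == "nearC"], "gC")
  expect_lt(res$distance[res$cns == "nearC"], 0)
  ## before gA on plus strand: negative distance
  expect_equal(res$gene[res$cns == "before"], "gA")
  expect_lt(res$distance[res$cns == "before"], 0)
  expect_error(nearest_gene(data.frame(chrom = 1, start = 5, end = 5,
                                       name = "x", strand = "+"),
                            genes), "malformed")
  ## random intervals against the brute-force all-pairs oracle
  set.seed(70)
  rg <- data.frame(chrom = sample(c("1", "2"), 10, TRUE),
                   start = sample(1000, 10))
  rg$end <- rg$start + sample(50:200, 10, TRUE)
  rg$name <- paste0("G", 1:10); rg$score <- 0
  rg$strand <- sample(c("+", "-"), 10, TRUE)
  rc <- data.frame(chrom = sample(c("1", "2"), 30, TRUE),
                   start = sample(1200, 30))
  rc$end <- rc$start + sample(10:40, 30, TRUE)
  rc$name <- paste0("C", 1:30); rc$score <- 0
  rc$strand <- sample(c("+", "-"), 30, TRUE)
  got <- nearest_gene(rc, rg)
  want <- nearest_gene_brute(rc, rg)
  ord <- function(d) d[order(d$cns, d$gene, d$distance), ]
  expect_equal(ord(got), ord(want), ignore_attr = TRUE)
})
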