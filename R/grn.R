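#' Tree-ensemble gene regulatory network inference
#'
#' For each target gene, a random-forest regression of its standardized
#' profile on all TF profiles (the target itself excluded from its
#' predictor set when it is a TF); the edge weight of a TF is its impurity
#' importance (summed variance reduction), normalized per target to sum 1.
#'
#' @param es an \code{expression_set} (>= 8 samples).
#' @param tf_ids,target_ids gene ids present in \code{es}.
#' @param n_trees trees per forest (default 1000).
#' @param seed integer seed.
#' @return A \code{target_network}: list with \code{edges} (data.frame tf,
#'   target, weight), \code{tf_ids}, \code{target_ids}, \code{threshold}
#'   (NA until thresholded), \code{space = "gene"}.
#' @export
infer_grn <- function(es, tf_ids, target_ids, n_trees = 1000L, seed = 1L) {
  if (ncol(es$matrix) < 8) stop("need >= 8 samples for GRN inference")
  miss <- setdiff(c(tf_ids, target_ids), rownames(es$matrix))
  if (length(miss)) stop("ids missing from expression set: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  x <- t(scale(t(es$matrix[unique(c(tf_ids, target_ids)), , drop = FALSE])))
  edges <- .rf_edges(x, tf_ids, target_ids, n_trees, seed)
  structure(list(edges = edges, tf_ids = tf_ids, target_ids = target_ids,
                 threshold = NA_real_, space = "gene",
                 target_sets = NULL),
            class = "target_network")
}

.rf_edges <- function(x, tf_ids, target_ids, n_trees, seed) {
  res <- lapply(seq_along(target_ids), function(i) {
    tg <- target_ids[i]
    preds <- setdiff(tf_ids, tg)
    if (length(preds) < 2) stop("fewer than 2 predictors for target ", tg)
    df <- data.frame(t(x[preds, , drop = FALSE]), check.names = FALSE)
    df$.y <- x[tg, ]
    rf <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = n_trees, mtry = max(1L, floor(sqrt(length(preds)))),
      importance = "impurity", seed = child_seed(seed, i),
      num.threads = 1L, verbose = FALSE)
    imp <- rf$variable.importance
    imp[imp < 0] <- 0
    w <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
    data.frame(tf = names(imp), target = tg, weight = as.numeric(w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Permuted-network FDR edge-weight threshold
#'
#' Re-runs the inference with each target's expression shuffled across
#' samples (TFs untouched), pools the permuted edge weights as a null, and
#' estimates FDR(w) = mean permuted count >= w / real count >= w. The
#' threshold is the smallest real weight whose monotone-adjusted FDR is at
#' or below \code{fdr}.
#'
#' @param es,tf_ids,target_ids,n_trees as in \code{\link{infer_grn}}.
#' @param net the real \code{target_network} from \code{\link{infer_grn}}.
#' @param fdr target false discovery rate (default 0.05).
#' @param n_perm_networks permuted networks to pool (default 1).
#' @param seed integer seed (independent of the real network's).
#' @return list with \code{threshold} (w*, +Inf when unattainable),
#'   \code{fdr_table} (weight, fdr_raw, fdr_adj), \code{null_weights}.
#' @export
permuted_edge_threshold <- function(es, tf_ids, target_ids, net,
                                    n_trees = 1000L, fdr = 0.05,
                                    n_perm_networks = 1L, seed = 1L) {
  if (n_perm_networks < 1) stop("n_perm_networks must be >= 1")
  x <- t(scale(t(es$matrix[unique(c(tf_ids, target_ids)), , drop = FALSE])))
  null_w <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm_networks), function(b) {
      ## shuffle each target's response across samples; TF predictor
      ## profiles keep their real values
      xtg <- x[target_ids, , drop = FALSE]
      for (j in seq_along(target_ids)) xtg[j, ] <- sample(x[target_ids[j], ])
      .rf_edges_perm(x, xtg, tf_ids, target_ids, n_trees,
                     child_seed(seed, b))$weight
    }), use.names = FALSE)
  })
  real_w <- net$edges$weight
  cand <- sort(unique(real_w))
  n_real <- length(real_w)
  n_null_per <- length(null_w) / n_perm_networks
  sr <- sort(real_w); sn <- sort(null_w)
  fdr_raw <- vapply(cand, function(w) {
    r <- n_real - findInterval(w, sr, left.open = TRUE)
    ## permuted tail count floored at 1: a lone real edge beyond the
    ## permuted maximum is not evidence of FDR 0
    nn <- max(1, length(sn) - findInterval(w, sn, left.open = TRUE)) /
      n_perm_networks
    if (r == 0) return(1)
    min(1, nn / r)
  }, 0)
  ## monotone adjustment: running minimum over ascending thresholds, so
  ## the estimate is nonincreasing in w and the threshold lands at the
  ## first genuine crossing; the tail floor above keeps sparse permuted
  ## tails (tiny real counts beyond the permuted maximum) from dipping
  fdr_adj <- cummin(fdr_raw)
  ok <- which(fdr_adj <= fdr)
  threshold <- if (length(ok)) cand[ok[1]] else {
    warning("no edge weight achieves FDR <= ", fdr, "; threshold set to +Inf")
    Inf
  }
  list(threshold = threshold,
       fdr_table = data.frame(weight = cand, fdr_raw = fdr_raw,
                              fdr_adj = fdr_adj),
       null_weights = null_w)
}

## inference against shuffled target responses; predictors use real profiles
.rf_edges_perm <- function(x, xtg_perm, tf_ids, target_ids, n_trees, seed) {
  res <- lapply(seq_along(target_ids), function(i) {
    tg <- target_ids[i]
    preds <- setdiff(tf_ids, tg)
    df <- data.frame(t(x[preds, , drop = FALSE]), check.names = FALSE)
    df$.y <- xtg_perm[i, ]
    rf <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = n_trees, mtry = max(1L, floor(sqrt(length(preds)))),
      importance = "impurity", seed = child_seed(seed, i),
      num.threads = 1L, verbose = FALSE)
    imp <- rf$variable.importance
    imp[imp < 0] <- 0
    w <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
    data.frame(tf = names(imp), target = tg, weight = as.numeric(w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Apply an edge-weight threshold and materialize per-TF target sets
#'
#' @param net a \code{target_network}.
#' @param threshold edge-weight threshold w* (e.g. from
#'   \code{\link{permuted_edge_threshold}}).
#' @return the network with \code{threshold} set and \code{target_sets}
#'   (named list TF -> character vector of targets with weight >= w*).
#' @export
threshold_network <- function(net, threshold) {
  keep <- net$edges$weight >= threshold
  ed <- net$edges[keep, , drop = FALSE]
  sets <- split(ed$target, factor(ed$tf, levels = net$tf_ids))
  net$threshold <- threshold
  net$target_sets <- lapply(sets, unique)
  net
}

#' Hypergeometric p-value for cross-species target-set overlap
#'
#' Maps one species' target set into the other's gene space through the
#' ortholog map (collisions collapse to one element) and returns the
#' upper-tail hypergeometric probability of the observed overlap within the
#' mapped universe.
#'
#' @param set_br targets in species-B gene space.
#' @param set_at targets in species-A gene space.
#' @param ortholog_map data.frame with columns \code{br}, \code{at}
#'   (each B gene maps to at most one A gene).
#' @param universe character vector of A-space genes defining the draw
#'   population.
#' @return list with \code{p}, \code{k} (overlap), \code{n} (mapped B set
#'   size), \code{K} (A set size), \code{N} (universe size).
#' @export
target_overlap_pvalue <- function(set_br, set_at, ortholog_map, universe) {
  if (anyDuplicated(ortholog_map$br))
    stop("each species-B gene must map to at most one species-A gene")
  mapped <- unique(ortholog_map$at[match(set_br, ortholog_map$br)])
  mapped <- mapped[!is.na(mapped)]
  mapped <- intersect(mapped, universe)
  set_at <- intersect(unique(set_at), universe)
  if (!length(mapped) || !length(set_at))
    return(list(p = NA_real_, k = 0L, n = length(mapped),
                K = length(set_at), N = length(universe), flagged = TRUE))
  N <- length(universe); K <- length(set_at); n <- length(mapped)
  k <- length(intersect(mapped, set_at))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(p = p, k = k, n = n, K = K, N = N, flagged = FALSE)
}

#' Permutation test for divergence between two paralog target sets
#'
#' Observed statistic: |log10 pA - log10 pB| of the two copies' overlap
#' p-values against the fixed species-A target set. The null draws random
#' target groups of the same sizes from the universe, recomputes both
#' overlap p-values and the difference. Br1 (the more conserved copy) is
#' assigned only when the permutation p is below \code{alpha}.
#'
#' @param pA,pB observed overlap p-values of copy A and copy B.
#' @param sizes integer vector length 2: mapped target-set sizes of the
#'   two copies.
#' @param set_at species-A target set (A-space ids).
#' @param universe A-space universe to sample from.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @param alpha significance level for Br1 assignment (default 0.05).
#' @param use_log compare log10 p-values (default TRUE); FALSE compares raw
#'   p differences.
#' @return list with \code{delta}, \code{p}, \code{br1} ("copyA"/"copyB"/NA),
#'   \code{n_perm}.
#' @export
divergence_permutation_test <- function(pA, pB, sizes, set_at, universe,
                                        n_perm = 10000L, seed = 1L,
                                        alpha = 0.05, use_log = TRUE) {
  if (any(sizes < 1)) stop("target group sizes must be >= 1")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  stat <- function(a, b) if (use_log) abs(log10(a) - log10(b)) else abs(a - b)
  delta <- stat(pA, pB)
  K <- length(intersect(unique(set_at), universe))
  N <- length(universe)
  pv <- function(k, n) stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  ## sizes sorted so the null is exactly invariant to copy order
  ss <- sort(as.integer(sizes))
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      kA <- sum(sample.int(N, ss[1]) <= K)
      kB <- sum(sample.int(N, ss[2]) <= K)
      stat(pv(kA, ss[1]), pv(kB, ss[2]))
    }, 0)
  })
  p <- (1 + sum(null >= delta)) / (1 + n_perm)
  br1 <- if (p < alpha) { if (pA <= pB) "copyA" else "copyB" } else NA_character_
  list(delta = delta, p = p, br1 = br1, n_perm = n_perm,
       null_mean = mean(null))
}

#' Project a thresholded gene-space network into CNS space
#'
#' Replaces each TF's gene target set by the union of the conserved
#' noncoding sequences (CNSs) associated with those genes, so overlap and
#' divergence tests can run on regulatory-element ids instead of genes.
#'
#' @param net a thresholded \code{target_network} in gene space.
#' @param cns_map data.frame with columns \code{cns}, \code{gene}.
#' @return the network with \code{space = "CNS"} and CNS-id target sets;
#'   TFs whose targets have no CNS get an empty set (flagged via attribute
#'   \code{"empty_tfs"}).
#' @export
project_targets_to_cns <- function(net, cns_map) {
  if (is.null(net$target_sets))
    stop("network must be thresholded first (see threshold_network)")
  sets <- lapply(net$target_sets, function(tg)
    sort(unique(cns_map$cns[cns_map$gene %in% tg])))
  empty <- names(sets)[vapply(sets, length, 0L) == 0 &
                         vapply(net$target_sets, length, 0L) > 0]
  net$target_sets <- sets
  net$space <- "CNS"
  attr(net, "empty_tfs") <- empty
  net
}

#' Filter CNS alignment hits
#'
#' Applies, in order: (1) drop rows with bitscore <= \code{bitscore_min};
#' (2) drop rows with query coverage (qcovs) below \code{min_qcovs};
#' (3) drop ALL remaining rows of any CNS query whose surviving hit count
#' exceeds \code{species_cap} (1 for a diploid reference, 3 for a
#' triplicated one). Idempotent.
#'
#' @param hits data.frame with at least \code{qaccver}, \code{saccver},
#'   \code{bitscore}, \code{qcovs} (BLAST outfmt-10 style).
#' @param species_cap maximum allowed surviving hits per CNS (default 3).
#' @param bitscore_min bitscore at or below which rows are dropped
#'   (default 28.2).
#' @param min_qcovs minimum query coverage kept (default 60).
#' @return the filtered data.frame.
#' @export
filter_cns_hits <- function(hits, species_cap = 3L, bitscore_min = 28.2,
                            min_qcovs = 60) {
  need <- c("qaccver", "saccver", "bitscore", "qcovs")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  keep <- hits$bitscore > bitscore_min & hits$qcovs >= min_qcovs
  out <- hits[keep, , drop = FALSE]
  cnt <- table(out$qaccver)
  bad <- names(cnt)[cnt > species_cap]
  out <- out[!(out$qaccver %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nearest same-strand gene for each CNS interval
#'
#' For every CNS interval, reports the nearest gene(s) on the same strand
#' and chromosome, with all ties reported. Distances are signed: negative
#' when the CNS lies before the gene (in genomic coordinates), positive
#' when after, and 0 when the CNS is intragenic (overlapping). Intervals
#' are BED-style 0-based half-open.
#'
#' @param cns_intervals,genes data.frames with BED6 columns
#'   \code{chrom,start,end,name,score,strand}.
#' @return data.frame (cns, gene, distance) with one row per association.
#' @export
nearest_gene <- function(cns_intervals, genes) {
  .check_bed <- function(b, what) {
    need <- c("chrom", "start", "end", "name", "strand")
    miss <- setdiff(need, names(b))
    if (length(miss)) stop(what, " missing BED column(s): ",
                           paste(miss, collapse = ", "))
    bad <- which(b$end <= b$start | b$start < 0)
    if (length(bad)) stop("malformed ", what, " interval at line ", bad[1])
  }
  .check_bed(cns_intervals, "cns")
  .check_bed(genes, "genes")
  out <- vector("list", nrow(cns_intervals))
  for (i in seq_len(nrow(cns_intervals))) {
    c0 <- cns_intervals[i, ]
    g <- genes[genes$chrom == c0$chrom & genes$strand == c0$strand, ,
               drop = FALSE]
    if (!nrow(g)) next
    ## signed distance, 0 for any overlap
    d <- ifelse(c0$end <= g$start, -(g$start - c0$end + 1),
         ifelse(c0$start >= g$end, c0$start - g$end + 1, 0))
    best <- which(abs(d) == min(abs(d)))
    out[[i]] <- data.frame(cns = c0$name, gene = g$name[best],
                           distance = d[best], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cns = character(), gene = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
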