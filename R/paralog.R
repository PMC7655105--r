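#' Expand paralog groups into two-member pairs
#'
#' Two-copy groups give one pair; three-copy groups are converted into
#' three two-way comparisons (ab, bc, ac) so one analysis covers both.
#' Pairs are kept only when both members are in the expressed set.
#'
#' @param groups data.frame with columns \code{group_id}, \code{gene_id}
#'   (one row per member), or a named list of member vectors.
#' @param expressed character vector of expressed gene ids.
#' @return data.frame (group_id, gene1, gene2, provenance) where provenance
#'   is \code{"2-copy"} or \code{"3-copy-split"}.
#' @export
expand_pairs <- function(groups, expressed) {
  if (is.list(groups) && !is.data.frame(groups)) {
    groups <- data.frame(
      group_id = rep(names(groups), lengths(groups)),
      gene_id = unlist(groups, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  sp <- split(groups$gene_id, groups$group_id)
  out <- lapply(names(sp), function(gid) {
    members <- unique(sp[[gid]])
    if (length(members) > 3)
      stop("group ", gid, " has more than 3 members")
    if (length(members) < 2) return(NULL)
    members <- members[members %in% expressed]
    if (length(members) < 2) return(NULL)
    cmb <- utils::combn(members, 2)
    data.frame(group_id = gid, gene1 = cmb[1, ], gene2 = cmb[2, ],
               provenance = if (length(sp[[gid]]) >= 3) "3-copy-split"
                            else "2-copy",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(group_id = character(), gene1 = character(),
                      gene2 = character(), provenance = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

## build a pair-level kME encoding: "treatment" becomes the pair member,
## courses come from the members' (treatment, replicate) courses, with the
## original treatment retained as a covariate (e.g. entrainment)
.pair_kme <- function(kme, pairs) {
  arr <- kme$values
  genes <- dimnames(arr)[[1]]
  i1 <- match(pairs$gene1, genes)
  i2 <- match(pairs$gene2, genes)
  ok <- !is.na(i1) & !is.na(i2)
  if (!all(ok))
    warning(sum(!ok), " pair(s) skipped: member missing from kME encoding")
  pairs <- pairs[ok, , drop = FALSE]
  i1 <- i1[ok]; i2 <- i2[ok]
  cc <- dim(arr)[3]
  pair_ids <- paste(pairs$gene1, pairs$gene2, sep = "|")
  v1 <- arr[i1, , , drop = FALSE]
  v2 <- arr[i2, , , drop = FALSE]
  vals <- array(NA_real_, dim = c(length(i1), dim(arr)[2], 2L * cc),
                dimnames = list(pair_ids, dimnames(arr)[[2]], NULL))
  vals[, , seq_len(cc)] <- v1
  vals[, , cc + seq_len(cc)] <- v2
  courses <- rbind(
    data.frame(member = "copy1", entrainment = kme$courses$treatment,
               replicate = kme$courses$replicate,
               stringsAsFactors = FALSE),
    data.frame(member = "copy2", entrainment = kme$courses$treatment,
               replicate = kme$courses$replicate,
               stringsAsFactors = FALSE))
  courses$course <- paste(courses$member, courses$entrainment,
                          courses$replicate, sep = ".")
  dimnames(vals)[[3]] <- courses$course
  list(kme = structure(list(values = vals, courses = courses,
                            scope = c("member", "entrainment", "replicate")),
                       class = "kme_encoding"),
       pairs = pairs)
}

#' Differential pattern and median tests for paralog pairs
#'
#' Applies the pattern-test machinery with "treatment" replaced by the pair
#' member (copy1 vs copy2) and the original treatment (e.g. LD vs HC
#' entrainment) modeled as a covariate. Significant pairs are oriented:
#' Br1 is gene1 when the signed t-sum is positive, otherwise gene2; the
#' test itself is symmetric in member order (same p, flipped sign).
#'
#' @param es an \code{expression_set} (used for the median test).
#' @param pairs data.frame with columns gene1, gene2 (e.g. from
#'   \code{\link{expand_pairs}}).
#' @param kme a \code{kme_encoding} of the same expression set.
#' @param n_perm_sets permutation sets for both nulls.
#' @param seed integer seed.
#' @param use_covariate model the original treatment as covariate
#'   (default TRUE).
#' @param alpha significance cutoff (default 0.01).
#' @return data.frame per pair: gene1, gene2, provenance (if present),
#'   score, signed_sum, p_pattern, t_median, p_median, significant_pattern,
#'   significant_median, Br1 (NA unless the pattern test is significant).
#' @export
pair_pattern_test <- function(es, pairs, kme, n_perm_sets = 1L, seed,
                              use_covariate = TRUE, alpha = 0.01) {
  ## canonicalize member order so the result is exactly symmetric in
  ## gene1/gene2; signs are flipped back on report
  orig <- pairs
  swapped <- pairs$gene1 > pairs$gene2
  tmp <- pairs$gene1[swapped]
  pairs$gene1[swapped] <- pairs$gene2[swapped]
  pairs$gene2[swapped] <- tmp
  pk <- .pair_kme(kme, pairs)
  covar <- if (use_covariate &&
               length(unique(pk$kme$courses$entrainment)) > 1)
    "entrainment" else NULL
  pt <- pattern_test(pk$kme, n_perm_sets = n_perm_sets, seed = seed,
                     treatment_col = "member", covariate_col = covar,
                     alpha = alpha)
  pairs <- pk$pairs
  med <- median_profile(es, group_by = c("treatment", "replicate"))
  m1 <- med[pairs$gene1, , drop = FALSE]
  m2 <- med[pairs$gene2, , drop = FALSE]
  pm <- cbind(m1, m2)
  rownames(pm) <- paste(pairs$gene1, pairs$gene2, sep = "|")
  courses <- data.frame(
    member = rep(c("copy1", "copy2"), each = ncol(m1)),
    entrainment = rep(sub("\\.[^.]*$", "", colnames(med)), 2),
    stringsAsFactors = FALSE)
  mt <- median_change_test(pm, courses, n_perm_sets = n_perm_sets,
                           seed = child_seed(seed, 1), treatment_col = "member",
                           covariate_col = if (!is.null(covar)) "entrainment"
                                           else NULL,
                           alpha = alpha)
  stopifnot(identical(pt$table$gene, mt$table$gene))
  kept <- paste(pairs$gene1, pairs$gene2, sep = "|")
  ko <- match(kept, paste(pmin(orig$gene1, orig$gene2),
                          pmax(orig$gene1, orig$gene2), sep = "|"))
  flip <- swapped[ko]
  sgn <- ifelse(flip, -1, 1)
  out <- data.frame(orig[ko, , drop = FALSE],
                    score = pt$table$score,
                    signed_sum = sgn * pt$table$signed_sum,
                    p_pattern = pt$table$p,
                    t_median = sgn * mt$table$t,
                    p_median = mt$table$p,
                    significant_pattern = pt$table$significant,
                    significant_median = mt$table$significant,
                    stringsAsFactors = FALSE)
  out$Br1 <- ifelse(out$significant_pattern,
                    ifelse(out$signed_sum > 0, out$gene1, out$gene2),
                    NA_character_)
  attr(out, "pattern_null") <- pt$null
  attr(out, "median_null") <- mt$null
  out
}

#' Split paralog groups into highest- and lowest-expressed members
#'
#' Members are ranked by mean log2 expression over all timepoints; the
#' highest and lowest are emitted (the middle copy of a 3-copy group is
#' excluded). A matched control is produced by randomly pairing single-copy
#' genes (each used at most once) and splitting the random pairs the same
#' way.
#'
#' @param groups data.frame (group_id, gene_id) or named list of members.
#' @param es an \code{expression_set}.
#' @param single_copy character vector of single-copy gene ids for the
#'   matched control.
#' @param seed integer seed for the control pairing.
#' @return list with \code{paralog} (group_id, high, low) and
#'   \code{control} (pair_id, high, low) data.frames.
#' @export
high_low_split <- function(groups, es, single_copy = character(), seed = 1L) {
  if (is.list(groups) && !is.data.frame(groups)) {
    groups <- data.frame(group_id = rep(names(groups), lengths(groups)),
                         gene_id = unlist(groups, use.names = FALSE),
                         stringsAsFactors = FALSE)
  }
  mu <- rowMeans(es$matrix)
  sp <- split(groups$gene_id, groups$group_id)
  para <- do.call(rbind, lapply(names(sp), function(gid) {
    members <- unique(sp[[gid]])
    members <- members[members %in% names(mu)]
    if (length(members) < 2) return(NULL)
    ## ties in mean expression broken deterministically by gene id order
    ord <- order(-mu[members], members)
    data.frame(group_id = gid, high = members[ord[1]],
               low = members[ord[length(members)]],
               stringsAsFactors = FALSE)
  }))
  rownames(para) <- NULL
  single_copy <- intersect(single_copy, names(mu))
  control <- NULL
  if (length(single_copy) >= 2) {
    perm <- with_seed(seed, sample(single_copy))
    npair <- floor(length(perm) / 2)
    g1 <- perm[seq_len(npair) * 2 - 1]
    g2 <- perm[seq_len(npair) * 2]
    hi <- ifelse(mu[g1] >= mu[g2], g1, g2)
    lo <- ifelse(mu[g1] >= mu[g2], g2, g1)
    control <- data.frame(pair_id = sprintf("ctrl_%04d", seq_len(npair)),
                          high = hi, low = lo, stringsAsFactors = FALSE)
    rownames(control) <- NULL
  }
  list(paralog = para, control = control)
}

#' Permutation enrichment of condition-responsive genes in a pair subset
#'
#' Tests whether a subset of paralog pairs (e.g. those with divergent
#' patterns) is enriched for responsive genes, by drawing random same-size
#' subsets of the full pair list. Three statistics: (i) number of
#' responsive genes covered by the subset's pairs, (ii) number of subset
#' pairs with exactly one responsive member, (iii) number with both.
#' Upper-tail p: \eqn{(1 + \#\{null \ge obs\}) / (1 + n_{perm})}.
#'
#' @param pairs_subset,all_pairs data.frames with gene1, gene2;
#'   \code{pairs_subset} must be a subset of \code{all_pairs}.
#' @param responsive_genes character vector of responsive gene ids.
#' @param n_perm number of random subsets (default 10000).
#' @param seed integer seed.
#' @return named list of three results (\code{genes}, \code{one_member},
#'   \code{both_members}), each with \code{observed}, \code{n_perm},
#'   \code{null_mean}, \code{tail_count}, \code{p}.
#' @export
response_enrichment <- function(pairs_subset, responsive_genes, all_pairs,
                                n_perm = 10000L, seed = 1L) {
  n_sub <- nrow(pairs_subset)
  n_all <- nrow(all_pairs)
  if (n_sub > n_all) stop("subset larger than the full pair list")
  r1 <- all_pairs$gene1 %in% responsive_genes
  r2 <- all_pairs$gene2 %in% responsive_genes
  key_all <- paste(all_pairs$gene1, all_pairs$gene2, sep = "|")
  key_sub <- paste(pairs_subset$gene1, pairs_subset$gene2, sep = "|")
  idx_sub <- match(key_sub, key_all)
  if (anyNA(idx_sub)) stop("pairs_subset contains pairs not in all_pairs")
  stat3 <- function(idx) {
    g <- unique(c(all_pairs$gene1[idx], all_pairs$gene2[idx]))
    c(genes = sum(g %in% responsive_genes),
      one_member = sum(xor(r1[idx], r2[idx])),
      both_members = sum(r1[idx] & r2[idx]))
  }
  obs <- stat3(idx_sub)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) stat3(sample.int(n_all, n_sub)),
           c(genes = 0, one_member = 0, both_members = 0))
  })
  out <- lapply(names(obs), function(nm) {
    tail_count <- sum(null[nm, ] >= obs[[nm]])
    list(observed = as.numeric(obs[[nm]]), n_perm = n_perm,
         null_mean = mean(null[nm, ]), tail_count = tail_count,
         p = (1 + tail_count) / (1 + n_perm))
  })
  names(out) <- names(obs)
  out
}
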