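#' Empirical-Bayes moderated linear-model contrasts
#'
#' Ordinary least squares per gene on a cell-means design built from
#' \code{groups} (one coefficient per group level) plus optional additive
#' covariate factors, followed by empirical-Bayes variance shrinkage and
#' moderated t-statistics for the requested contrasts. The shrinkage
#' hyperparameters (prior df d0, prior variance s0^2) are estimated by
#' moment-matching the marginal distribution of the log sample variances to
#' a scaled log-F via digamma/trigamma inversion; the moderated variance is
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}.
#'
#' Fitting is delegated to limma (lmFit/contrasts.fit/eBayes); this wrapper
#' fixes the design construction and exposes the hyperparameters.
#'
#' @param response numeric matrix, genes x conditions.
#' @param groups factor of length \code{ncol(response)} defining the cell
#'   means.
#' @param contrasts named list; each element is a named numeric vector of
#'   weights over \code{levels(groups)} (missing levels get weight 0).
#' @param covariates optional data.frame of additional factors (one row per
#'   condition) entering the design additively.
#' @return A \code{moderated_fit}: list with \code{t}, \code{coefficients}
#'   (genes x contrasts), \code{s2} (residual variances), \code{df_residual},
#'   \code{df_prior}, \code{s2_prior}, \code{s2_post}, \code{design}.
#' @export
fit_moderated_contrasts <- function(response, groups, contrasts,
                                    covariates = NULL) {
  response <- as.matrix(response)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != ncol(response))
    stop("one group per response column required")
  df <- data.frame(.g = groups)
  form <- ~ 0 + .g
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) df[[nm]] <- as.factor(covariates[[nm]])
    form <- stats::as.formula(paste("~ 0 + .g +",
                                    paste(names(covariates), collapse = " + ")))
  }
  design <- stats::model.matrix(form, data = df)
  colnames(design) <- sub("^\\.g", "", colnames(design))
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  if (is.null(names(contrasts)) || any(!nzchar(names(contrasts))))
    stop("contrasts must be a named list")
  cmat <- vapply(contrasts, function(w) {
    v <- stats::setNames(numeric(ncol(design)), colnames(design))
    bad <- setdiff(names(w), colnames(design))
    if (length(bad)) stop("unknown design column(s) in contrast: ",
                          paste(bad, collapse = ", "))
    v[names(w)] <- w
    v
  }, numeric(ncol(design)))
  rownames(cmat) <- colnames(design)
  fit <- limma::lmFit(response, design)
  fit <- limma::contrasts.fit(fit, cmat)
  fit <- limma::eBayes(fit)
  if (!is.finite(fit$df.prior[1]))
    warning("prior df estimated as infinite; all variances shrunk to the prior")
  structure(list(t = fit$t, coefficients = fit$coefficients,
                 s2 = fit$sigma^2, df_residual = fit$df.residual,
                 df_prior = fit$df.prior, s2_prior = fit$s2.prior,
                 s2_post = fit$s2.post, design = design,
                 contrast_matrix = cmat),
            class = "moderated_fit")
}

#' Flatten a kME encoding into a genes x (module, course) response matrix
#'
#' @param kme a \code{kme_encoding} from \code{\link{compute_kme}}.
#' @return matrix with one column per (module, course), plus attribute
#'   \code{"layout"}: data.frame with module and the course metadata per
#'   column.
#' @export
kme_response <- function(kme) {
  arr <- kme$values
  g <- dim(arr)[1]; m <- dim(arr)[2]; cc <- dim(arr)[3]
  mat <- matrix(arr, nrow = g, ncol = m * cc,
                dimnames = list(dimnames(arr)[[1]], NULL))
  layout <- data.frame(module = rep(dimnames(arr)[[2]], times = cc),
                       kme$courses[rep(seq_len(cc), each = m), , drop = FALSE],
                       row.names = NULL)
  colnames(mat) <- paste(layout$module, layout$course, sep = "|")
  attr(mat, "layout") <- layout
  mat
}

#' Per-gene pattern-change scores from a moderated fit
#'
#' The pattern-change score of a gene is the sum of absolute moderated
#' t-statistics over the per-module contrasts; the signed sum retains the
#' direction used to orient pair members.
#'
#' @param fit a \code{moderated_fit} with one contrast per module.
#' @return data.frame (gene, score, signed_sum).
#' @export
pattern_change_scores <- function(fit) {
  t <- fit$t
  data.frame(gene = rownames(t),
             score = rowSums(abs(t)),
             signed_sum = rowSums(t),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Empirical p-values against a permutation null
#'
#' \eqn{p_g = (1 + \#\{null \ge obs_g\}) / (1 + |null|)}; never below
#' \eqn{1/(|null|+1)}.
#'
#' @param observed numeric vector of observed scores.
#' @param null numeric vector of null scores.
#' @return numeric vector of p-values, same length/names as observed.
#' @export
empirical_pvalues <- function(observed, null) {
  if (!length(null)) stop("null distribution is empty")
  ns <- sort(null)
  ge <- length(null) - findInterval(observed, ns, left.open = TRUE)
  stats::setNames((1 + ge) / (1 + length(null)), names(observed))
}

## internal: fit per-module treatment contrasts on a kME response matrix
.fit_kme_contrasts <- function(resp, layout, treatment_col, covariate_col) {
  trt <- as.factor(layout[[treatment_col]])
  if (nlevels(trt) != 2)
    stop("pattern test requires exactly 2 levels of '", treatment_col, "'")
  groups <- factor(paste(layout$module, trt, sep = "."))
  lv <- levels(trt)
  mods <- sort(unique(layout$module))
  contrasts <- lapply(mods, function(m)
    stats::setNames(c(1, -1), paste(m, lv, sep = ".")))
  names(contrasts) <- mods
  covars <- if (!is.null(covariate_col))
    stats::setNames(list(as.factor(layout[[covariate_col]])), covariate_col)
  fit_moderated_contrasts(resp, groups, contrasts,
                          covariates = if (!is.null(covariate_col))
                            as.data.frame(covars) else NULL)
}

## permute gene rows independently within each underlying dataset block
## (treatment, and covariate level when present), destroying the
## within-gene cross-block pairing while preserving each block's marginal
## pattern population; mirrors re-assigning gene accessions to expression
## patterns separately per input dataset
.permute_within_treatment <- function(resp, layout, treatment_col,
                                      covariate_col = NULL) {
  block <- layout[[treatment_col]]
  if (!is.null(covariate_col))
    block <- paste(block, layout[[covariate_col]], sep = "\r")
  out <- resp
  for (tr in unique(block)) {
    cols <- which(block == tr)
    out[, cols] <- resp[sample.int(nrow(resp)), cols, drop = FALSE]
  }
  out
}

#' Permutation null for pattern-change scores
#'
#' For each permuted set, gene labels are shuffled independently within each
#' treatment (one permutation per treatment applied to that treatment's
#' whole kME block) and the full scoring pipeline (moderated fit plus score)
#' is re-run; all permuted-gene scores are pooled.
#'
#' @param kme a \code{kme_encoding}.
#' @param n_perm_sets number of full-size permuted sets (>= 1).
#' @param seed integer seed (mandatory).
#' @param treatment_col course column holding the compared condition.
#' @param covariate_col optional course column modeled as covariate.
#' @return numeric vector of pooled null scores
#'   (length \code{n_perm_sets * n_genes}).
#' @export
permutation_null <- function(kme, n_perm_sets = 1L, seed,
                             treatment_col = "treatment",
                             covariate_col = NULL) {
  if (n_perm_sets < 1) stop("n_perm_sets must be >= 1")
  resp <- kme_response(kme)
  layout <- attr(resp, "layout")
  keep <- stats::complete.cases(resp)
  resp <- resp[keep, , drop = FALSE]
  with_seed(seed, {
    unlist(lapply(seq_len(n_perm_sets), function(i) {
      perm <- .permute_within_treatment(resp, layout, treatment_col,
                                        covariate_col)
      fit <- .fit_kme_contrasts(perm, layout, treatment_col, covariate_col)
      pattern_change_scores(fit)$score
    }), use.names = FALSE)
  })
}

#' Differential pattern test on kME encodings
#'
#' Runs the moderated per-module contrasts on the kME response, scores each
#' gene by the summed absolute moderated t, builds a permutation null by
#' shuffling gene labels within treatment, and assigns empirical p-values.
#'
#' @inheritParams permutation_null
#' @param alpha significance cutoff on the empirical p (default 0.01).
#' @return A \code{pattern_test_result}: list with \code{table} (gene,
#'   score, signed_sum, p, significant), \code{null} (pooled null scores),
#'   \code{fit}, \code{alpha}, \code{seed}.
#' @export
pattern_test <- function(kme, n_perm_sets = 1L, seed,
                         treatment_col = "treatment",
                         covariate_col = NULL, alpha = 0.01) {
  resp <- kme_response(kme)
  layout <- attr(resp, "layout")
  keep <- stats::complete.cases(resp)
  if (!all(keep))
    warning(sum(!keep), " gene(s) with missing kME dropped from the test")
  respc <- resp[keep, , drop = FALSE]
  fit <- .fit_kme_contrasts(respc, layout, treatment_col, covariate_col)
  obs <- pattern_change_scores(fit)
  null <- permutation_null(kme, n_perm_sets = n_perm_sets, seed = seed,
                           treatment_col = treatment_col,
                           covariate_col = covariate_col)
  p <- empirical_pvalues(stats::setNames(obs$score, obs$gene), null)
  tab <- data.frame(gene = obs$gene, score = obs$score,
                    signed_sum = obs$signed_sum, p = as.numeric(p),
                    significant = as.numeric(p) < alpha,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, null = null, fit = fit, alpha = alpha,
                 seed = seed, n_perm_sets = n_perm_sets),
            class = "pattern_test_result")
}

#' Differential median-expression test
#'
#' The level counterpart of the pattern test: one median log2 value per
#' (treatment, replicate) course, a single moderated treatment contrast,
#' |t| as the score, and the same within-treatment label-permutation null.
#' Each gene's median vector is centered (its grand mean removed) before
#' the fit: the permutation null re-pairs course blocks across genes, and
#' without centering it would be dominated by between-gene baseline
#' differences rather than treatment offsets.
#'
#' @param medians genes x courses matrix from \code{\link{median_profile}}.
#' @param courses data.frame (one row per column of \code{medians}) with at
#'   least the treatment column.
#' @inheritParams pattern_test
#' @return A \code{median_test_result}: list with \code{table} (gene, t,
#'   score, p, significant), \code{null}, \code{alpha}, \code{seed}.
#' @export
median_change_test <- function(medians, courses, n_perm_sets = 1L, seed,
                               treatment_col = "treatment",
                               covariate_col = NULL, alpha = 0.01) {
  if (nrow(courses) != ncol(medians))
    stop("one course row per median column required")
  medians <- medians - rowMeans(medians)
  fit1 <- function(m) {
    trt <- as.factor(courses[[treatment_col]])
    if (nlevels(trt) != 2) stop("median test requires exactly 2 treatments")
    contr <- list(delta = stats::setNames(c(1, -1), levels(trt)))
    covars <- if (!is.null(covariate_col))
      stats::setNames(data.frame(as.factor(courses[[covariate_col]])),
                      covariate_col)
    fit_moderated_contrasts(m, trt, contr, covariates = covars)
  }
  fit <- fit1(medians)
  tvec <- drop(fit$t)
  null <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm_sets), function(i) {
      perm <- .permute_within_treatment(medians, courses, treatment_col,
                                        covariate_col)
      abs(drop(fit1(perm)$t))
    }), use.names = FALSE)
  })
  score <- abs(tvec)
  p <- empirical_pvalues(stats::setNames(score, rownames(medians)), null)
  tab <- data.frame(gene = rownames(medians), t = tvec, score = score,
                    p = as.numeric(p), significant = as.numeric(p) < alpha,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, null = null, alpha = alpha, seed = seed,
                 n_perm_sets = n_perm_sets),
            class = "median_test_result")
}

#' Combined pattern + median score
#'
#' The plain sum of the pattern and median scores per gene (the default).
#' A variant divides each component by the standard deviation of its own
#' permutation null before summing; note that the pattern null (scores of
#' completely re-paired patterns) is intrinsically much wider than the
#' observed score spread, so null-SD standardization down-weights the
#' pattern component heavily.
#'
#' @param pattern a \code{pattern_test_result}.
#' @param median a \code{median_test_result}.
#' @param standardize divide each score by its null SD first
#'   (default FALSE: raw sum).
#' @return named numeric vector of combined scores.
#' @export
combined_score <- function(pattern, median, standardize = FALSE) {
  pt <- pattern$table; mt <- median$table
  if (!setequal(pt$gene, mt$gene))
    stop("pattern and median tests cover different gene universes")
  mt <- mt[match(pt$gene, mt$gene), ]
  if (standardize) {
    sp <- stats::sd(pattern$null); sm <- stats::sd(median$null)
    if (sp <= 0 || sm <= 0) stop("degenerate null distribution")
    stats::setNames(pt$score / sp + mt$score / sm, pt$gene)
  } else {
    stats::setNames(pt$score + mt$score, pt$gene)
  }
}

#' Cluster significant genes (or pair members) by expression pattern
#'
#' Items are represented by their z-scored mean time profiles (means over
#' replicates within each (treatment, time); for pairs the two member
#' profiles are concatenated), clustered by average linkage on 1 - Pearson
#' correlation, cut at \code{cut_height}, and the clusters are ordered by
#' the ZT phase of their mean profile and labeled \code{pDif_01, ...}.
#'
#' @param es an \code{expression_set}.
#' @param items character vector of gene ids, or a 2-column matrix /
#'   data.frame of pairs (gene1, gene2).
#' @param cut_height dendrogram cut height on 1 - correlation (default 0.5).
#' @param min_cluster smallest reported cluster (default 20); smaller
#'   clusters are absorbed into label 0.
#' @param period hours per cycle for phase ordering (default 24).
#' @return data.frame with the item ids, \code{cluster} (integer, 0 =
#'   unclustered), and \code{cluster_label} (\code{pDif_xx} in phase order).
#' @export
cluster_differential_patterns <- function(es, items, cut_height = 0.5,
                                          min_cluster = 20L, period = 24) {
  pairs <- !is.null(dim(items))
  prof <- .mean_time_profile(es)
  feat <- if (pairs) {
    items <- as.matrix(items)
    cbind(prof[items[, 1], , drop = FALSE], prof[items[, 2], , drop = FALSE])
  } else prof[items, , drop = FALSE]
  n <- nrow(feat)
  if (n < 2) stop("need at least 2 items to cluster")
  featz <- t(scale(t(feat)))
  if (n < min_cluster) {
    warning("fewer items than min_cluster; returning a single cluster")
    cl <- rep(1L, n)
  } else {
    d <- stats::as.dist(1 - stats::cor(t(featz)))
    hc <- stats::hclust(d, method = "average")
    cl <- stats::cutree(hc, h = cut_height)
    sizes <- table(cl)
    keep <- as.integer(names(sizes)[sizes >= min_cluster])
    cl <- ifelse(cl %in% keep, cl, 0L)
  }
  times <- sort(unique(es$design$time))
  tcols <- seq_along(times)
  phase_of <- function(v) times[which.max(v)] %% period
  labs <- sort(unique(cl[cl > 0]))
  if (length(labs)) {
    ph <- vapply(labs, function(l)
      phase_of(colMeans(featz[cl == l, tcols, drop = FALSE])), 0)
    ord <- labs[order(ph, labs)]
    remap <- stats::setNames(seq_along(ord), ord)
    cl[cl > 0] <- remap[as.character(cl[cl > 0])]
  }
  out <- if (pairs)
    data.frame(gene1 = items[, 1], gene2 = items[, 2], stringsAsFactors = FALSE)
  else data.frame(gene = items, stringsAsFactors = FALSE)
  out$cluster <- as.integer(cl)
  out$cluster_label <- ifelse(cl > 0, sprintf("pDif_%02d", cl), "")
  out
}

## mean profile over replicates within (treatment, time), concatenated
## across treatments in design order -> genes x (treatment x time)
.mean_time_profile <- function(es) {
  d <- es$design
  key <- interaction(d$treatment, d$time, sep = "@", drop = TRUE)
  cols <- levels(key)
  prof <- vapply(cols, function(k)
    rowMeans(es$matrix[, d$sample[key == k], drop = FALSE]),
    numeric(nrow(es$matrix)))
  ## order columns by treatment then time
  meta <- do.call(rbind, strsplit(cols, "@", fixed = TRUE))
  ord <- order(meta[, 1], as.numeric(meta[, 2]))
  prof[, ord, drop = FALSE]
}

#' Per-timepoint pairwise moderated-t baseline
#'
#' The conventional alternative to a pattern test: a moderated two-group
#' comparison at each timepoint separately, scoring each gene by its most
#' significant timepoint (max |t|).
#'
#' @param es an \code{expression_set} with exactly 2 treatments and
#'   replicated timepoints.
#' @param treatment_col design column to compare (default "treatment").
#' @return named numeric vector: per-gene max |moderated t| over timepoints.
#' @export
pairwise_timepoint_scores <- function(es, treatment_col = "treatment") {
  d <- es$design
  trt <- as.factor(d[[treatment_col]])
  if (nlevels(trt) != 2) stop("pairwise baseline requires 2 treatments")
  times <- sort(unique(d$time))
  tmat <- vapply(times, function(z) {
    cols <- which(d$time == z)
    g <- droplevels(trt[cols])
    if (nlevels(g) != 2 || any(table(g) < 2))
      stop("each timepoint needs both treatments with >= 2 replicates")
    fit <- fit_moderated_contrasts(
      es$matrix[, cols, drop = FALSE], g,
      list(delta = stats::setNames(c(1, -1), levels(g))))
    abs(drop(fit$t))
  }, numeric(nrow(es$matrix)))
  stats::setNames(apply(tmat, 1, max), rownames(es$matrix))
}
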