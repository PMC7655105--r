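#' Network construction parameters
#'
#' @param soft_power integer soft-thresholding power (>= 1).
#' @param signed use a signed adjacency ((1+r)/2)^beta instead of |r|^beta.
#' @param min_module_size smallest cluster kept as a module (>= 2).
#' @param cut_height static cut height on the 1-TOM dendrogram, in (0, 1];
#'   \code{NULL} (default) scans the merge heights and picks the height
#'   that maximizes the number of clusters reaching
#'   \code{min_module_size}.
#' @param merge_corr modules whose eigengenes correlate above this are merged.
#' @return list of class \code{network_params}.
#' @export
network_params <- function(soft_power = 6L, signed = FALSE,
                           min_module_size = 30L, cut_height = NULL,
                           merge_corr = 0.85) {
  if (soft_power < 1) stop("soft_power must be >= 1")
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  if (!is.null(cut_height) && (cut_height <= 0 || cut_height > 1))
    stop("cut_height must be in (0, 1]")
  if (merge_corr < 0 || merge_corr > 1) stop("merge_corr must be in [0, 1]")
  stopifnot_scalar_flag(signed, "signed")
  structure(list(soft_power = as.integer(soft_power), signed = signed,
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height, merge_corr = merge_corr),
            class = "network_params")
}

## adjacency from a correlation matrix; diagonal set to 0
.adjacency <- function(corr, power, signed) {
  a <- if (signed) ((1 + corr) / 2)^power else abs(corr)^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' \eqn{TOM_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})}
#' with the adjacency diagonal treated as 0. Symmetric, entries in [0, 1],
#' unit diagonal.
#'
#' @param adj symmetric adjacency matrix with zero diagonal, entries in [0,1].
#' @return the TOM matrix.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj))) stop("adjacency must be symmetric")
  diag(adj) <- 0
  k <- rowSums(adj)
  num <- adj %*% adj + adj
  den <- outer(k, k, pmin) + 1 - adj
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Pick a soft-thresholding power by the scale-free topology criterion
#'
#' Returns the smallest candidate power whose scale-free model fit R^2
#' (log-log regression of the binned connectivity distribution, counted only
#' when the slope is negative) reaches \code{r2_cut}; falls back to 12 with
#' a warning when none does.
#'
#' @param es an \code{expression_set} (>= 50 genes).
#' @param candidate_powers integer vector of powers to try.
#' @param r2_cut required model fit (default 0.8).
#' @param signed signed adjacency flag.
#' @return list with \code{power} and a \code{fit} table (power, r2, slope).
#' @export
pick_soft_threshold <- function(es, candidate_powers = c(1:10, 12, 14, 16, 18, 20),
                                r2_cut = 0.8, signed = FALSE) {
  if (!length(candidate_powers)) stop("candidate_powers must be nonempty")
  if (nrow(es$matrix) < 50) stop("need >= 50 genes to assess scale-free fit")
  corr <- stats::cor(t(es$matrix))
  fit <- t(vapply(candidate_powers, function(b) {
    a <- .adjacency(corr, b, signed)
    k <- rowSums(a)
    k <- k[k > 0]
    if (length(unique(k)) < 5) return(c(r2 = 0, slope = 0))
    nb <- 10L
    br <- seq(min(k), max(k), length.out = nb + 1L)
    cut <- cut(k, breaks = br, include.lowest = TRUE)
    dk <- tapply(k, cut, mean)
    pk <- tabulate(as.integer(cut), nbins = nb) / length(k)
    keep <- !is.na(dk) & pk > 0 & dk > 0
    if (sum(keep) < 3) return(c(r2 = 0, slope = 0))
    lmfit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
    c(r2 = summary(lmfit)$r.squared, slope = stats::coef(lmfit)[2])
  }, c(r2 = 0, slope = 0)))
  fit <- data.frame(power = candidate_powers, r2 = fit[, "r2"],
                    slope = fit[, "slope"])
  ok <- fit$r2 >= r2_cut & fit$slope < 0
  if (any(ok)) {
    power <- fit$power[which(ok)[1]]
  } else {
    warning("no candidate power reached scale-free R^2 >= ", r2_cut,
            "; using default 12")
    power <- 12L
  }
  list(power = as.integer(power), fit = fit)
}

## default static cut height: scan a quantile grid of merge heights and
## take the height yielding the most clusters of at least min_size genes
## (ties: more genes assigned, then the lower height). Deterministic, and
## scale-free across noise levels, unlike any fixed constant.
.scan_cut_height <- function(hc, min_size) {
  grid <- unique(stats::quantile(hc$height, seq(0.5, 0.999,
                                                length.out = 120)))
  cls <- stats::cutree(hc, h = grid)
  if (is.null(dim(cls))) cls <- matrix(cls, ncol = 1)
  nbig <- apply(cls, 2, function(cl) sum(table(cl) >= min_size))
  nass <- apply(cls, 2, function(cl) { s <- table(cl); sum(s[s >= min_size]) })
  grid[order(-nbig, -nass, grid)[1]]
}

#' Detect co-expression modules
#'
#' Builds a weighted correlation network (|r|^beta or signed variant), the
#' topological overlap matrix, average-linkage clusters of 1-TOM, applies a
#' static cut, drops clusters below \code{min_module_size} to the unassigned
#' label 0, merges modules with highly correlated eigengenes, and renumbers
#' modules by the ZT phase of their eigengene peak.
#'
#' @param es an \code{expression_set}.
#' @param params a \code{\link{network_params}}.
#' @return A \code{module_set}: list with \code{assignment} (named integer,
#'   0 = unassigned), \code{eigengenes} (modules x samples, rows
#'   standardized), \code{design}, \code{phase} (ZT hours of eigengene peak
#'   per module), \code{params}.
#' @export
detect_modules <- function(es, params = network_params()) {
  mat <- es$matrix
  rowsd <- apply(mat, 1, stats::sd)
  if (any(rowsd == 0)) {
    warning(sum(rowsd == 0), " constant gene row(s) dropped")
    mat <- mat[rowsd > 0, , drop = FALSE]
  }
  if (nrow(mat) < 2 * params$min_module_size)
    stop("too few variable genes for module detection")
  corr <- stats::cor(t(mat))
  adj <- .adjacency(corr, params$soft_power, params$signed)
  tom <- tom_similarity(adj)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  h <- params$cut_height %||% .scan_cut_height(hc, params$min_module_size)
  cl <- stats::cutree(hc, h = h)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= params$min_module_size])
  assignment <- ifelse(cl %in% keep, cl, 0L)
  names(assignment) <- rownames(mat)
  if (!any(assignment > 0))
    stop("no cluster reached min_module_size; lower min_module_size or set cut_height")
  assignment <- .relabel_dense(assignment)
  eg <- module_eigengenes(expression_set(mat, es$design, es$norm_factors),
                          assignment)
  merged <- .merge_close_modules(assignment, eg, params$merge_corr)
  if (merged$changed)
    eg <- module_eigengenes(expression_set(mat, es$design, es$norm_factors),
                            merged$assignment)
  assignment <- merged$assignment
  ms <- .order_by_phase(assignment, eg, es$design)
  structure(list(assignment = ms$assignment, eigengenes = ms$eigengenes,
                 design = es$design, phase = ms$phase, params = params),
            class = "module_set")
}

.relabel_dense <- function(assignment) {
  labs <- sort(unique(assignment[assignment > 0]))
  map <- stats::setNames(seq_along(labs), labs)
  out <- assignment
  out[assignment > 0] <- map[as.character(assignment[assignment > 0])]
  out
}

## merge modules whose eigengene correlation exceeds merge_corr
.merge_close_modules <- function(assignment, eigengenes, merge_corr) {
  if (nrow(eigengenes) < 2 || merge_corr >= 1)
    return(list(assignment = assignment, changed = FALSE))
  ec <- stats::cor(t(eigengenes))
  hc <- stats::hclust(stats::as.dist(1 - ec), method = "average")
  grp <- stats::cutree(hc, h = 1 - merge_corr)
  if (length(unique(grp)) == nrow(eigengenes))
    return(list(assignment = assignment, changed = FALSE))
  mod_ids <- as.integer(sub("^M", "", rownames(eigengenes)))
  map <- stats::setNames(grp, mod_ids)
  out <- assignment
  out[assignment > 0] <- map[as.character(assignment[assignment > 0])]
  list(assignment = .relabel_dense(out), changed = TRUE)
}

## phase of a module = ZT time (mod 24) of its eigengene maximum on the
## mean over replicates/treatments; ties broken by the earlier ZT
.module_phase <- function(eigengene, design, period = 24) {
  tm <- tapply(eigengene, design$time, mean)
  tt <- as.numeric(names(tm))
  peak <- tt[which.max(tm)]
  peak %% period
}

.order_by_phase <- function(assignment, eigengenes, design, period = 24) {
  phase <- apply(eigengenes, 1, .module_phase, design = design, period = period)
  ids <- as.integer(sub("^M", "", rownames(eigengenes)))
  ord <- order(phase, ids)
  relabel <- stats::setNames(seq_along(ord), ids[ord])
  out <- assignment
  out[assignment > 0] <- relabel[as.character(assignment[assignment > 0])]
  eg <- eigengenes[ord, , drop = FALSE]
  rownames(eg) <- sprintf("M%02d", seq_len(nrow(eg)))
  list(assignment = out, eigengenes = eg,
       phase = stats::setNames(phase[ord], rownames(eg)))
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular direction of the
#' row-standardized member submatrix, standardized to zero mean and unit
#' variance across samples, with sign oriented so that the mean correlation
#' with member genes is non-negative.
#'
#' @param es an \code{expression_set}.
#' @param assignment named integer vector, gene -> module (0 = unassigned).
#' @return matrix modules x samples with rownames \code{M01, M02, ...}.
#' @export
module_eigengenes <- function(es, assignment) {
  mods <- sort(unique(assignment[assignment > 0]))
  if (!length(mods)) stop("no assigned modules")
  out <- matrix(NA_real_, length(mods), ncol(es$matrix),
                dimnames = list(sprintf("M%02d", mods), colnames(es$matrix)))
  for (i in seq_along(mods)) {
    m <- mods[i]
    genes <- names(assignment)[assignment == m]
    if (length(genes) < 2) stop("module ", m, " has fewer than 2 genes")
    x <- es$matrix[genes, , drop = FALSE]
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) stop("module ", m, " contains constant gene(s)")
    xs <- t(scale(t(x)))
    sv <- svd(xs, nu = 0, nv = 1)
    if (sv$d[1] <= 0) stop("module ", m, " is singular")
    e <- drop(sv$v[, 1])
    e <- drop(scale(e))
    if (mean(stats::cor(t(x), e)) < 0) e <- -e
    out[i, ] <- e
  }
  out
}

#' Module-membership (kME) encoding
#'
#' kME of gene g to module m within a time course is the Pearson correlation
#' between the gene's expression and the module eigengene over the samples
#' of that (treatment, replicate) course. The full set of kMEs encodes each
#' gene's expression pattern numerically.
#'
#' @param es an \code{expression_set}.
#' @param eigengenes modules x samples matrix aligned with \code{es}.
#' @param scope design columns defining a course (default
#'   \code{c("treatment","replicate")}).
#' @return A \code{kme_encoding}: list with \code{values} (3-d array genes x
#'   modules x courses), \code{courses} (data.frame of course metadata).
#' @export
compute_kme <- function(es, eigengenes, scope = c("treatment", "replicate")) {
  if (!identical(colnames(eigengenes), colnames(es$matrix)))
    stop("eigengene columns must align with expression samples")
  d <- es$design
  key <- interaction(d[scope], sep = ".", drop = TRUE)
  courses <- levels(key)
  arr <- array(NA_real_,
               dim = c(nrow(es$matrix), nrow(eigengenes), length(courses)),
               dimnames = list(rownames(es$matrix), rownames(eigengenes),
                               courses))
  for (ci in seq_along(courses)) {
    cols <- d$sample[key == courses[ci]]
    x <- es$matrix[, cols, drop = FALSE]
    e <- eigengenes[, cols, drop = FALSE]
    rowsd <- apply(x, 1, stats::sd)
    const <- rowsd == 0
    if (any(const))
      warning(sum(const), " constant course profile(s) in ", courses[ci],
              "; kME set to NA")
    arr[!const, , ci] <- stats::cor(t(x[!const, , drop = FALSE]), t(e))
  }
  meta <- unique(d[scope])
  meta$course <- as.character(interaction(meta, sep = ".", drop = TRUE))
  meta <- meta[match(courses, meta$course), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = arr, courses = meta, scope = scope),
            class = "kme_encoding")
}

#' Module overlap between two module sets
#'
#' One row per pair of modules sharing at least one gene: number of common
#' genes plus the Pearson correlation of the two eigengenes on the shared
#' ZT time grid (each eigengene first averaged within time).
#'
#' @param msA,msB \code{module_set} objects.
#' @param shared_genes optional gene universe restriction.
#' @return data.frame (moduleA, moduleB, n_common, eigengene_corr).
#' @export
module_overlap_stats <- function(msA, msB, shared_genes = NULL) {
  gA <- names(msA$assignment)[msA$assignment > 0]
  gB <- names(msB$assignment)[msB$assignment > 0]
  univ <- intersect(names(msA$assignment), names(msB$assignment))
  if (!is.null(shared_genes)) univ <- intersect(univ, shared_genes)
  if (!length(univ)) stop("gene universes are disjoint")
  a <- msA$assignment[intersect(gA, univ)]
  b <- msB$assignment[intersect(gB, univ)]
  common <- intersect(names(a), names(b))
  tab <- table(moduleA = a[common], moduleB = b[common])
  profA <- .time_profile(msA)
  profB <- .time_profile(msB)
  times <- intersect(colnames(profA), colnames(profB))
  if (length(times) < 3) stop("fewer than 3 shared ZT times")
  rows <- which(tab >= 1, arr.ind = TRUE)
  out <- data.frame(
    moduleA = as.integer(rownames(tab)[rows[, 1]]),
    moduleB = as.integer(colnames(tab)[rows[, 2]]),
    n_common = as.integer(tab[rows]))
  out$eigengene_corr <- mapply(function(i, j)
    stats::cor(profA[sprintf("M%02d", i), times],
               profB[sprintf("M%02d", j), times]),
    out$moduleA, out$moduleB)
  out[order(out$moduleA, out$moduleB), , drop = FALSE]
}

## eigengene averaged within ZT time -> modules x times matrix
.time_profile <- function(ms) {
  tt <- ms$design$time
  ut <- sort(unique(tt))
  prof <- t(vapply(seq_len(nrow(ms$eigengenes)), function(i)
    vapply(ut, function(z) mean(ms$eigengenes[i, tt == z]), 0), numeric(length(ut))))
  dimnames(prof) <- list(rownames(ms$eigengenes), as.character(ut))
  prof
}

#' Hypergeometric over/under enrichment of a flagged gene set in a module
#'
#' With k = |module intersect flagged| drawn from
#' Hypergeometric(N = |universe|, K = |flagged|, n = |module|):
#' p_over = P[X >= k], p_under = P[X <= k]. The signed score is
#' -log10(p_over) when k exceeds its expectation nK/N (enrichment, positive)
#' and +log10(p_under)... i.e. minus the depletion score otherwise.
#'
#' @param module_genes,flagged,universe character vectors of gene ids;
#'   \code{module_genes} and \code{flagged} must lie inside \code{universe}.
#' @return list with \code{k, n, K, N, p_over, p_under, signed_log10}.
#' @export
hypergeometric_enrichment <- function(module_genes, flagged, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  module_genes <- unique(module_genes); flagged <- unique(flagged)
  if (length(setdiff(module_genes, universe)) ||
      length(setdiff(flagged, universe)))
    stop("module_genes and flagged must be subsets of universe")
  N <- length(universe); K <- length(flagged); n <- length(module_genes)
  k <- length(intersect(module_genes, flagged))
  p_over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_under <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  signed <- if (k > n * K / N) -log10(p_over) else log10(p_under)
  list(k = k, n = n, K = K, N = N, p_over = p_over, p_under = p_under,
       signed_log10 = signed)
}
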