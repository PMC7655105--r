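# Independent oracles, coded straight from the published formulas and kept
# separate from the package implementation paths they check.

## ---- weighted trimmed-mean-of-M-values normalization factors ----------
## Reference column: upper quartile of counts/libsize closest to the mean
## upper quartile. M-trim 30%, A-trim 5%, inverse-asymptotic-variance
## weights; factors rescaled to geometric mean 1.
tmm_oracle <- function(counts) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(obs, ref_col) {
    nO <- sum(obs); nR <- sum(ref_col)
    keep <- obs > 0 & ref_col > 0
    obs <- obs[keep]; refc <- ref_col[keep]
    M <- log2((obs / nO) / (refc / nR))
    A <- (log2(obs / nO) + log2(refc / nR)) / 2
    w <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    keep2 <- abs(A) < 1e10
    M <- M[keep2]; A <- A[keep2]; w <- w[keep2]
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    f <- sum(M[sel] / w[sel]) / sum(1 / w[sel])
    if (!is.finite(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(counts)), function(j)
    one_factor(counts[, j], counts[, ref]), 0)
  f / exp(mean(log(f)))
}

## ---- closed-form empirical-Bayes moderated t -------------------------
## Per-gene OLS, then (d0, s0^2) by moment-matching log s^2 to a scaled
## log-F via digamma/trigamma inversion; moderated variance
## (d0 s0^2 + d s^2)/(d0 + d).
trigamma_inverse_oracle <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-12) break
  }
  y
}

eb_moderated_t_oracle <- function(response, design, contrast) {
  n <- ncol(response); p <- ncol(design)
  XtXi <- solve(crossprod(design))
  beta <- response %*% design %*% XtXi
  fitted <- beta %*% t(design)
  d <- n - p
  s2 <- rowSums((response - fitted)^2) / d
  est <- drop(beta %*% contrast)
  se_unscaled <- sqrt(drop(t(contrast) %*% XtXi %*% contrast))
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse_oracle(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  s2_post <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else rep(s02, length(s2))
  list(t = est / (sqrt(s2_post) * se_unscaled), d0 = d0, s02 = s02,
       s2 = s2, s2_post = s2_post)
}

## ---- exhaustive hypergeometric enumeration ---------------------------
## Enumerates all size-n subsets of a universe of size N with K flagged.
hyper_enum_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  ks <- colSums(draws <= K)
  c(p_over = mean(ks >= k), p_under = mean(ks <= k))
}

## ---- AUROC by exhaustive pair counting -------------------------------
auroc_pairs_oracle <- function(scores, labels) {
  pos <- which(as.logical(labels)); neg <- which(!as.logical(labels))
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

## ---- BH step-up by hand ----------------------------------------------
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n); out[o] <- q
  out
}

## ---- brute-force nearest same-strand gene ----------------------------
## Same signed-distance convention as the package documents: negative when
## the CNS lies before the gene, positive after, 0 on overlap; all ties.
nearest_gene_brute <- function(cns, genes) {
  out <- list()
  for (i in seq_len(nrow(cns))) {
    c0 <- cns[i, ]
    best_d <- Inf; rows <- list()
    for (j in seq_len(nrow(genes))) {
      g0 <- genes[j, ]
      if (g0$chrom != c0$chrom || g0$strand != c0$strand) next
      d <- if (c0$end <= g0$start) -(g0$start - c0$end + 1)
           else if (c0$start >= g0$end) c0$start - g0$end + 1
           else 0
      if (abs(d) < best_d) { best_d <- abs(d); rows <- list() }
      if (abs(d) == best_d)
        rows[[length(rows) + 1]] <- data.frame(cns = c0$name, gene = g0$name,
                                               distance = d)
    }
    if (length(rows)) out[[length(out) + 1]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---- rule-by-rule CNS hit filter -------------------------------------
cns_filter_brute <- function(hits, cap, bitscore_min = 28.2, min_qcovs = 60) {
  step1 <- hits[hits$bitscore > bitscore_min, , drop = FALSE]
  step2 <- step1[step1$qcovs >= min_qcovs, , drop = FALSE]
  keep <- rep(TRUE, nrow(step2))
  for (q in unique(step2$qaccver))
    if (sum(step2$qaccver == q) > cap) keep[step2$qaccver == q] <- FALSE
  out <- step2[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
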