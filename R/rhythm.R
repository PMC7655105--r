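#' Harmonic (cosinor) rhythm fit
#'
#' Least-squares fit of \eqn{y = m + a\cos(2\pi t/\tau) + b\sin(2\pi t/\tau)}
#' per gene, giving amplitude \eqn{A = \sqrt{a^2+b^2}}, peak phase
#' \eqn{\varphi} in [0, tau) hours, the fit R^2, and the F-test p-value of
#' the joint (a, b) rhythm term, BH-adjusted across genes.
#'
#' @param values numeric vector (one series) or genes x timepoints matrix.
#' @param times numeric sampling times in hours; needs >= 6 points spanning
#'   at least one period.
#' @param period rhythm period tau in hours (default 24).
#' @return data.frame (gene, amplitude, phase, mesor, R2, p, q, cycling)
#'   where \code{cycling} flags q <= 0.01.
#' @export
harmonic_fit <- function(values, times, period = 24) {
  y <- if (is.null(dim(values))) matrix(values, nrow = 1,
                                        dimnames = list("series1", NULL))
       else as.matrix(values)
  if (ncol(y) != length(times)) stop("one time per column required")
  if (length(times) < 6 || diff(range(times)) < period)
    stop("need >= 6 timepoints spanning at least one period")
  w <- 2 * pi * times / period
  X <- cbind(1, cos(w), sin(w))
  if (qr(X)$rank < 3) stop("degenerate time grid: harmonic design is singular")
  n <- length(times)
  coef <- t(solve(crossprod(X), crossprod(X, t(y))))
  fitted <- coef %*% t(X)
  rss <- rowSums((y - fitted)^2)
  tss <- rowSums((y - rowMeans(y))^2)
  a <- coef[, 2]; b <- coef[, 3]
  amplitude <- sqrt(a^2 + b^2)
  phase <- (atan2(b, a) * period / (2 * pi)) %% period
  ## numerical wrap: a phase indistinguishable from tau collapses to 0
  phase[period - phase < 1e-9] <- 0
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  df2 <- n - 3
  fstat <- ((tss - rss) / 2) / (rss / df2)
  p <- ifelse(rss > 0, stats::pf(fstat, 2, df2, lower.tail = FALSE),
              ifelse(tss > 0, 0, 1))
  adj <- bh_adjust(p, alpha = 0.01)
  data.frame(gene = rownames(y), amplitude = amplitude, phase = phase,
             mesor = coef[, 1], R2 = r2, p = p, q = adj$q,
             cycling = adj$selected, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Circular phase difference
#'
#' Wraps \code{phi1 - phi2} into \eqn{(-\tau/2, \tau/2]}; antiphase pairs
#' return exactly +tau/2.
#'
#' @param phi1,phi2 phases in hours, in [0, period).
#' @param period hours per cycle (default 24).
#' @return numeric vector of wrapped differences.
#' @export
phase_difference <- function(phi1, phi2, period = 24) {
  d <- (phi1 - phi2) %% period
  ifelse(d > period / 2, d - period, d)
}

#' Benjamini-Hochberg adjustment with selection
#'
#' Step-up adjusted p-values (via \code{stats::p.adjust}) and the genes
#' selected at the given FDR level.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param alpha FDR level for selection (default 0.01).
#' @return list with \code{q} (adjusted values) and \code{selected}
#'   (logical, \code{q <= alpha}).
#' @export
bh_adjust <- function(p, alpha = 0.01) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, selected = q <= alpha)
}

#' Adapter for externally computed rhythm p-values
#'
#' Reads a 2-column (gene, p) TSV produced by an external rhythm detector
#' and applies the BH selection, so published nonparametric rhythm calls
#' can replace the built-in cosinor fit.
#'
#' @param file path to a 2-column TSV (gene, p), no header required.
#' @param alpha BH FDR level (default 0.01).
#' @return data.frame (gene, p, q, cycling).
#' @export
read_external_rhythm_calls <- function(file, alpha = 0.01) {
  d <- utils::read.table(file, sep = "\t", header = FALSE,
                         col.names = c("gene", "p"),
                         stringsAsFactors = FALSE)
  adj <- bh_adjust(d$p, alpha = alpha)
  data.frame(gene = d$gene, p = d$p, q = adj$q, cycling = adj$selected,
             stringsAsFactors = FALSE)
}
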