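#' Construct a validated count table
#'
#' Bundles a genes x samples matrix of raw counts with per-gene lengths.
#' Gene and sample identifiers must be unique, counts finite and
#' non-negative, lengths at least 1 bp.
#'
#' @param counts integer-like matrix (genes x samples) with rownames
#'   (gene ids) and colnames (sample ids).
#' @param gene_lengths_bp numeric vector of gene lengths in bp, named by
#'   gene id or in row order of \code{counts}.
#' @return An object of class \code{count_table} with elements
#'   \code{counts} and \code{gene_lengths_bp}.
#' @export
count_table <- function(counts, gene_lengths_bp) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0")
  if (!is.null(names(gene_lengths_bp))) {
    missing <- setdiff(rownames(counts), names(gene_lengths_bp))
    if (length(missing))
      stop("gene lengths missing for: ", paste(utils::head(missing, 5), collapse = ", "))
    gene_lengths_bp <- gene_lengths_bp[rownames(counts)]
  }
  if (length(gene_lengths_bp) != nrow(counts))
    stop("one gene length per gene required")
  if (any(!is.finite(gene_lengths_bp)) || any(gene_lengths_bp < 1))
    stop("gene lengths must be >= 1 bp")
  structure(list(counts = counts,
                 gene_lengths_bp = stats::setNames(as.numeric(gene_lengths_bp),
                                                   rownames(counts))),
            class = "count_table")
}

#' Construct a validated sample design table
#'
#' One row per sample: treatment, time in hours (ZT convention), replicate,
#' plus optional categorical covariates. Every \code{(treatment, replicate)}
#' pair defines one time course.
#'
#' @param sample data.frame or vector of sample ids, or a data.frame with
#'   columns \code{sample}, \code{treatment}, \code{time}, \code{replicate}.
#' @param treatment,time,replicate vectors parallel to \code{sample} when
#'   \code{sample} is a vector of ids.
#' @param covariates optional data.frame of extra categorical columns.
#' @return data.frame of class \code{sample_design}.
#' @export
sample_design <- function(sample, treatment = NULL, time = NULL,
                          replicate = NULL, covariates = NULL) {
  if (is.data.frame(sample)) {
    d <- sample
    need <- c("sample", "treatment", "time", "replicate")
    miss <- setdiff(need, names(d))
    if (length(miss)) stop("design missing columns: ", paste(miss, collapse = ", "))
  } else {
    d <- data.frame(sample = as.character(sample),
                    treatment = as.character(treatment),
                    time = as.numeric(time),
                    replicate = as.character(replicate),
                    stringsAsFactors = FALSE)
    if (!is.null(covariates)) d <- cbind(d, covariates)
  }
  d$sample <- as.character(d$sample)
  d$treatment <- as.character(d$treatment)
  d$replicate <- as.character(d$replicate)
  d$time <- as.numeric(d$time)
  if (anyDuplicated(d$sample)) stop("duplicate sample ids in design")
  if (any(!is.finite(d$time))) stop("non-finite time values in design")
  class(d) <- c("sample_design", "data.frame")
  d
}

## id of the (treatment, replicate) course each design row belongs to
course_id <- function(design) paste(design$treatment, design$replicate, sep = ".")

#' TMM-normalized log2 FPKM expression set
#'
#' Computes trimmed-mean-of-M-values (TMM) normalization factors
#' (30\% M-trim, 5\% A-trim, reference column chosen by upper-quartile
#' proximity to the mean upper quartile, factors rescaled to geometric mean
#' 1) and converts counts to log2 FPKM:
#' \deqn{\log_2\frac{c_{gs} + p}{(N_s f_s/10^6)(L_g/10^3)}}
#' where \eqn{p} is an unscaled prior count, \eqn{N_s f_s} the effective
#' library size and \eqn{L_g} the annotated gene length.
#'
#' @param ct a \code{\link{count_table}}.
#' @param design a \code{\link{sample_design}} covering all samples.
#' @param prior_count positive prior count added before the log (default 0.1).
#' @return An \code{expression_set}: list with \code{matrix} (genes x samples,
#'   log2 scale), \code{design}, \code{norm_factors}, \code{prior_count}.
#' @export
normalize_counts <- function(ct, design, prior_count = 0.1) {
  if (!inherits(ct, "count_table")) stop("'ct' must be a count_table")
  if (!is.numeric(prior_count) || prior_count <= 0)
    stop("prior_count must be > 0")
  counts <- ct$counts
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size for sample(s): ",
                          paste(colnames(counts)[lib <= 0], collapse = ", "))
  if (!setequal(design$sample, colnames(counts)) ||
      length(design$sample) != ncol(counts))
    stop("design samples must match count columns one-to-one")
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = 0.3, sumTrim = 0.05)
  eff_lib <- lib * f
  len_kb <- ct$gene_lengths_bp / 1e3
  denom <- outer(len_kb, eff_lib / 1e6)
  mat <- log2((counts + prior_count) / denom)
  es <- list(matrix = mat, design = design,
             norm_factors = stats::setNames(f, colnames(counts)),
             prior_count = prior_count)
  class(es) <- "expression_set"
  es
}

#' Build an expression set from an existing log-scale matrix
#'
#' For data already on a log2 (or otherwise variance-stabilized) scale.
#'
#' @param mat numeric genes x samples matrix, finite values.
#' @param design a \code{\link{sample_design}} matching \code{colnames(mat)}.
#' @param norm_factors optional per-sample factors (default 1).
#' @return An \code{expression_set}.
#' @export
expression_set <- function(mat, design, norm_factors = NULL) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("expression matrix must be finite")
  if (!setequal(design$sample, colnames(mat)) ||
      length(design$sample) != ncol(mat))
    stop("design samples must match matrix columns one-to-one")
  design <- design[match(colnames(mat), design$sample), , drop = FALSE]
  nf <- norm_factors %||% stats::setNames(rep(1, ncol(mat)), colnames(mat))
  structure(list(matrix = mat, design = design, norm_factors = nf,
                 prior_count = NA_real_),
            class = "expression_set")
}

#' Impute a missing sample from flanking timepoints of the other replicate
#'
#' Replaces the column for \code{(treatment, time, replicate)} with the mean
#' of the two flanking timepoints of the other replicate in the same
#' treatment, the handling used for dropped outlier libraries in paired
#' replicate time courses.
#'
#' @param es an \code{expression_set}.
#' @param treatment,time,replicate identify the course position to impute.
#' @return The expression set with the named column replaced.
#' @export
impute_neighbor_mean <- function(es, treatment, time, replicate) {
  d <- es$design
  idx <- which(d$treatment == treatment & d$time == time & d$replicate == replicate)
  if (length(idx) != 1L) stop("target sample not uniquely identified")
  other <- d[d$treatment == treatment & d$replicate != replicate, , drop = FALSE]
  below <- other[other$time < time, , drop = FALSE]
  above <- other[other$time > time, , drop = FALSE]
  if (!nrow(below) || !nrow(above))
    stop("no flanking timepoints available in the other replicate")
  lo <- below$sample[which.max(below$time)]
  hi <- above$sample[which.min(above$time)]
  es$matrix[, d$sample[idx]] <- (es$matrix[, lo] + es$matrix[, hi]) / 2
  es
}

#' Per-group median expression profile
#'
#' Collapses samples to their median log2 value within groups defined by
#' design columns, e.g. \code{c("treatment", "replicate")} gives one median
#' per time course.
#'
#' @param es an \code{expression_set}.
#' @param group_by character vector of design column names.
#' @return numeric matrix genes x groups; group names join the key values
#'   with ".".
#' @export
median_profile <- function(es, group_by = c("treatment", "replicate")) {
  d <- es$design
  bad <- setdiff(group_by, names(d))
  if (length(bad)) stop("unknown design key(s): ", paste(bad, collapse = ", "))
  key <- interaction(d[group_by], sep = ".", drop = TRUE)
  groups <- levels(key)
  out <- vapply(groups, function(g) {
    cols <- d$sample[key == g]
    if (!length(cols)) stop("empty group: ", g)
    apply(es$matrix[, cols, drop = FALSE], 1, stats::median)
  }, numeric(nrow(es$matrix)))
  out <- matrix(out, nrow = nrow(es$matrix),
                dimnames = list(rownames(es$matrix), groups))
  out
}

#' Read a count table plus gene lengths from delimited files
#'
#' @param counts_file TSV/CSV, first column gene id, header of sample ids.
#' @param lengths_file 2-column TSV/CSV: gene id, length in bp.
#' @param sep field separator ("\\t" default; "," autodetected by extension).
#' @return a \code{\link{count_table}}.
#' @export
read_count_table <- function(counts_file, lengths_file, sep = NULL) {
  pick_sep <- function(f) if (grepl("\\.csv$", f, ignore.case = TRUE)) "," else "\t"
  s1 <- sep %||% pick_sep(counts_file)
  cm <- utils::read.table(counts_file, sep = s1, header = TRUE,
                          row.names = 1, check.names = FALSE)
  s2 <- sep %||% pick_sep(lengths_file)
  lt <- utils::read.table(lengths_file, sep = s2, header = FALSE,
                          col.names = c("gene", "length"))
  count_table(as.matrix(cm), stats::setNames(lt$length, lt$gene))
}

#' Read a sample design CSV
#'
#' Expects columns \code{sample,treatment,time,replicate} plus any extra
#' covariate columns.
#'
#' @param file path to a CSV file.
#' @return a \code{\link{sample_design}}.
#' @export
read_sample_design <- function(file) {
  sample_design(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' Write an expression set as TSV plus a JSON sidecar of norm factors
#'
#' @param es an \code{expression_set}.
#' @param file output TSV path; the sidecar is \code{<file>.json}.
#' @return invisibly, the two paths written.
#' @export
write_expression_set <- function(es, file) {
  df <- data.frame(gene = rownames(es$matrix), es$matrix,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- paste0(file, ".json")
  jsonlite::write_json(list(norm_factors = as.list(es$norm_factors),
                            prior_count = es$prior_count),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(file, side))
}
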