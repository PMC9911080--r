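# Quantification: per-family count matrices by small-RNA length class,
# reads-per-million normalization, and a precision-weighted (voom-style)
# linear model for differential abundance against a resistance covariate.

#' Construct a count matrix
#'
#' @param counts integer matrix, families in rows, libraries in columns.
#' @param library_sizes named positive integer vector per library; must be
#'   at least each library's column sum.
#' @param meta data frame with one row per library: columns `library`,
#'   `line`, `replicate`, and optionally `resistance`.
#' @param length_window the read-length window `[lo, hi]` (nt) the counts
#'   were restricted to.
#' @param class_label label for the length class (e.g. `"piRNA"`).
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(counts, library_sizes, meta,
                         length_window = c(23, 31), class_label = "piRNA") {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), !is.null(colnames(counts)),
            !is.null(rownames(counts)))
  if (is.null(names(library_sizes)))
    names(library_sizes) <- colnames(counts)
  library_sizes <- library_sizes[colnames(counts)]
  if (any(is.na(library_sizes)) || any(library_sizes <= 0))
    stop("library_sizes must be positive and cover every library")
  if (any(colSums(counts) > library_sizes))
    stop("library_sizes smaller than column sums")
  meta <- meta[match(colnames(counts), meta$library), , drop = FALSE]
  if (anyNA(meta$library)) stop("metadata missing for some libraries")
  structure(list(counts = counts, library_sizes = library_sizes,
                 meta = meta, length_window = length_window,
                 class_label = class_label),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d families x %d libraries (%s, %g-%g nt)\n",
              nrow(x$counts), ncol(x$counts), x$class_label,
              x$length_window[1], x$length_window[2]))
  invisible(x)
}

#' Count alignments by family within a read-length window
#'
#' One increment per aligned read whose length falls in `[lo, hi]`, grouped
#' by family and library.
#'
#' @param alignments alignment data frame with a `library` column (a single
#'   implicit library is assumed if absent).
#' @param length_window inclusive nt window `c(lo, hi)`; the conventional
#'   piRNA window is 23-31 nt and the siRNA window 20-22 nt.
#' @param library_sizes named per-library sizes (reads surviving trimming,
#'   the length floor, and miRNA subtraction). Defaults to per-library
#'   alignment totals (all lengths) when not supplied.
#' @param meta per-library metadata data frame (see [count_matrix()]);
#'   minimal metadata is synthesized when absent.
#' @param families optional family universe (rows), so that families with
#'   zero counts are retained.
#' @param class_label label stored on the result.
#' @return a [count_matrix()].
#' @export
count_by_family <- function(alignments, length_window = c(23, 31),
                            library_sizes = NULL, meta = NULL,
                            families = NULL, class_label = "piRNA") {
  stopifnot(length_window[1] <= length_window[2])
  aln <- alignments
  if (is.null(aln$library)) aln$library <- "lib1"
  libs <- if (!is.null(meta)) meta$library else
    sort_c(unique(aln$library))
  if (is.null(families))
    families <- sort_c(unique(aln$family))
  keep <- aln$read_length >= length_window[1] &
    aln$read_length <= length_window[2]
  sub <- aln[keep, , drop = FALSE]
  counts <- matrix(0L, length(families), length(libs),
                   dimnames = list(families, libs))
  if (nrow(sub)) {
    tab <- table(factor(sub$family, levels = families),
                 factor(sub$library, levels = libs))
    counts[] <- as.integer(tab)
  }
  if (is.null(library_sizes)) {
    tot <- table(factor(aln$library, levels = libs))
    library_sizes <- stats::setNames(pmax(as.integer(tot), 1L), libs)
  }
  if (is.null(meta))
    meta <- data.frame(library = libs, line = libs, replicate = 1L,
                       stringsAsFactors = FALSE)
  count_matrix(counts, library_sizes, meta, length_window, class_label)
}

#' Reads-per-million normalization
#'
#' `RPM = count / library_size * 1e6`. With `average_replicates = TRUE`
#' replicate columns of the same line are averaged (mean of the replicate
#' RPM values), giving one column per line.
#'
#' @param x a [count_matrix()].
#' @param average_replicates collapse replicates to per-line means.
#' @return numeric matrix of RPM values.
#' @export
normalize_rpm <- function(x, average_replicates = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  if (any(x$library_sizes <= 0)) stop("library sizes must be positive")
  rpm <- sweep(x$counts, 2, x$library_sizes, "/") * 1e6
  if (average_replicates) {
    lines <- unique(x$meta$line)
    rpm <- vapply(lines, function(ln)
      rowMeans(rpm[, x$meta$line == ln, drop = FALSE]),
      numeric(nrow(rpm)))
    colnames(rpm) <- lines
  }
  rpm
}

#' Precision weights from the mean-variance trend (voom-style)
#'
#' Computes `log2cpm = log2((count + 0.5) / (library_size + 1) * 1e6)`, fits
#' a per-family linear model on the covariate, smooths the square root of
#' the residual standard deviation against the mean log2-CPM with lowess
#' (span 0.5), and assigns each observation the predicted value at its
#' fitted log2-CPM raised to the power -4 as a precision weight. This is a
#' simplified voom: the downstream tests use ordinary (not moderated)
#' t-statistics.
#'
#' @param x a [count_matrix()].
#' @param covariate per-library numeric covariate (defaults to
#'   `meta$resistance`).
#' @return list with `logcpm` and `weights` matrices (families x
#'   libraries), the `covariate`, and the smoothed trend; class
#'   `voom_fit`. Weights are strictly positive and finite.
#' @export
voom_fit <- function(x, covariate = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(covariate)) covariate <- x$meta$resistance
  n <- ncol(x$counts)
  if (n < 3) stop("need at least 3 libraries to fit the model")
  logcpm <- log2(sweep(x$counts + 0.5, 2, x$library_sizes + 1, "/") * 1e6)
  X <- cbind(1, covariate)
  qrX <- qr(X)
  if (qrX$rank < 2) stop("covariate is constant: design is singular")
  B <- t(qr.coef(qrX, t(logcpm)))          # families x 2
  fitted <- B %*% t(X)
  res <- logcpm - fitted
  sdev <- sqrt(rowSums(res^2) / (n - 2))
  sqrt_sd <- pmax(sqrt(sdev), 1e-3)        # floor keeps weights finite
  mean_lc <- rowMeans(logcpm)
  if (nrow(logcpm) >= 4 && stats::var(mean_lc) > 0) {
    lo <- lowess(mean_lc, sqrt_sd, f = 0.5)
    pred <- approx(lo$x, lo$y, xout = as.vector(fitted), rule = 2,
                   ties = mean)$y
  } else {
    pred <- rep(sqrt_sd, n)                # too few families for a trend
  }
  w <- matrix(pmax(pred, 1e-3)^-4, nrow(logcpm), n,
              dimnames = dimnames(logcpm))
  structure(list(logcpm = logcpm, weights = w, covariate = covariate,
                 trend = if (exists("lo", inherits = FALSE)) lo else NULL),
            class = "voom_fit")
}

#' Differential abundance by precision-weighted least squares
#'
#' Per family, regresses log2-CPM on `(intercept, covariate)` by weighted
#' least squares; `t = coefficient / SE` with `n - 2` degrees of freedom,
#' two-sided p, and Benjamini-Hochberg adjustment across families.
#'
#' @param logcpm matrix (families x libraries) or a `voom_fit`.
#' @param weights positive weight matrix of the same shape (ignored when a
#'   `voom_fit` is given).
#' @param covariate per-library numeric covariate (non-constant).
#' @return data frame `family`, `effect` (log2 units per covariate unit),
#'   `t`, `p`, `p_adj`, sorted by `p`; class `differential_result`.
#' @export
differential_abundance <- function(logcpm, weights = NULL, covariate = NULL) {
  if (inherits(logcpm, "voom_fit")) {
    fit <- logcpm
    logcpm <- fit$logcpm
    weights <- fit$weights
    if (is.null(covariate)) covariate <- fit$covariate
  }
  if (is.null(weights)) weights <- matrix(1, nrow(logcpm), ncol(logcpm))
  n <- ncol(logcpm)
  if (n < 3) stop("need at least 3 libraries")
  if (stats::var(covariate) == 0) stop("covariate is constant")
  x <- covariate
  # weighted simple regression, vectorized across families
  sw <- rowSums(weights)
  xbar <- rowSums(weights * rep(x, each = nrow(weights))) / sw
  ybar <- rowSums(weights * logcpm) / sw
  xc <- outer(rep(1, nrow(weights)), x) - xbar
  yc <- logcpm - ybar
  sxx <- rowSums(weights * xc^2)
  beta <- rowSums(weights * xc * yc) / sxx
  rss <- rowSums(weights * (yc - beta * xc)^2)
  s2 <- rss / (n - 2)
  se <- sqrt(s2 / sxx)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df = n - 2)
  out <- data.frame(family = rownames(logcpm), effect = beta, t = tstat,
                    p = p, p_adj = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$family), ]
  rownames(out) <- NULL
  class(out) <- c("differential_result", "data.frame")
  out
}
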