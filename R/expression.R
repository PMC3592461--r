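## Expression stage: quantile normalisation of linear probe intensities,
## median-polish summarisation to probe-set and cluster level, gene-level
## normalised intensities (GNI), Splice Index (SI) and two-group
## differential expression with Welch t-tests and Benjamini-Hochberg
## correction. The summarisation pipeline is an RMA without background
## correction: log2 -> quantile normalise -> median polish.

#' Quantile-normalize a linear intensity matrix
#'
#' Each column's sorted values are replaced by the across-column mean of
#' sorted values; ties within a column receive the mean of their target
#' quantiles, so within-column rank order is preserved and all sorted
#' columns become identical. Delegates to
#' \code{\link[limma]{normalizeQuantiles}}.
#'
#' @param mat numeric matrix, linear scale, all values > 0, >= 2 columns.
#' @return the normalized matrix, linear scale.
#' @export
quantileNormalize <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (any(mat <= 0))
    stop("quantile normalization expects positive linear intensities")
  if (ncol(mat) < 2L) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Median-polish summarization of probes into features
#'
#' For each target feature (probe set or transcript cluster) the linear
#' probes-by-samples sub-matrix is log2-transformed and decomposed by
#' Tukey median polish into overall + probe (row) + sample (column)
#' effects; the per-sample summary is overall + column effect. Iteration
#' stops after 10 sweeps or when the change drops below 1e-6. A
#' single-probe feature summarizes to that probe's log2 values.
#'
#' @param mat numeric matrix, linear scale, rownames = probe ids.
#' @param featureOf named character vector mapping probe id to feature id;
#'   probes absent from the map are ignored.
#' @param featureOrder optional character vector fixing the output row
#'   order (default: order of first appearance in \code{featureOf}).
#' @return numeric matrix, log2 scale, rows = features, columns as input.
#' @export
summarizeByFeature <- function(mat, featureOf, featureOrder = NULL) {
  stopifnot(is.matrix(mat), is.numeric(mat), !is.null(rownames(mat)))
  if (any(mat <= 0))
    stop("summarization expects positive linear intensities")
  featureOf <- featureOf[names(featureOf) %in% rownames(mat)]
  missing <- setdiff(names(featureOf), rownames(mat))
  if (length(missing))
    stop("probes absent from the matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  if (is.null(featureOrder))
    featureOrder <- unique(unname(featureOf))
  if (!all(featureOf %in% featureOrder))
    stop("featureOrder does not cover all mapped features")
  l2 <- log2(mat[names(featureOf), , drop = FALSE])
  out <- matrix(NA_real_, length(featureOrder), ncol(mat),
                dimnames = list(featureOrder, colnames(mat)))
  byFeature <- split(seq_along(featureOf), factor(featureOf, featureOrder))
  for (f in featureOrder) {
    idx <- byFeature[[f]]
    if (length(idx) == 0L)
      stop("feature without probes: ", f)
    sub <- l2[idx, , drop = FALSE]
    if (nrow(sub) == 1L) {
      out[f, ] <- sub[1L, ]
    } else {
      ## the 10-sweep cap is deliberate; hitting it is not a condition
      mp <- withCallingHandlers(
        stats::medpolish(sub, eps = 1e-6, maxiter = 10L,
                         trace.iter = FALSE, na.rm = FALSE),
        warning = function(w) {
          if (grepl("did not converge", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      out[f, ] <- mp$overall + mp$col
    }
  }
  out
}

#' Gene-level normalized intensities
#'
#' GNI of probe set p in sample s is the log2 probe-set expression minus
#' the log2 expression of the probe set's transcript cluster: the
#' exon-specific signal with the gene-level signal removed.
#'
#' @param probesetExpr log2 matrix, rows = probe sets.
#' @param clusterExpr log2 matrix, rows = clusters, same samples.
#' @param psToCluster named character vector: cluster id per probe-set id.
#' @return numeric matrix of GNI values (log2 units), rows = probe sets.
#' @export
computeGNI <- function(probesetExpr, clusterExpr, psToCluster) {
  if (!identical(colnames(probesetExpr), colnames(clusterExpr)))
    stop("probe-set and cluster matrices must share the same samples")
  ps <- rownames(probesetExpr)
  cl <- unname(psToCluster[ps])
  if (any(is.na(cl)))
    stop("probe set(s) without cluster mapping: ",
         paste(utils::head(ps[is.na(cl)], 5L), collapse = ", "))
  if (!all(cl %in% rownames(clusterExpr)))
    stop("cluster(s) missing from the cluster matrix")
  probesetExpr - clusterExpr[cl, , drop = FALSE]
}

## internal: Welch two-sample t p-value for one feature; the degenerate
## zero-variance case resolves to p = 1 for equal means, p = 0 otherwise.
welchP <- function(x, y) {
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Splice Index per probe set
#'
#' SI is the difference of mean GNI between the two groups (group 1 minus
#' group 2): the log2 fold change of exon-specific signal, flagging
#' differential exon usage. P-values come from a Welch two-sample t-test
#' on the per-sample GNI values; FDR is Benjamini-Hochberg across all
#' probe sets.
#'
#' @param gni GNI matrix from \code{\link{computeGNI}}.
#' @param design named factor from \code{\link{groupDesign}}; names must
#'   cover the matrix columns, each group with >= 2 samples.
#' @param psToCluster named character vector: cluster id per probe-set id.
#' @return a \code{data.frame} with columns \code{probeset_id},
#'   \code{cluster_id}, \code{si}, \code{p_value}, \code{fdr}.
#' @export
spliceIndex <- function(gni, design, psToCluster) {
  g <- splitSamples(gni, design)
  si <- rowMeans(gni[, g$s1, drop = FALSE]) -
    rowMeans(gni[, g$s2, drop = FALSE])
  p <- vapply(seq_len(nrow(gni)), function(i)
    welchP(gni[i, g$s1], gni[i, g$s2]), numeric(1))
  data.frame(probeset_id = rownames(gni),
             cluster_id = unname(psToCluster[rownames(gni)]),
             si = unname(si),
             p_value = p,
             fdr = stats::p.adjust(p, method = "BH"),
             row.names = NULL)
}

#' Two-group differential expression of transcript clusters
#'
#' Per cluster: log2 fold change of group means (group 1 minus group 2),
#' Welch t p-value and Benjamini-Hochberg FDR.
#'
#' @param clusterExpr log2 matrix, rows = clusters.
#' @param design named factor from \code{\link{groupDesign}}.
#' @return a \code{data.frame} with columns \code{cluster_id},
#'   \code{log2_fold_change}, \code{p_value}, \code{fdr}.
#' @export
differentialExpression <- function(clusterExpr, design) {
  g <- splitSamples(clusterExpr, design)
  fc <- rowMeans(clusterExpr[, g$s1, drop = FALSE]) -
    rowMeans(clusterExpr[, g$s2, drop = FALSE])
  p <- vapply(seq_len(nrow(clusterExpr)), function(i)
    welchP(clusterExpr[i, g$s1], clusterExpr[i, g$s2]), numeric(1))
  data.frame(cluster_id = rownames(clusterExpr),
             log2_fold_change = unname(fc),
             p_value = p,
             fdr = stats::p.adjust(p, method = "BH"),
             row.names = NULL)
}

## internal: validate the design against matrix columns; first factor
## level is group 1.
splitSamples <- function(mat, design) {
  if (!is.factor(design) || nlevels(design) != 2L)
    stop("design must be a two-level factor from groupDesign()")
  if (!all(colnames(mat) %in% names(design)))
    stop("design does not cover samples: ",
         paste(setdiff(colnames(mat), names(design)), collapse = ", "))
  d <- design[colnames(mat)]
  s1 <- names(d)[d == levels(design)[1L]]
  s2 <- names(d)[d == levels(design)[2L]]
  if (length(s1) < 2L || length(s2) < 2L)
    stop("each group needs at least two samples in the matrix")
  list(s1 = s1, s2 = s2)
}

#' Select the most variable features
#'
#' Keeps the n rows with the largest sample variance, preserving the
#' original row order among the selected (used to pick the most variable
#' lncRNAs before clustering heat maps; default n = 150).
#'
#' @param mat log2 expression matrix.
#' @param n number of rows to keep.
#' @return the row-subset matrix.
#' @export
selectTopVariance <- function(mat, n = 150L) {
  stopifnot(is.matrix(mat), n >= 1L)
  if (n >= nrow(mat)) return(mat)
  v <- apply(mat, 1L, stats::var)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(n)])
  mat[keep, , drop = FALSE]
}
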