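#' Relative expression by the 2^-ddCt (Livak) method
#'
#' Per replicate, dCt = Ct_target - Ct_reference; ddCt subtracts the mean
#' dCt of the calibrator group (pH 6.0 control by default) for the same
#' gene; the fold change is 2^-ddCt. Folds are summarized by their
#' geometric mean — which makes the calibrator group's mean fold exactly 1
#' by construction — with spread reported as the standard deviation of
#' log2 folds.
#'
#' @param ct data.frame with columns `group`, `replicate`, `gene_id`,
#'   `ct_target`, `ct_reference` (see [readCtTable()]).
#' @param calibratorGroup the calibrator (control) group value, default 6
#'   (pH 6.0); must be present for every gene.
#' @return list with `perReplicate` (data.frame: gene_id, group, replicate,
#'   fold) and `summary` (data.frame: gene_id, group, meanFold
#'   (geometric), sdLog2, n).
#' @export
relativeExpression <- function(ct, calibratorGroup = 6) {
  need <- c("group", "replicate", "gene_id", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(ct)))
  if (any(is.na(ct$ct_reference)))
    stop("missing reference Ct")
  if (any(ct$ct_target <= 0 | ct$ct_reference <= 0))
    stop("Ct values must be positive")
  ct$dct <- ct$ct_target - ct$ct_reference
  out <- do.call(rbind, lapply(split(ct, ct$gene_id), function(g) {
    cal <- g$dct[g$group == calibratorGroup]
    if (!length(cal))
      stop("calibrator group absent for gene ", g$gene_id[1])
    g$calMean <- mean(cal)
    g$fold <- 2^-(g$dct - g$calMean)
    g
  }))
  rownames(out) <- NULL
  # geometric mean computed as 2^-(mean(dct) - calibrator mean): for the
  # calibrator group the two means are means of the same replicate vector,
  # so the group's mean fold is exactly 1
  summ <- do.call(rbind, lapply(
    split(out, list(out$gene_id, out$group), drop = TRUE), function(s)
      data.frame(gene_id = s$gene_id[1], group = s$group[1],
                 meanFold = 2^-(mean(s$dct) - s$calMean[1]),
                 sdLog2 = stats::sd(log2(s$fold)), n = nrow(s),
                 stringsAsFactors = FALSE)))
  summ <- summ[order(summ$gene_id, summ$group), , drop = FALSE]
  rownames(summ) <- NULL
  list(perReplicate = out[, c("gene_id", "group", "replicate", "fold")],
       summary = summ)
}

#' Two-tailed treatment-vs-control significance with star coding
#'
#' Welch two-sample t-test (two-tailed) between replicate values of a
#' treatment group and the control group, used both for root fresh weight
#' and for gene expression. Stars follow the study's coding: `*` for
#' p <= 0.05, `**` for p <= 0.01.
#'
#' @param valuesTreatment,valuesControl numeric replicate values (>= 2
#'   each).
#' @return list with `p` and `stars` (`""`, `"*"`, or `"**"`).
#' @export
treatmentSignificance <- function(valuesTreatment, valuesControl) {
  stopifnot(length(valuesTreatment) >= 2, length(valuesControl) >= 2)
  v1 <- stats::sd(valuesTreatment); v0 <- stats::sd(valuesControl)
  if (v1 == 0 && v0 == 0) {
    p <- if (mean(valuesTreatment) == mean(valuesControl)) 1 else 0
  } else {
    p <- stats::t.test(valuesTreatment, valuesControl,
                       var.equal = FALSE)$p.value
  }
  stars <- if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
  list(p = p, stars = stars)
}

#' Spearman correlations among hub-gene stress responses
#'
#' Correlates the relative-expression profiles of the hub genes across all
#' group x replicate measurements (5 pH groups x 3 replicates = 15 values
#' by default; set `useGroupMeans = TRUE` to correlate the 5 group means
#' instead). Significance is flagged at p <= 0.05 (two-sided, t transform).
#'
#' @param rel result of [relativeExpression()].
#' @param useGroupMeans correlate group geometric means instead of
#'   replicate values (default FALSE).
#' @param alpha significance cutoff for the flag matrix (default 0.05).
#' @return list with `rho` (symmetric, unit diagonal), `p`, and
#'   `significant` (logical) matrices; constant genes yield NA rho with a
#'   warning.
#' @export
hubCorrelations <- function(rel, useGroupMeans = FALSE, alpha = 0.05) {
  pr <- if (useGroupMeans) {
    s <- rel$summary
    stats::reshape(s[, c("gene_id", "group", "meanFold")],
                   idvar = "gene_id", timevar = "group",
                   direction = "wide")
  } else {
    pr <- rel$perReplicate
    pr <- pr[order(pr$group, pr$replicate), , drop = FALSE]
    stats::reshape(transform(pr, col = paste(group, replicate, sep = "_")
                             )[, c("gene_id", "col", "fold")],
                   idvar = "gene_id", timevar = "col",
                   direction = "wide")
  }
  m <- as.matrix(pr[, -1, drop = FALSE])
  rownames(m) <- pr$gene_id
  constant <- apply(m, 1, function(x) stats::sd(x) == 0)
  if (any(constant))
    warning("constant expression profile(s): ",
            paste(rownames(m)[constant], collapse = ", "))
  sm <- .spearmanMatrix(m)
  rho <- sm$rho; p <- sm$p
  rho[constant, ] <- NA; rho[, constant] <- NA
  p[constant, ] <- NA; p[, constant] <- NA
  diag(rho) <- 1; diag(p) <- 0
  list(rho = rho, p = p, significant = !is.na(p) & p <= alpha)
}
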