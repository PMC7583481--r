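# Differential-PTM statistics: batch-aware linear model per mark, contrasts,
# FDR correction, significance tiers, and hierarchical clustering for heatmap
# ordering.

#' Fit the per-mark differential model
#'
#' For each mark, fits ordinary least squares of `log2(ratio)` on batch date
#' and condition (both categorical): `log2(mark) ~ date + condition`. Each
#' requested contrast `A - B` is estimated from the fitted condition
#' coefficients with a two-sided p-value from the t distribution on the
#' residual degrees of freedom. Ratios of zero are floored at `pseudo_ratio`
#' before the log transform. Marks with zero variance across samples are
#' dropped with a warning; a design in which condition is confounded with
#' batch is an explicit error.
#'
#' @param ratios Long data frame with columns `sample`, `mark`, `ratio`.
#' @param sheet Sample sheet: data frame with columns `sample`, `condition`,
#'   `batch`.
#' @param contrasts List of length-2 character vectors `c(A, B)`, each
#'   estimating condition A minus condition B on the log2 scale.
#' @param pseudo_ratio Floor applied to ratios before `log2` (default 1e-6).
#' @return Data frame with one row per mark x contrast: `mark`, `contrast`,
#'   `log2fc`, `se`, `t`, `df`, `p`, plus BH `q` and significance `tier`
#'   computed within each contrast.
#' @export
fit_mark_model <- function(ratios, sheet, contrasts, pseudo_ratio = 1e-6) {
  stopifnot(all(c("sample", "mark", "ratio") %in% names(ratios)),
            all(c("sample", "condition", "batch") %in% names(sheet)))
  if (length(unique(sheet$condition)) < 2L) {
    stop("need >= 2 conditions for contrasts")
  }
  if (!is.list(contrasts)) contrasts <- list(contrasts)
  sheet$condition <- factor(sheet$condition)
  sheet$batch <- factor(sheet$batch)
  multi_batch <- nlevels(sheet$batch) > 1L
  if (multi_batch) {
    tab <- table(sheet$batch, sheet$condition)
    X <- stats::model.matrix(~ batch + condition, sheet)
    if (qr(X)$rank < ncol(X)) {
      culprit <- rownames(tab)[rowSums(tab > 0) == 1L]
      stop("condition is confounded with batch date",
           if (length(culprit)) paste0(" (batch ",
             paste(culprit, collapse = ", "),
             " contains a single condition)"))
    }
  }

  out <- do.call(rbind, lapply(split(ratios, ratios$mark), function(d) {
    d <- merge(d, sheet, by = "sample")
    d$y <- log2(pmax(d$ratio, pseudo_ratio))
    if (stats::var(d$y) == 0) {
      warning("mark ", d$mark[1], " has zero variance; dropped",
              call. = FALSE)
      return(NULL)
    }
    fml <- if (multi_batch) y ~ batch + condition else y ~ condition
    fit <- stats::lm(fml, data = d)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    df <- fit$df.residual
    if (df < 1L) stop("no residual degrees of freedom for mark ", d$mark[1])
    lv <- levels(d$condition)
    do.call(rbind, lapply(contrasts, function(ct) {
      stopifnot(length(ct) == 2L)
      if (!all(ct %in% lv)) {
        stop("contrast condition(s) not in sample sheet: ",
             paste(setdiff(ct, lv), collapse = ", "))
      }
      cf <- function(cond) {
        nm <- paste0("condition", cond)
        if (nm %in% names(beta)) beta[[nm]] else 0
      }
      L <- stats::setNames(numeric(length(beta)), names(beta))
      nmA <- paste0("condition", ct[1]); nmB <- paste0("condition", ct[2])
      if (nmA %in% names(L)) L[nmA] <- 1
      if (nmB %in% names(L)) L[nmB] <- -1
      est <- cf(ct[1]) - cf(ct[2])
      se <- sqrt(drop(t(L) %*% V %*% L))
      tval <- est / se
      data.frame(mark = d$mark[1],
                 contrast = paste(ct[1], "vs", ct[2]),
                 log2fc = est, se = se, t = tval, df = df,
                 p = 2 * stats::pt(-abs(tval), df),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out <- do.call(rbind, lapply(split(out, out$contrast), function(g) {
    g$q <- adjust_fdr(g$p)
    g$tier <- significance_tiers(g$q)
    g
  }))
  rownames(out) <- NULL
  out
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up q-values by default (monotone, capped at 1).
#' `method = "storey"` rescales them by a pi0 estimate
#' `min(1, mean(p > lambda) / (1 - lambda))`, a lightweight variant of the
#' q-value approach; BH (pi0 = 1) is the reproducible default.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"storey"`.
#' @param lambda Tuning point for the Storey pi0 estimate (default 0.5).
#' @return q-values, same length and order as `p`.
#' @export
adjust_fdr <- function(p, method = c("BH", "storey"), lambda = 0.5) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey" && length(p) > 1L) {
    pi0 <- min(1, mean(p > lambda) / (1 - lambda))
    q <- pmin(1, q * pi0)
  }
  q
}

#' Significance tiers as star labels
#'
#' Maps a corrected p-value to the star bins used for heatmap annotation:
#' `(0.05, 0.1] -> *`, `(0.01, 0.05] -> **`, `(0.001, 0.01] -> ***`,
#' `(0.0001, 0.001] -> ****`, `(0, 0.0001] -> *****`; values above 0.1 get
#' an empty label.
#'
#' @param q Corrected p-values.
#' @return Character vector of star labels.
#' @export
significance_tiers <- function(q) {
  breaks <- c(0, 1e-4, 1e-3, 1e-2, 0.05, 0.1, Inf)
  labels <- c("*****", "****", "***", "**", "*", "")
  labels[as.integer(cut(q, breaks, labels = FALSE,
                        include.lowest = TRUE))]
}

#' Hierarchical clustering of marks for heatmap ordering
#'
#' Agglomerative clustering of the log2 fold-change matrix rows with complete
#' linkage on Euclidean distances (the referenced defaults). Ties are broken
#' deterministically by input order.
#'
#' @param mat Numeric matrix, marks in rows (rownames used as labels).
#' @param linkage Linkage method passed to [stats::hclust()] (default
#'   `"complete"`).
#' @param impute If `TRUE`, non-finite entries are replaced by the row mean;
#'   otherwise they are an error.
#' @return A list with `order` (leaf labels in dendrogram order), `merge`,
#'   `height`, and the underlying `hclust` object.
#' @export
cluster_marks <- function(mat, linkage = "complete", impute = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need >= 2 marks to cluster")
  if (any(!is.finite(mat))) {
    if (!impute) stop("non-finite values in fold-change matrix ",
                      "(set impute = TRUE to replace by row means)")
    for (i in seq_len(nrow(mat))) {
      bad <- !is.finite(mat[i, ])
      mat[i, bad] <- mean(mat[i, !bad])
    }
  }
  hc <- stats::hclust(stats::dist(mat), method = linkage)
  labs <- if (!is.null(rownames(mat))) rownames(mat) else
    as.character(seq_len(nrow(mat)))
  list(order = labs[hc$order], merge = hc$merge, height = hc$height,
       hclust = hc)
}
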