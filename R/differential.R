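# Multi-group differential abundance: per-protein omnibus tests (one-way
# ANOVA on log2 intensities, or Kruskal-Wallis on ranks), Benjamini-
# Hochberg q-values, linear-scale fold changes, and the q/fold-change
# enrichment-calling rule. Zeros are treated as "not quantified" and
# excluded from tests, never imputed.

#' Per-protein omnibus test across condition groups
#'
#' Tests each protein for any difference in abundance across the condition
#' groups of the matrix. The parametric branch is one-way ANOVA on
#' log2-transformed intensities (the standard variance-stabilizing scale
#' for MS intensity data); the nonparametric branch is the Kruskal-Wallis
#' rank test. `method = "auto"` screens each protein with Shapiro-Wilk per
#' group (groups with n >= 3) and falls back to Kruskal-Wallis when any
#' group rejects normality at p < 0.05.
#'
#' With `batch_covariate = TRUE`, per-protein batch means are removed on
#' the log2 scale (mean-centering each batch, restoring the protein grand
#' mean) before testing, so variance attributable to processing batch does
#' not enter the comparison.
#'
#' Proteins constant across all samples are flagged `test_used =
#' "degenerate"` with p = 1. Zero intensities are excluded as not
#' quantified; a protein whose groups lose too many values for the chosen
#' test is likewise degenerate.
#'
#' @param matrix an [abundance_matrix()] with >= 2 conditions, each with
#'   >= 2 samples.
#' @param method `"auto"`, `"anova"`, or `"kruskal_wallis"`.
#' @param batch_covariate remove per-batch means (log2 scale) before
#'   testing.
#' @return a data frame of class `DifferentialResult` with columns
#'   `protein_id`, `p_value`, `q_value` (Benjamini-Hochberg across the
#'   matrix), `test_used`; attribute `batch_adjusted`.
#' @seealso [compute_qvalues()], [fold_changes()], [call_enriched()]
#' @export
multigroup_test <- function(matrix,
                            method = c("auto", "anova", "kruskal_wallis"),
                            batch_covariate = FALSE) {
  stopifnot(inherits(matrix, "AbundanceMatrix"))
  method <- match.arg(method)
  cond <- factor(matrix$sample_meta$condition)
  if (nlevels(cond) < 2) stop("need at least 2 condition groups")
  small <- names(which(table(cond) < 2))
  if (length(small)) {
    stop("condition group(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  }
  ints <- matrix$intensities
  logm <- ints
  logm[logm <= 0] <- NA  # not quantified
  logm <- log2(logm)
  if (batch_covariate) {
    batch <- matrix$sample_meta$batch
    grand <- rowMeans(logm, na.rm = TRUE)
    for (b in unique(batch)) {
      cols <- which(batch == b)
      bm <- rowMeans(logm[, cols, drop = FALSE], na.rm = TRUE)
      logm[, cols] <- logm[, cols, drop = FALSE] - bm + grand
    }
  }

  test_one <- function(y) {
    ok <- is.finite(y)
    yy <- y[ok]; gg <- droplevels(cond[ok])
    if (length(yy) == 0 || sd(yy) == 0 || nlevels(gg) < 2 ||
        any(table(gg) < 2)) {
      return(c(p = 1, test = "degenerate"))
    }
    use <- method
    if (use == "auto") {
      non_normal <- FALSE
      for (g in levels(gg)) {
        v <- yy[gg == g]
        if (length(v) >= 3 && sd(v) > 0) {
          sw <- tryCatch(shapiro.test(v)$p.value, error = function(e) 1)
          if (is.finite(sw) && sw < 0.05) non_normal <- TRUE
        }
      }
      use <- if (non_normal) "kruskal_wallis" else "anova"
    }
    if (use == "anova") {
      p <- tryCatch(oneway.test(yy ~ gg, var.equal = TRUE)$p.value,
                    error = function(e) NaN)
      if (!is.finite(p)) {
        # zero within-group variance with distinct group means
        p <- .Machine$double.xmin
      }
      c(p = p, test = "anova")
    } else {
      p <- tryCatch(kruskal.test(yy, gg)$p.value, error = function(e) NaN)
      if (!is.finite(p)) return(c(p = 1, test = "degenerate"))
      c(p = p, test = "kruskal_wallis")
    }
  }

  res <- apply(logm, 1, test_one)
  p <- pmin(pmax(as.numeric(res["p", ]), .Machine$double.xmin), 1)
  out <- data.frame(protein_id = rownames(ints),
                    p_value = p,
                    q_value = compute_qvalues(p),
                    test_used = as.character(res["test", ]),
                    stringsAsFactors = FALSE)
  attr(out, "batch_adjusted") <- batch_covariate
  class(out) <- c("DifferentialResult", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted
#' ascending, `q_(i) = min_{j >= i} ( m * p_(j) / j )` clipped to 1 and
#' mapped back to the input order. The q-value of a protein is the FDR
#' incurred by declaring everything at least as significant.
#'
#' @param p_values numeric vector of p-values in (0, 1]; NaN or
#'   out-of-range values are rejected.
#' @return q-values in input order.
#' @examples
#' compute_qvalues(c(0.005, 0.011, 0.02, 0.04))
#' @export
compute_qvalues <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1] with no NA/NaN")
  }
  p.adjust(p, method = "BH")
}

#' Linear-scale fold changes against a reference condition
#'
#' For each protein and each non-reference condition, the ratio of mean
#' intensities (condition over reference) on the raw linear scale. A 0/0
#' cell yields `NA` (undefined); x/0 with x > 0 yields `Inf`.
#'
#' @param matrix an [abundance_matrix()].
#' @param reference condition label serving as the denominator.
#' @return data frame with `protein_id` and one column
#'   `fc_<condition>_vs_<reference>` per non-reference condition.
#' @export
fold_changes <- function(matrix, reference) {
  stopifnot(inherits(matrix, "AbundanceMatrix"))
  conds <- unique(matrix$sample_meta$condition)
  if (!reference %in% conds) stop("reference condition not present: ",
                                  reference)
  cond_mean <- function(cc) {
    cols <- matrix$sample_meta$sample_id[matrix$sample_meta$condition == cc]
    rowMeans(matrix$intensities[, cols, drop = FALSE])
  }
  ref_mean <- cond_mean(reference)
  out <- data.frame(protein_id = rownames(matrix$intensities),
                    stringsAsFactors = FALSE)
  for (cc in setdiff(conds, reference)) {
    num <- cond_mean(cc)
    fc <- ifelse(num == 0 & ref_mean == 0, NA_real_,
                 ifelse(ref_mean == 0, Inf, num / ref_mean))
    out[[paste0("fc_", cc, "_vs_", reference)]] <- fc
  }
  out
}

#' Call condition-enriched proteins by q-value and fold change
#'
#' A protein is called enriched when its q-value is at most `q_max` and
#' its fold change exceeds `fc_min` in at least one of the listed
#' (condition, reference) comparisons -- the rule used to define the gene
#' sets that feed pathway enrichment and network proximity.
#'
#' @param result a `DifferentialResult` (or any data frame with
#'   `protein_id` and `q_value`) augmented with the fold-change columns of
#'   [fold_changes()] for every listed comparison, or those columns merged
#'   in by the caller.
#' @param q_max maximum q-value (e.g. 0.1 for cell-culture data, 0.3 for
#'   tissue-scale discovery data).
#' @param fc_min fold-change threshold; a comparison passes when
#'   fc > `fc_min`.
#' @param comparisons list of 2-vectors `c(condition, reference)`; each
#'   must have a matching `fc_<condition>_vs_<reference>` column.
#' @return data frame with `protein_id` and `passed_comparisons`
#'   (comma-separated `condition_vs_reference` labels), one row per
#'   enriched protein.
#' @export
call_enriched <- function(result, q_max, fc_min, comparisons) {
  stopifnot(is.data.frame(result),
            all(c("protein_id", "q_value") %in% names(result)))
  if (length(comparisons) == 0) stop("no comparisons given")
  if (!is.list(comparisons)) comparisons <- list(comparisons)
  labels <- vapply(comparisons, function(cp) {
    col <- paste0("fc_", cp[1], "_vs_", cp[2])
    if (!col %in% names(result)) {
      stop("missing fold-change column for comparison ", cp[1], " vs ",
           cp[2], " (unknown condition label?)")
    }
    paste0(cp[1], "_vs_", cp[2])
  }, character(1))
  pass <- matrix(FALSE, nrow(result), length(comparisons))
  for (i in seq_along(comparisons)) {
    fc <- result[[paste0("fc_", labels[i])]]
    pass[, i] <- !is.na(fc) & fc > fc_min & result$q_value <= q_max
  }
  keep <- rowSums(pass) > 0
  data.frame(
    protein_id = result$protein_id[keep],
    passed_comparisons = vapply(which(keep), function(r) {
      paste(labels[pass[r, ]], collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a differential result (with any merged fold-change columns) as TSV
#'
#' @param result a `DifferentialResult` data frame.
#' @param path output path.
#' @export
write_differential <- function(result, path) {
  write_tsv(as.data.frame(result), path)
}
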