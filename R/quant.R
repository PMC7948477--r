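# Normalization and aggregation arithmetic for label-free and targeted
# (PRM-style) proteomics tables: heavy-standard ratio normalization, sum
# normalization per sample or per protein across conditions, peptide-to-
# protein averaging, and the unique-peptide / complete-case inclusion
# filters applied before any statistics.

#' Peptide-level intensity table
#'
#' Validates a long-format table of extracted-ion intensities: one row per
#' (peptide, donor, condition), with the parent protein, the intensity in
#' arbitrary area units, and a flag for heavy-isotope standard rows.
#'
#' @param df data frame with columns `peptide`, `protein_id`, `donor`,
#'   `condition`, `intensity`, and optionally `is_heavy_standard`
#'   (default `FALSE`).
#' @return the validated data frame with class `PeptideIntensityTable`.
#' @export
peptide_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("peptide", "protein_id", "donor", "condition", "intensity")
  if (!all(need %in% names(df))) {
    stop("peptide table needs columns: ", paste(need, collapse = ", "))
  }
  if (!"is_heavy_standard" %in% names(df)) df$is_heavy_standard <- FALSE
  df$is_heavy_standard <- as.logical(df$is_heavy_standard)
  if (any(!is.finite(df$intensity)) || any(df$intensity < 0)) {
    stop("intensities must be finite and >= 0")
  }
  key <- paste(df$peptide, df$donor, df$condition, df$is_heavy_standard,
               sep = "\r")
  if (anyDuplicated(key)) {
    stop("each (peptide, donor, condition) may appear at most once")
  }
  df <- df[, c(need, "is_heavy_standard")]
  class(df) <- c("PeptideIntensityTable", "data.frame")
  df
}

#' Sum normalization
#'
#' Divides intensity vectors by their totals so values become relative
#' shares.
#'
#' Two scopes are supported. `"per_sample"` divides each sample column of an
#' abundance matrix by its column total (total-intensity load
#' normalization). `"per_protein_across_conditions"` is the targeted-MS
#' convention: for each protein (or peptide) and donor, the vector of its
#' values across condition groups is divided by that vector's sum, so each
#' value is the share of that analyte's signal found in each condition.
#' Groups whose values are all zero are left at zero and collected in the
#' `flagged_groups` attribute with a warning.
#'
#' @param x an [abundance_matrix()] or [peptide_table()].
#' @param scope `"per_sample"` or `"per_protein_across_conditions"`.
#'   Peptide tables support only the latter.
#' @return an object of the same class and shape, normalized.
#' @examples
#' m <- matrix(c(2, 3, 5), 3, 1, dimnames = list(paste0("P", 1:3), "s1"))
#' meta <- data.frame(sample_id = "s1", donor = "d1", condition = "A")
#' am <- abundance_matrix(m, meta, setNames(rep(3L, 3), paste0("P", 1:3)))
#' sum_normalize(am, "per_sample")$intensities
#' @export
sum_normalize <- function(x, scope = c("per_sample",
                                       "per_protein_across_conditions")) {
  UseMethod("sum_normalize")
}

#' @export
sum_normalize.AbundanceMatrix <- function(x,
    scope = c("per_sample", "per_protein_across_conditions")) {
  scope <- match.arg(scope)
  ints <- x$intensities
  flagged <- character(0)
  if (scope == "per_sample") {
    tot <- colSums(ints)
    zero <- tot <= 0
    if (any(zero)) {
      flagged <- colnames(ints)[zero]
      warning("all-zero sample(s) left unnormalized: ",
              paste(flagged, collapse = ", "))
      tot[zero] <- 1
    }
    ints <- sweep(ints, 2, tot, "/")
  } else {
    for (dn in unique(x$sample_meta$donor)) {
      cols <- x$sample_meta$sample_id[x$sample_meta$donor == dn]
      tot <- rowSums(ints[, cols, drop = FALSE])
      zero <- tot <= 0
      if (any(zero)) {
        flagged <- c(flagged, paste(rownames(ints)[zero], dn, sep = "/"))
        tot[zero] <- 1
      }
      ints[, cols] <- ints[, cols, drop = FALSE] / tot
    }
    if (length(flagged)) {
      warning("all-zero (protein, donor) group(s) left at zero: ",
              paste(head(flagged, 5), collapse = ", "),
              if (length(flagged) > 5) " ...")
    }
  }
  out <- abundance_matrix(ints, x$sample_meta, x$unique_peptides)
  attr(out, "flagged_groups") <- flagged
  out
}

#' @export
sum_normalize.PeptideIntensityTable <- function(x,
    scope = c("per_sample", "per_protein_across_conditions")) {
  scope <- match.arg(scope)
  if (scope != "per_protein_across_conditions") {
    stop("peptide tables are sum-normalized per protein across conditions")
  }
  grp <- paste(x$peptide, x$protein_id, x$donor, x$is_heavy_standard,
               sep = "\r")
  tot <- tapply(x$intensity, grp, sum)[grp]
  zero <- tot <= 0
  flagged <- unique(paste(x$peptide[zero], x$donor[zero], sep = "/"))
  if (length(flagged)) {
    warning("all-zero (peptide, donor) group(s) left at zero: ",
            paste(head(flagged, 5), collapse = ", "))
    tot[zero] <- 1
  }
  x$intensity <- as.numeric(x$intensity / tot)
  out <- peptide_table(as.data.frame(x))
  attr(out, "flagged_groups") <- flagged
  out
}

#' Normalize endogenous peptides to heavy-isotope standards
#'
#' Within each (donor, condition) group, every endogenous intensity is
#' divided by the mean intensity of the heavy-standard rows belonging to
#' the listed standard proteins, correcting per-run load before any
#' between-condition comparison. Heavy rows are dropped from the output.
#'
#' @param table a [peptide_table()].
#' @param standard_protein_ids proteins whose heavy rows serve as the
#'   standard.
#' @return a [peptide_table()] of endogenous rows, ratio-normalized.
#' @export
normalize_to_standard <- function(table, standard_protein_ids) {
  stopifnot(inherits(table, "PeptideIntensityTable"))
  grp <- paste(table$donor, table$condition, sep = "/")
  is_std <- table$is_heavy_standard &
    table$protein_id %in% standard_protein_ids
  std_mean <- tapply(table$intensity[is_std], grp[is_std], mean)
  missing <- setdiff(unique(grp), names(std_mean))
  if (length(missing)) {
    stop("no heavy standard in group(s): ", paste(missing, collapse = ", "))
  }
  out <- table[!table$is_heavy_standard, , drop = FALSE]
  out$intensity <- out$intensity /
    as.numeric(std_mean[paste(out$donor, out$condition, sep = "/")])
  peptide_table(as.data.frame(out))
}

#' Aggregate peptide intensities to one protein signal per donor
#'
#' For each (protein, donor, condition) cell, the unweighted mean over that
#' protein's peptides -- the "average of one to three sum-normalized
#' peptides" convention of targeted proteomics. Single-peptide proteins
#' pass through unchanged. The returned matrix records, per protein, the
#' number of distinct peptides averaged.
#'
#' @param table a [peptide_table()] of endogenous rows, typically already
#'   sum-normalized per protein across conditions.
#' @return an [abundance_matrix()] with one sample per (donor, condition);
#'   `unique_peptides` holds the peptide count per protein. Cells with no
#'   observed peptide are 0 (not quantified).
#' @export
aggregate_peptides <- function(table) {
  stopifnot(inherits(table, "PeptideIntensityTable"))
  tab <- table[!table$is_heavy_standard, , drop = FALSE]
  if (nrow(tab) == 0) stop("no endogenous peptide rows to aggregate")
  agg <- aggregate(intensity ~ protein_id + donor + condition, data = tab,
                   FUN = mean)
  agg$sample_id <- paste(agg$donor, agg$condition, sep = "_")
  proteins <- sort(unique(agg$protein_id))
  samples <- unique(agg[, c("sample_id", "donor", "condition")])
  samples <- samples[order(samples$sample_id), , drop = FALSE]
  ints <- matrix(0, length(proteins), nrow(samples),
                 dimnames = list(proteins, samples$sample_id))
  ints[cbind(match(agg$protein_id, proteins),
             match(agg$sample_id, samples$sample_id))] <- agg$intensity
  npep <- tapply(tab$peptide, tab$protein_id,
                 function(p) length(unique(p)))
  abundance_matrix(ints, samples, setNames(as.integer(npep[proteins]),
                                           proteins))
}

#' Filter proteins by unique-peptide support
#'
#' Keeps exactly the proteins identified by at least `min_unique` unique
#' peptides (the standard inclusion rule before differential analysis: 3
#' or more for tissue-scale discovery data, 2 or more for cell-culture
#' data). Row order is preserved.
#'
#' @param matrix an [abundance_matrix()].
#' @param min_unique minimum unique-peptide count (>= 1).
#' @return the filtered [abundance_matrix()].
#' @export
filter_by_unique_peptides <- function(matrix, min_unique) {
  stopifnot(inherits(matrix, "AbundanceMatrix"), min_unique >= 1)
  keep <- matrix$unique_peptides >= min_unique
  abundance_matrix(matrix$intensities[keep, , drop = FALSE],
                   matrix$sample_meta, matrix$unique_peptides[keep])
}

#' Keep only fully quantified proteins
#'
#' Retains proteins with a strictly positive intensity in every (donor,
#' condition) cell of the required condition groups, mirroring the
#' "quantifiable in all donors" inclusion rule for targeted data. Missing
#' values are encoded as 0 and are never imputed.
#'
#' @param matrix an [abundance_matrix()].
#' @param required_groups condition labels that must be fully observed;
#'   defaults to all conditions present.
#' @return the filtered [abundance_matrix()].
#' @export
filter_complete_cases <- function(matrix,
                                  required_groups = NULL) {
  stopifnot(inherits(matrix, "AbundanceMatrix"))
  required_groups <- required_groups %||%
    unique(matrix$sample_meta$condition)
  unknown <- setdiff(required_groups, matrix$sample_meta$condition)
  if (length(unknown)) {
    stop("unknown condition group(s): ", paste(unknown, collapse = ", "))
  }
  cols <- matrix$sample_meta$sample_id[
    matrix$sample_meta$condition %in% required_groups]
  keep <- rowSums(matrix$intensities[, cols, drop = FALSE] > 0) ==
    length(cols)
  abundance_matrix(matrix$intensities[keep, , drop = FALSE],
                   matrix$sample_meta, matrix$unique_peptides[keep])
}

#' Read / write a peptide table as TSV
#'
#' @param table a [peptide_table()].
#' @param path file path.
#' @return `write_peptides` returns `path` invisibly; `read_peptides`
#'   returns a [peptide_table()].
#' @export
write_peptides <- function(table, path) {
  stopifnot(inherits(table, "PeptideIntensityTable"))
  write_tsv(as.data.frame(table), path)
}

#' @rdname write_peptides
#' @export
read_peptides <- function(path) {
  peptide_table(read_tsv(path))
}
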