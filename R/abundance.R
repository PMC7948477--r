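#' Protein-by-sample abundance matrix with sample metadata
#'
#' The central quantitative container: a non-negative intensity matrix
#' (proteins in rows, samples in columns), per-sample metadata (donor,
#' condition, batch), and per-protein unique-peptide counts. Zeros encode
#' "not quantified"; the package never imputes them.
#'
#' @param intensities numeric matrix, proteins x samples, with row names
#'   (protein ids) and column names (sample ids); all values finite and >= 0.
#' @param sample_meta data frame with columns `sample_id`, `donor`,
#'   `condition` and optionally `batch` (defaults to a single batch), one row
#'   per column of `intensities`, in matching order or matchable by
#'   `sample_id`.
#' @param unique_peptides named integer vector of unique-peptide counts per
#'   protein; names must cover the row names of `intensities`.
#' @return an object of class `AbundanceMatrix`: a list with elements
#'   `intensities`, `sample_meta`, `unique_peptides`.
#' @examples
#' m <- matrix(2^rnorm(12, 20), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    donor = c("d1", "d1", "d2", "d2"),
#'                    condition = c("A", "B", "A", "B"))
#' am <- abundance_matrix(m, meta, c(P1 = 3L, P2 = 1L, P3 = 5L))
#' am
#' @export
abundance_matrix <- function(intensities, sample_meta, unique_peptides) {
  stopifnot(is.matrix(intensities), is.numeric(intensities))
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop("intensities must have protein row names and sample column names")
  }
  if (anyDuplicated(rownames(intensities))) stop("duplicate protein ids")
  if (anyDuplicated(colnames(intensities))) stop("duplicate sample ids")
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative")
  }
  stopifnot(is.data.frame(sample_meta))
  need <- c("sample_id", "donor", "condition")
  if (!all(need %in% names(sample_meta))) {
    stop("sample_meta needs columns: ", paste(need, collapse = ", "))
  }
  if (!"batch" %in% names(sample_meta)) sample_meta$batch <- "batch1"
  sample_meta <- as.data.frame(lapply(sample_meta, as.character),
                               stringsAsFactors = FALSE)
  idx <- match(colnames(intensities), sample_meta$sample_id)
  if (anyNA(idx)) stop("every sample column needs a sample_meta row")
  sample_meta <- sample_meta[idx, c("sample_id", "donor", "condition", "batch"),
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  if (any(table(sample_meta$condition) < 1L)) stop("empty condition group")
  up <- unique_peptides
  if (is.null(names(up)) || !all(rownames(intensities) %in% names(up))) {
    stop("unique_peptides must be named and cover all proteins")
  }
  up <- as.integer(up[rownames(intensities)])
  if (any(is.na(up)) || any(up < 1L)) {
    stop("unique_peptides must be positive integers")
  }
  names(up) <- rownames(intensities)
  structure(list(intensities = intensities, sample_meta = sample_meta,
                 unique_peptides = up),
            class = "AbundanceMatrix")
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix: %d proteins x %d samples\n",
              nrow(x$intensities), ncol(x$intensities)))
  tab <- table(x$sample_meta$condition)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat(sprintf("donors: %d, batches: %d\n",
              length(unique(x$sample_meta$donor)),
              length(unique(x$sample_meta$batch))))
  invisible(x)
}

#' @export
dim.AbundanceMatrix <- function(x) dim(x$intensities)

#' Write / read an AbundanceMatrix as plain TSV files
#'
#' Three files are written under a common prefix: `<prefix>_matrix.tsv`
#' (first column `protein_id`, one column per sample),
#' `<prefix>_samples.tsv` (sample metadata) and `<prefix>_peptides.tsv`
#' (per-protein unique-peptide counts).
#'
#' @param x an [abundance_matrix()].
#' @param prefix path prefix for the three files.
#' @return `write_abundance` returns the three paths invisibly;
#'   `read_abundance` returns an `AbundanceMatrix`.
#' @export
write_abundance <- function(x, prefix) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  mat <- data.frame(protein_id = rownames(x$intensities),
                    as.data.frame(x$intensities, check.names = FALSE),
                    check.names = FALSE)
  paths <- paste0(prefix, c("_matrix.tsv", "_samples.tsv", "_peptides.tsv"))
  write_tsv(mat, paths[1])
  write_tsv(x$sample_meta, paths[2])
  write_tsv(data.frame(protein_id = names(x$unique_peptides),
                       unique_peptides = unname(x$unique_peptides)),
            paths[3])
  invisible(paths)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(prefix) {
  mat <- read_tsv(paste0(prefix, "_matrix.tsv"))
  meta <- read_tsv(paste0(prefix, "_samples.tsv"))
  pep <- read_tsv(paste0(prefix, "_peptides.tsv"))
  ints <- as.matrix(mat[, -1, drop = FALSE])
  rownames(ints) <- mat$protein_id
  abundance_matrix(ints, meta,
                   setNames(pep$unique_peptides, pep$protein_id))
}
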