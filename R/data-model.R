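#' Construct a count matrix
#'
#' A count matrix is a plain integer matrix of reads with genes in rows and
#' samples in columns, identified by unique row and column names. Counts
#' must be non-negative integers; fractional input is rejected rather than
#' rounded so that any thinning or spiking decision stays explicit.
#'
#' @param counts Numeric matrix of non-negative integers.
#' @param gene_ids Character vector of unique gene identifiers
#'   (default: rownames).
#' @param sample_ids Character vector of unique sample identifiers
#'   (default: colnames).
#' @return An integer matrix with `dimnames` set.
#' @examples
#' count_matrix(matrix(0:3, 2, 2), c("g1", "g2"), c("s1", "s2"))
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    pb_stop("count matrix needs gene and sample identifiers", "pb_structure_error")
  }
  if (length(gene_ids) != nrow(counts) || length(sample_ids) != ncol(counts)) {
    pb_stop("identifier lengths do not match matrix dimensions",
            "pb_structure_error")
  }
  if (anyDuplicated(gene_ids)) {
    pb_stop(sprintf("duplicate gene id: %s", gene_ids[duplicated(gene_ids)][1]),
            "pb_structure_error")
  }
  if (anyDuplicated(sample_ids)) {
    pb_stop(sprintf("duplicate sample id: %s",
                    sample_ids[duplicated(sample_ids)][1]),
            "pb_structure_error")
  }
  check_counts_integral(counts, gene_ids, sample_ids)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, sample_ids)
  counts
}

check_counts_integral <- function(counts, gene_ids, sample_ids) {
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    pb_stop(sprintf("invalid count %s at (%s, %s): must be a non-negative integer",
                    format(counts[bad[1]]), gene_ids[i[1]], sample_ids[i[2]]),
            "pb_value_error")
  }
  invisible(TRUE)
}

#' Construct a sample design table
#'
#' Per-sample experimental factors: treatment, block, biological replicate
#' and technical replicate. A missing `block` is interpreted as one common
#' block; a missing `tech_rep` as a single technical replicate; a missing
#' `bio_rep` defaults to the sample id (every sample its own biological
#' replicate).
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param treatment Treatment labels (coerced to character).
#' @param block Block labels, or `NULL` for a single common block.
#' @param bio_rep Biological-replicate labels within treatment.
#' @param tech_rep Technical-replicate labels within biological replicate.
#' @return A `data.frame` with columns `sample_id`, `treatment`, `block`,
#'   `bio_rep`, `tech_rep`.
#' @export
design_table <- function(sample_id, treatment, block = NULL,
                         bio_rep = NULL, tech_rep = NULL) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) {
    pb_stop("duplicate sample_id in design", "pb_structure_error")
  }
  if (is.null(block)) block <- rep("1", n)
  if (is.null(bio_rep)) bio_rep <- sample_id
  if (is.null(tech_rep)) tech_rep <- rep("1", n)
  d <- data.frame(
    sample_id = sample_id,
    treatment = as.character(treatment),
    block = as.character(block),
    bio_rep = as.character(bio_rep),
    tech_rep = as.character(tech_rep),
    stringsAsFactors = FALSE
  )
  key <- paste(d$treatment, d$bio_rep, d$tech_rep, sep = "\r")
  if (anyDuplicated(key)) {
    pb_stop("(treatment, bio_rep, tech_rep) must uniquely identify a sample",
            "pb_structure_error")
  }
  d
}

#' Construct a ground-truth table
#'
#' Records, per gene, whether it is truly differentially expressed (a member
#' of the alternative set S1 rather than the null set S0) and its true
#' natural-log effect (group 2 minus group 1); the effect is 0 for every
#' null gene.
#'
#' @param gene_id Character vector of gene identifiers.
#' @param is_de Logical vector, `TRUE` for S1 members.
#' @param true_log_effect Numeric vector of natural-log effects.
#' @return A `data.frame` with columns `gene_id`, `is_de`, `true_log_effect`.
#' @export
truth_table <- function(gene_id, is_de, true_log_effect) {
  stopifnot(length(gene_id) == length(is_de),
            length(gene_id) == length(true_log_effect))
  is_de <- as.logical(is_de)
  if (any(!is_de & true_log_effect != 0)) {
    pb_stop("null genes must have true_log_effect == 0", "pb_value_error")
  }
  data.frame(gene_id = as.character(gene_id), is_de = is_de,
             true_log_effect = as.numeric(true_log_effect),
             stringsAsFactors = FALSE)
}

#' Construct a per-gene test-result table
#'
#' @param gene_id Character vector of gene identifiers.
#' @param statistic Numeric test statistics.
#' @param p_value Numeric p-values in \[0, 1\] (NA allowed for flagged genes).
#' @param method Method tag (recycled), e.g. `"nb-lrt-tagwise"`.
#' @return A `data.frame` with columns `gene_id`, `statistic`, `p_value`,
#'   `method`.
#' @export
result_table <- function(gene_id, statistic, p_value, method) {
  ok <- is.na(p_value) | (p_value >= 0 & p_value <= 1)
  if (!all(ok)) pb_stop("p-values must lie in [0, 1]", "pb_value_error")
  data.frame(gene_id = as.character(gene_id),
             statistic = as.numeric(statistic),
             p_value = as.numeric(p_value),
             method = rep_len(as.character(method), length(gene_id)),
             stringsAsFactors = FALSE)
}

#' Validate a (counts, design) pair
#'
#' Checks every structural invariant shared by all pipeline stages: counts
#' are non-negative integers with unique gene and sample identifiers, and the
#' design covers exactly the samples of the count matrix. Returns its inputs
#' unchanged; idempotent and side-effect free.
#'
#' @param counts A count matrix (see [count_matrix()]).
#' @param design A design table (see [design_table()]).
#' @return `list(counts = counts, design = design)` invisibly testable.
#' @export
validate_dataset <- function(counts, design) {
  counts <- count_matrix(counts)
  required <- c("sample_id", "treatment", "block", "bio_rep", "tech_rep")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols)) {
    pb_stop(sprintf("design is missing column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "pb_structure_error")
  }
  extra <- setdiff(colnames(counts), design$sample_id)
  if (length(extra)) {
    pb_stop(sprintf("sample '%s' present in counts but absent from design",
                    extra[1]), "pb_structure_error")
  }
  extra2 <- setdiff(design$sample_id, colnames(counts))
  if (length(extra2)) {
    pb_stop(sprintf("sample '%s' present in design but absent from counts",
                    extra2[1]), "pb_structure_error")
  }
  # align design rows to count columns
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  list(counts = counts, design = design)
}
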