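#' Read a count matrix from disk
#'
#' Two dialects are supported. `tsv`: tab-separated, first row holds sample
#' ids (with an empty leading field), first column holds gene ids, cells are
#' integers. `mtx`: MatrixMarket coordinate integer format with sidecar id
#' files `<path>.genes` and `<path>.samples`, one identifier per line.
#'
#' @param path File path.
#' @param format `"tsv"` or `"mtx"`.
#' @return A validated count matrix.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) pb_stop(sprintf("no such file: %s", path),
                                  "pb_io_error")
  if (format == "tsv") {
    lines <- readLines(path)
    if (length(lines) < 2L) pb_stop(sprintf("parse error in %s: need a header and at least one gene row", path), "pb_parse_error")
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    sample_ids <- header[-1]
    body <- strsplit(lines[-1], "\t", fixed = TRUE)
    gene_ids <- vapply(body, `[[`, "", 1L)
    cells <- lapply(seq_along(body), function(i) {
      x <- body[[i]][-1]
      if (length(x) != length(sample_ids)) {
        pb_stop(sprintf("parse error at line %d: %d cells for %d samples",
                        i + 1L, length(x), length(sample_ids)), "pb_parse_error")
      }
      v <- suppressWarnings(as.numeric(x))
      if (anyNA(v) || any(v != round(v))) {
        pb_stop(sprintf("parse error at line %d: non-integer cell", i + 1L),
                "pb_parse_error")
      }
      v
    })
    m <- do.call(rbind, cells)
    return(count_matrix(m, gene_ids, sample_ids))
  }
  m <- as.matrix(Matrix::readMM(path))
  gene_ids <- readLines(paste0(path, ".genes"))
  sample_ids <- readLines(paste0(path, ".samples"))
  count_matrix(m, gene_ids, sample_ids)
}

#' Write a count matrix to disk
#'
#' @param cm Count matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"` (see [read_counts()] for the dialects).
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  cm <- count_matrix(cm)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("", colnames(cm)), collapse = "\t"), con)
    writeLines(paste(rownames(cm),
                     apply(cm, 1L, paste, collapse = "\t"), sep = "\t"), con)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(cm, sparse = TRUE), "generalMatrix"), path)
    writeLines(rownames(cm), paste0(path, ".genes"))
    writeLines(colnames(cm), paste0(path, ".samples"))
  }
  invisible(path)
}

fmt_real <- function(x) {
  # 12 significant digits: reproducible round trips without locale issues
  sub("e([+-])0*(\\d)", "e\\1\\2", formatC(x, digits = 12, format = "g"))
}

write_tsv_df <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_df <- function(path, required, optional = character()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    pb_stop(sprintf("%s: missing required column '%s'", path, missing_cols[1]),
            "pb_schema_error")
  }
  df
}

#' Read a design table from TSV
#'
#' Header columns: `sample_id`, `treatment` (required), `block`, `bio_rep`,
#' `tech_rep` (optional; defaults as in [design_table()]).
#'
#' @param path File path.
#' @return A design table.
#' @export
read_design <- function(path) {
  df <- read_tsv_df(path, c("sample_id", "treatment"))
  design_table(df$sample_id, df$treatment,
               block = if ("block" %in% names(df)) df$block,
               bio_rep = if ("bio_rep" %in% names(df)) df$bio_rep,
               tech_rep = if ("tech_rep" %in% names(df)) df$tech_rep)
}

#' @rdname read_design
#' @param design Design table to serialize.
#' @export
write_design <- function(design, path) write_tsv_df(design, path)

#' Read/write a ground-truth table (TSV)
#'
#' Columns: `gene_id`, `is_de` (`TRUE`/`FALSE`), `true_log_effect` (natural
#' log; serialized with 12 significant digits).
#'
#' @param path File path.
#' @return `read_truth`: a truth table.
#' @export
read_truth <- function(path) {
  df <- read_tsv_df(path, c("gene_id", "is_de", "true_log_effect"))
  truth_table(df$gene_id, as.logical(df$is_de),
              as.numeric(df$true_log_effect))
}

#' @rdname read_truth
#' @param tt Truth table to serialize.
#' @export
write_truth <- function(tt, path) {
  out <- data.frame(gene_id = tt$gene_id, is_de = tt$is_de,
                    true_log_effect = fmt_real(tt$true_log_effect))
  write_tsv_df(out, path)
}

#' Read/write a test-result table (TSV)
#'
#' Columns: `gene_id`, `statistic`, `p_value`, `method`.
#'
#' @param path File path.
#' @return `read_results`: a result table.
#' @export
read_results <- function(path) {
  df <- read_tsv_df(path, c("gene_id", "statistic", "p_value", "method"))
  result_table(df$gene_id, as.numeric(df$statistic),
               as.numeric(df$p_value), df$method)
}

#' @rdname read_results
#' @param rt Result table to serialize.
#' @export
write_results <- function(rt, path) {
  out <- rt
  out$statistic <- fmt_real(rt$statistic)
  out$p_value <- fmt_real(rt$p_value)
  write_tsv_df(out, path)
}

run_config_keys <- c(
  "T", "K", "n", "r", "n_levels", "r_levels", "p0", "pi", "q_threshold",
  "seed", "methods", "offset_scheme", "target_depth", "cv", "n_perm",
  "p", "t", "effect_mode", "out_dir", "format", "preset", "n_genes",
  "prior_count"
)

#' Read a run configuration (YAML)
#'
#' Flat YAML file holding the scenario grid, simulation and plasmode
#' settings, seeds and method list. Unknown keys are rejected so that typos
#' cannot silently fall back to defaults. Recognized keys: T, K, n, r,
#' n_levels, r_levels, p0, pi, q_threshold, seed, methods, offset_scheme,
#' target_depth, cv, n_perm, p, t, effect_mode, out_dir, format, preset,
#' n_genes, prior_count.
#'
#' @param path File path.
#' @return A named list of class `"run_config"`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) pb_stop(sprintf("%s: config must be a key-value map", path),
                             "pb_schema_error")
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    pb_stop(sprintf("%s: unknown config key '%s'", path, unknown[1]),
            "pb_schema_error")
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_config
#' @param cfg Configuration list to serialize.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the fully resolved configuration, package version, master seed,
#' per-stage sub-seeds and md5 digests of every output file, so that a run
#' can be reproduced bit-for-bit.
#'
#' @param dir Output directory (one manifest per directory).
#' @param config Resolved configuration list.
#' @param seed Master seed.
#' @param sub_seeds Named list/vector of per-stage sub-seeds.
#' @param files Character vector of output file paths to digest.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, seed, sub_seeds = NULL,
                           files = character()) {
  digests <- if (length(files)) as.list(tools::md5sum(files)) else list()
  manifest <- list(
    tool = "plasmodeBench",
    version = as.character(utils::packageVersion("plasmodeBench")),
    seed = seed,
    sub_seeds = as.list(sub_seeds),
    config = unclass(config),
    digests = digests
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
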