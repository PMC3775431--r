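#' Run code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the previous RNG state so
#' that callers' random streams are not disturbed. A `NULL` seed evaluates
#' `code` under the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Derive a labelled sub-seed from a master seed
#'
#' Deterministic mixing of a master seed with a stage label so that pipeline
#' stages draw from independent, reproducible streams. The result is always
#' a positive integer below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param label Character stage label, e.g. `"simulate/n3_r1/k07"`.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label),
            length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(label)) {
    h <- (h * 131 + k) %% m
  }
  as.integer(h %% (m - 1L) + 1L)
}

# stop() with a consistent condition class so callers can test error families
pb_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "plasmodeBench_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}

geometric_mean <- function(x) exp(mean(log(x)))
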