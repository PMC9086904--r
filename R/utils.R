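#' @keywords internal
#' @useDynLib morphnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Modulus for derived seeds: largest prime below 2^31 keeps every derived
# seed a valid 32-bit R integer.
.SEED_MOD <- 2147483647

#' Derive a reproducible sub-seed from a base seed and a string tag
#'
#' A single user-visible seed is expanded into independent substreams, one
#' per subject or pipeline stage, by mixing the seed with a stable
#' polynomial hash of a tag such as the subject identifier. The hash
#' depends only on the character codes of the tag, so substreams are
#' identical across platforms and across cohort orderings.
#'
#' @param seed integer base seed.
#' @param tag character scalar naming the substream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  codes <- utf8ToInt(as.character(tag))
  h <- (abs(seed) %% .SEED_MOD)
  for (cc in codes) {
    h <- (h * 31 + cc) %% .SEED_MOD
  }
  as.integer(h)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
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
  set.seed(as.integer(seed))
  force(expr)
}

# scalar checks used across the package
.check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (x < lo || x > hi) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, lo, hi, x),
         call. = FALSE)
  }
  invisible(x)
}

#' AAL-116 region label table
#'
#' The default 116-region automated-anatomical-labeling parcellation:
#' integer atlas label and region name, in atlas order. The pipeline is
#' parcellation-agnostic; this table is the default node definition.
#'
#' @return a data.frame with columns `label` (integer) and `name`
#'   (character), 116 rows.
#' @export
aal116_labels <- function() {
  path <- system.file("extdata", "aal116_labels.tsv", package = "morphnet",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$label <- as.integer(df$label)
  df
}
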