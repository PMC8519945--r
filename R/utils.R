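# Internal helpers shared across modules.
#
# All genomic intervals in this package are 0-based half-open [start, end);
# conversion to/from 1-based formats (GFF3, VCF) happens only at I/O time.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_invalid <- function(...) stop(..., call. = FALSE)

# Half-open interval intersection test, vectorised over the first interval set.
intervals_overlap <- function(start1, end1, start2, end2) {
  start1 < end2 & start2 < end1
}

# Deterministic per-stage seed derived from a master seed. Keeps every source
# of randomness tied to one user-visible seed while decoupling the streams of
# different pipeline stages. Result stays within the 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Run code under a local RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Validate a variant table (id, chrom, pos[, ref, alt]).
check_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(variants))) {
    stop_invalid("variant table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(variants$pos < 0)) stop_invalid("variant positions must be >= 0")
  if (anyDuplicated(variants$id)) stop_invalid("variant ids must be unique")
  invisible(variants)
}
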