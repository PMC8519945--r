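# Allele-level transcription-factor motif analysis: scan position weight
# matrices over the reference and alternative allele windows (+/- 25 bp of
# flanking sequence) and call motif gains/losses at a score threshold.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param motif_id Motif identifier.
#' @param matrix A 4 x width numeric matrix of per-position base
#'   probabilities (rows A, C, G, T) or counts (normalised internally).
#' @param pseudocount Small positive value added before log-odds scoring.
#' @return An object of class `pwm`.
#' @export
pwm <- function(motif_id, matrix, pseudocount = 1e-3) {
  stopifnot(nrow(matrix) == 4, pseudocount > 0)
  rownames(matrix) <- DNA_BASES
  cs <- colSums(matrix)
  if (any(cs <= 0)) stop_invalid("PWM columns must have positive sums")
  matrix <- sweep(matrix, 2, cs, "/")
  structure(list(motif_id = motif_id, matrix = matrix,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$motif_id, "width", ncol(x$matrix),
      "consensus", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per position)
#' @param x A `pwm` object.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$matrix, 2, which.max)], collapse = "")
}

reverse_complement <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Log2-odds score matrix against a uniform 0.25 background with pseudocount.
pwm_logodds <- function(x) {
  p <- (x$matrix + x$pseudocount) / (1 + 4 * x$pseudocount)
  log2(p / 0.25)
}

#' Best PWM match score over all offsets and both strands
#'
#' Scores are log2-odds sums against a uniform background: for each offset,
#' `sum_i log2(p_i(base) / 0.25)` with pseudocount-regularised probabilities;
#' the maximum over every offset on the forward and reverse-complement strand
#' is returned. Non-ACGT letters score 0 (neutral) at their position. When
#' the sequence is shorter than the motif `NA` is returned.
#'
#' @param x A [pwm()] object.
#' @param seq A character scalar (DNA).
#' @return Best score (numeric) or `NA` if the sequence is too short.
#' @export
pwm_best_score <- function(x, seq) {
  w <- ncol(x$matrix)
  lo <- pwm_logodds(x)
  cols <- seq_len(w)
  scan1 <- function(s) {
    idx <- match(strsplit(s, "")[[1]], DNA_BASES)
    n <- length(idx)
    if (n < w) return(NA_real_)
    max(vapply(0:(n - w), function(off) {
      b <- idx[off + cols]
      ok <- !is.na(b)
      sum(lo[cbind(b[ok], cols[ok])])
    }, numeric(1)))
  }
  fwd <- scan1(seq)
  if (is.na(fwd)) return(NA_real_)
  max(fwd, scan1(reverse_complement(seq)))
}

#' Extract reference and alternative allele windows around a variant
#'
#' Returns the sequence from `flank` bp upstream through `flank` bp
#' downstream of the variant (truncated at sequence ends), once with the
#' reference allele and once with the alternative allele substituted. For
#' indels the two windows differ in length.
#'
#' @param sequence A character scalar holding the chromosome sequence, or a
#'   named character vector of chromosome sequences.
#' @param variant One-row data frame (`chrom`, `pos` 0-based, `ref`, `alt`).
#' @param flank Flanking bases on each side (default 25).
#' @return List with elements `ref` and `alt`.
#' @export
extract_allele_windows <- function(sequence, variant, flank = 25) {
  seq <- if (length(sequence) > 1 || !is.null(names(sequence))) {
    sequence[[variant$chrom]]
  } else sequence
  n <- nchar(seq)
  pos <- variant$pos # 0-based
  ref <- variant$ref
  alt <- variant$alt
  if (pos < 0 || pos + nchar(ref) > n) stop_invalid("variant outside sequence")
  observed <- substr(seq, pos + 1, pos + nchar(ref))
  if (observed != ref) {
    stop_invalid("reference allele mismatch at position ", pos,
                 ": sequence has ", observed, ", variant says ", ref)
  }
  left <- substr(seq, max(pos - flank, 0) + 1, pos)
  right <- substr(seq, pos + nchar(ref) + 1,
                  min(pos + nchar(ref) + flank, n))
  list(ref = paste0(left, ref, right), alt = paste0(left, alt, right))
}

#' Call motif gains and losses between alleles
#'
#' For each motif, presence in a window means best score strictly greater
#' than `threshold`. A gain is presence in the alternative window only, a
#' loss presence in the reference window only; motifs present or absent in
#' both emit no record.
#'
#' @param library List of [pwm()] objects.
#' @param ref_window,alt_window Allele windows from
#'   [extract_allele_windows()].
#' @param threshold Match-score threshold (default 7.5, strict `>`).
#' @param variant_id Optional id recorded in the output.
#' @return Data frame: `variant_id`, `motif_id`, `direction`
#'   (`"gain"`/`"loss"`), `ref_best`, `alt_best`; sorted by motif id.
#' @export
call_gain_loss <- function(library, ref_window, alt_window, threshold = 7.5,
                           variant_id = NA_character_) {
  rows <- list()
  for (m in library) {
    rb <- pwm_best_score(m, ref_window)
    ab <- pwm_best_score(m, alt_window)
    pres_r <- !is.na(rb) && rb > threshold
    pres_a <- !is.na(ab) && ab > threshold
    if (pres_r == pres_a) next
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = variant_id, motif_id = m$motif_id,
      direction = if (pres_a) "gain" else "loss",
      ref_best = rb, alt_best = ab, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(variant_id = character(), motif_id = character(),
                      direction = character(), ref_best = numeric(),
                      alt_best = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif gain/loss calls for a set of variants
#'
#' @param sequence Chromosome sequence(s) (see [extract_allele_windows()]).
#' @param variants Variant table (`id`, `chrom`, `pos`, `ref`, `alt`).
#' @param library List of [pwm()] objects.
#' @inheritParams call_gain_loss
#' @param flank Flank size in bp.
#' @return Row-bound [call_gain_loss()] records sorted by (variant, motif).
#' @export
scan_variants_motifs <- function(sequence, variants, library,
                                 threshold = 7.5, flank = 25) {
  rows <- lapply(seq_len(nrow(variants)), function(k) {
    v <- variants[k, , drop = FALSE]
    w <- extract_allele_windows(sequence, v, flank = flank)
    call_gain_loss(library, w$ref, w$alt, threshold = threshold,
                   variant_id = v$id)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(variant_id = character(), motif_id = character(),
                      direction = character(), ref_best = numeric(),
                      alt_best = numeric()))
  }
  out <- out[order(out$variant_id, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
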