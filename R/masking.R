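#' Configuration for sliding-window alignment masking
#'
#' The quality filter masks every `window_length`-column window of a
#' multiple sequence alignment that contains more than `max_mismatches`
#' mismatching columns (gaps are not counted as mismatches and are
#' themselves replaced by `mask_char`), and drops an alignment outright
#' once more than `drop_fraction` of its columns have been masked. The
#' defaults — 15 bp windows, more than six mismatches, more than 20%
#' masked — give the filter its conventional phylogenomic form.
#'
#' @param window_length Window size in columns (default 15).
#' @param max_mismatches Largest tolerated mismatch count per window
#'   (default 6; a window is masked only when the count *exceeds* this).
#' @param drop_fraction Masked-column proportion above which the alignment
#'   is dropped (default 0.20; strict inequality).
#' @param mask_char Symbol written over masked residues (default `"N"`).
#' @param step Window step in columns (default 1).
#' @param mismatch_mode `"column"` (default) counts each variable column as
#'   one mismatch, reading "mismatch among all species" as a column
#'   property; `"pairwise"` counts, per column, every unordered pair of
#'   rows that disagree — a stricter tally exposed for sensitivity
#'   analysis.
#' @return A `masking_config` object.
#' @export
masking_config <- function(window_length = 15, max_mismatches = 6,
                           drop_fraction = 0.20, mask_char = "N",
                           step = 1, mismatch_mode = c("column", "pairwise")) {
  check_scalar(window_length, "window_length", lower = 1, integer = TRUE)
  check_scalar(max_mismatches, "max_mismatches", lower = 0, integer = TRUE)
  if (mismatch_mode[1] == "column" && max_mismatches > window_length) {
    stop("field 'max_mismatches' cannot exceed window_length", call. = FALSE)
  }
  check_scalar(drop_fraction, "drop_fraction", lower = 0, upper = 1)
  check_scalar(step, "step", lower = 1, integer = TRUE)
  if (!is.character(mask_char) || nchar(mask_char[1]) != 1L) {
    stop("field 'mask_char' must be a single character", call. = FALSE)
  }
  mismatch_mode <- match.arg(mismatch_mode)
  structure(
    list(window_length = as.integer(window_length),
         max_mismatches = as.integer(max_mismatches),
         drop_fraction = drop_fraction, mask_char = mask_char[1],
         step = as.integer(step), mismatch_mode = mismatch_mode),
    class = "masking_config"
  )
}

#' Count mismatching columns in an alignment slice
#'
#' A column mismatches when at least two of its non-gap, non-masked
#' characters differ; gaps and mask symbols are ignored ("not counting
#' indels/gaps"), so a column that is constant apart from gaps contributes
#' nothing.
#'
#' @param alignment_slice Character matrix (rows = sequences, columns =
#'   sites); at least two rows.
#' @param config A [masking_config()]; `mismatch_mode` selects the
#'   column-wise (default) or pairwise tally.
#' @return Integer mismatch count for the slice.
#' @examples
#' slice <- rbind(s1 = c("A", "C", "G"), s2 = c("A", "T", "G"))
#' count_window_mismatches(slice)
#' @export
count_window_mismatches <- function(alignment_slice, config = masking_config()) {
  m <- as_alignment_matrix(alignment_slice)
  if (nrow(m) < 2L) {
    stop("alignment slice must have at least 2 rows", call. = FALSE)
  }
  sum(column_mismatches(m, config))
}

## Per-column mismatch contribution for a character matrix. Vectorized:
## per-character count profiles via colSums rather than a per-column loop.
column_mismatches <- function(m, config) {
  miss <- is_missing_char(m, config$mask_char)
  alphabet <- setdiff(unique(as.vector(m)), c("-", config$mask_char, "?", "n"))
  n_nonmiss <- colSums(!miss)
  if (length(alphabet) == 0) return(integer(ncol(m)))
  counts <- vapply(alphabet, function(ch) colSums(m == ch & !miss),
                   numeric(ncol(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1) # single column
  n_alleles <- rowSums(counts > 0)
  if (config$mismatch_mode == "column") {
    as.integer(n_alleles > 1 & n_nonmiss >= 2)
  } else {
    as.integer((n_nonmiss * (n_nonmiss - 1) - rowSums(counts * (counts - 1))) / 2)
  }
}

#' Mask low-quality windows of an alignment
#'
#' Slides a window across the alignment (step `config$step`); every window
#' whose mismatch count exceeds `config$max_mismatches` has all of its
#' columns masked in all rows. Gap characters are replaced by the mask
#' symbol throughout, but only window-masked columns count towards
#' `masked_fraction`. The alignment is flagged `dropped` when
#' `masked_fraction > drop_fraction`.
#'
#' @param alignment Character matrix of aligned sequences (equal-length
#'   rows), or a `Biostrings::DNAStringSet`.
#' @param config A [masking_config()].
#' @return A `masked_alignment` object: list with `sequences` (masked
#'   character matrix), `masked_fraction`, `dropped`, and `masked_columns`
#'   (logical per column).
#' @examples
#' aln <- rbind(s1 = strsplit("ACGTACGTACGTACG", "")[[1]],
#'              s2 = strsplit("ACGTACGTACGTACG", "")[[1]])
#' mask_alignment(aln)$masked_fraction
#' @export
mask_alignment <- function(alignment, config = masking_config()) {
  m <- as_alignment_matrix(alignment)
  if (any(is.na(m))) stop("alignment is ragged (unequal row lengths)", call. = FALSE)
  L <- ncol(m)
  if (L < config$window_length) {
    stop("alignment shorter than the masking window", call. = FALSE)
  }
  mm <- column_mismatches(m, config)
  starts <- seq.int(1L, L - config$window_length + 1L, by = config$step)
  masked_cols <- rep(FALSE, L)
  ## cumulative sums give each window's mismatch total in O(1)
  cs <- c(0L, cumsum(mm))
  for (s in starts) {
    e <- s + config$window_length - 1L
    if (cs[e + 1L] - cs[s] > config$max_mismatches) {
      masked_cols[s:e] <- TRUE
    }
  }
  out <- m
  out[, masked_cols] <- config$mask_char
  out[is_missing_char(out, config$mask_char)] <- config$mask_char
  structure(
    list(sequences = out,
         masked_fraction = mean(masked_cols),
         dropped = mean(masked_cols) > config$drop_fraction,
         masked_columns = masked_cols),
    class = "masked_alignment"
  )
}

#' @export
print.masked_alignment <- function(x, ...) {
  cat(sprintf("<masked_alignment> %d x %d, %.1f%% masked%s\n",
              nrow(x$sequences), ncol(x$sequences),
              100 * x$masked_fraction,
              if (x$dropped) " (dropped)" else ""))
  invisible(x)
}

#' Mask a table of loci and report per-locus outcomes
#'
#' Data-frame front end to [mask_alignment()]: applies the window filter to
#' every alignment in a loci table and records the masked fraction and the
#' drop decision per locus.
#'
#' @param loci Tibble with `locus_id` and an `alignment` list-column.
#' @param config A [masking_config()].
#' @return `loci` with `alignment` replaced by its masked version and new
#'   columns `masked_fraction` and `dropped`.
#' @export
mask_loci <- function(loci, config = masking_config()) {
  if (!is.data.frame(loci) || !("alignment" %in% names(loci))) {
    stop("'loci' must be a tibble with an 'alignment' list-column", call. = FALSE)
  }
  res <- lapply(loci$alignment, mask_alignment, config = config)
  loci$alignment <- lapply(res, `[[`, "sequences")
  loci$masked_fraction <- vapply(res, `[[`, numeric(1), "masked_fraction")
  loci$dropped <- vapply(res, `[[`, logical(1), "dropped")
  loci
}
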