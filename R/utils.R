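#' @keywords internal
#' @importFrom rlang .data
#' @importFrom tibble tibble
"_PACKAGE"

## Canonical triplet topology labels. "AB|C" means A and B form the cherry
## exclusive of C; the outgroup O roots the triplet.
TRIPLET_TOPOLOGIES <- c("AB|C", "AC|B", "BC|A", "UNRESOLVED")

DNA_BASES <- c("A", "C", "G", "T")

#' Jukes-Cantor distance correction
#'
#' Converts a raw (observed) proportion of differing sites `p` into the
#' expected number of substitutions per site under the one-parameter
#' equal-rates substitution model, `k = -3/4 * log(1 - 4p/3)`.
#'
#' @param p Numeric vector of raw per-site difference proportions in
#'   `[0, 0.75)`. Values at or beyond the model's validity bound 0.75 give
#'   `NA` (the distance is undefined there).
#' @return Numeric vector of corrected distances (substitutions/site).
#'   `jc_correct(0)` is exactly 0, and `jc_correct(p) >= p` elsewhere.
#' @examples
#' jc_correct(c(0, 0.02, 0.3))
#' @export
jc_correct <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 | is.na(p)))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log1p(-4 * p[ok] / 3)
  out
}

## Deterministic per-locus seed stream: a fixed integer hash of
## (master seed, locus index, stage) so that locus i's draws do not depend
## on how many other loci are simulated in the same call. `stage` separates
## the genealogy stream from the sequence stream of the same locus.
derive_seed <- function(seed, index, stage = 0L) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps seeds in integer range
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + as.numeric(index) * 16807 + as.numeric(stage) * 69621) %% m
  as.integer(s)
}

## Validate a named scalar; used by config constructors so that errors name
## the offending field.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("field '%s' must be a single non-missing number", name),
         call. = FALSE)
  }
  if (integer && x != as.integer(x)) {
    stop(sprintf("field '%s' must be an integer", name), call. = FALSE)
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    stop(sprintf("field '%s' out of range", name), call. = FALSE)
  }
  invisible(x)
}

## Is the character missing for comparison purposes (gap or mask symbol)?
is_missing_char <- function(x, mask_char = "N") {
  x == "-" | x == mask_char | x == "?" | x == "n"
}

as_alignment_matrix <- function(x) {
  if (is.matrix(x) && is.character(x)) {
    return(x)
  }
  if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet")) {
    w <- Biostrings::width(x)
    if (length(unique(w)) != 1L) stop("sequences have unequal lengths", call. = FALSE)
    m <- t(vapply(as.character(x), function(s) strsplit(s, "")[[1]],
                  character(w[1])))
    rownames(m) <- names(x)
    return(toupper(m))
  }
  stop("alignment must be a character matrix or a DNAStringSet", call. = FALSE)
}
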