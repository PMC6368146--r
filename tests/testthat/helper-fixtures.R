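# Fixtures built in code: small alignments, trees, and an independent
# brute-force reimplementation of the window-masking filter used as an
# oracle against the package implementation.

aln_rows <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- if (!is.null(names(rows))) names(rows) else
    paste0("s", seq_along(rows))
  m
}

quartet_aln <- function(a, b, c, o) aln_rows(A = a, B = b, C = c, O = o)

newick <- function(s) ape::read.tree(text = s)

random_alignment <- function(n_rows, n_cols, gap_prob = 0.05) {
  m <- matrix(sample(c("A", "C", "G", "T"), n_rows * n_cols, replace = TRUE),
              nrow = n_rows)
  gaps <- matrix(stats::runif(n_rows * n_cols) < gap_prob, nrow = n_rows)
  m[gaps] <- "-"
  rownames(m) <- paste0("s", seq_len(n_rows))
  m
}

# Literal reimplementation of the masking rule, column by column and
# window by window, with no shared code with mask_alignment().
mask_oracle <- function(m, window = 15, max_mm = 6, drop = 0.2, step = 1,
                        mask_char = "N") {
  missing_chars <- c("-", mask_char, "?", "n")
  L <- ncol(m)
  col_variable <- function(j) {
    ch <- m[, j]
    ch <- ch[!(ch %in% missing_chars)]
    length(ch) >= 2 && length(unique(ch)) >= 2
  }
  masked <- rep(FALSE, L)
  for (s in seq(1, L - window + 1, by = step)) {
    cols <- s:(s + window - 1)
    if (sum(vapply(cols, col_variable, logical(1))) > max_mm) {
      masked[cols] <- TRUE
    }
  }
  out <- m
  out[, masked] <- mask_char
  out[out %in% missing_chars] <- mask_char
  list(sequences = out, masked_fraction = mean(masked),
       dropped = mean(masked) > drop)
}
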