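# BLOSUM62 lookup with a zero-scoring pad character.
#
# The substitution matrix itself comes from Biostrings (the standard NCBI
# half-bit table, including the ambiguity rows B, Z, X).  Windows that run
# over a protein terminus are padded; the pad character scores 0 against
# everything, so truncated windows are neither rewarded nor punished.

blosum_env <- new.env(parent = emptyenv())

# 25 x 25 Biostrings table augmented with a zero pad row/column
blosum62_table <- function(pad = "X") {
  key <- paste0("tab_", pad)
  if (is.null(blosum_env[[key]])) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    b <- e$BLOSUM62
    if (pad %in% rownames(b)) {
      # pad rule takes precedence: that letter now scores 0 everywhere
      b[pad, ] <- 0L
      b[, pad] <- 0L
    } else {
      b <- rbind(cbind(b, 0L), 0L)
      rownames(b)[nrow(b)] <- pad
      colnames(b)[ncol(b)] <- pad
    }
    blosum_env[[key]] <- b
  }
  blosum_env[[key]]
}

# windows -> integer matrix (n x width) of row indices into the table
encode_windows <- function(windows, tab, width = 15L) {
  n <- length(windows)
  len <- nchar(windows)
  if (any(len != width)) {
    abort(sprintf(
      "all windows must have length %d; offending window(s): %s",
      width, paste(utils::head(windows[len != width], 3), collapse = ", ")
    ), class = "kinsub_dimension_error")
  }
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, ncol = width, byrow = TRUE)
  idx <- match(chars, rownames(tab))
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    abort(sprintf("unknown residue code(s): %s", paste(bad, collapse = ", ")),
          class = "kinsub_lookup_error")
  }
  matrix(idx, nrow = n, ncol = width)
}

#' Positionwise BLOSUM62 similarity of two phosphosite windows
#'
#' Scores two aligned 15-residue windows as the sum over positions of the
#' BLOSUM62 substitution score of the residue pair.  Positions where either
#' window carries the pad character contribute 0.
#'
#' @param w1,w2 Character scalars: aligned windows of equal length
#'   (15 residues by default), uppercase one-letter amino-acid codes.
#'   Ambiguity codes B and Z use their standard BLOSUM62 rows.
#' @param pad Pad character used at protein termini; scores 0 against every
#'   residue (default `"X"`; note that with this default a genuine X
#'   ambiguity residue also scores 0).
#' @param width Required window length (default 15).
#' @return A single numeric raw similarity score (unnormalized, can be
#'   negative).
#' @examples
#' blosum_window_similarity("AAAAAAASAAAAAAA", "AAAAAAASAAAAAAA")  # 60
#' @export
blosum_window_similarity <- function(w1, w2, pad = "X", width = 15L) {
  tab <- blosum62_table(pad)
  i <- encode_windows(c(w1, w2), tab, width)
  sum(tab[cbind(i[1, ], i[2, ])])
}

# dense raw score matrix between two window sets (symmetric when b missing)
blosum_raw_matrix <- function(windows_a, windows_b = NULL, pad = "X",
                              width = 15L) {
  tab <- blosum62_table(pad)
  ia <- encode_windows(windows_a, tab, width)
  ib <- if (is.null(windows_b)) ia else encode_windows(windows_b, tab, width)
  s <- matrix(0, nrow(ia), nrow(ib))
  for (k in seq_len(width)) {
    s <- s + tab[ia[, k], ib[, k], drop = FALSE]
  }
  dimnames(s) <- list(names(windows_a) %||% rownames(ia),
                      if (is.null(windows_b)) names(windows_a) else names(windows_b))
  s
}
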