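# Fixed residue alphabets used throughout the package.
#
# The 20 standard amino acids are kept in alphabetical order of their
# one-letter codes, with the dummy padding residue "X" always last.  Every
# encoder, profile reader and serialized model refers to this single order.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.PAD <- "X"

.AA21 <- c(.AA20, .PAD)

# Column order used by PSI-BLAST ascii PSSM files; profile readers/writers
# translate between this and the internal alphabetical order.
.PSIBLAST_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")

#' Residue alphabet used for feature encoding
#'
#' Returns the fixed residue order that every encoder and trained model in
#' this package uses: the 20 standard amino acids in alphabetical order of
#' their one-letter codes, optionally followed by the dummy terminal-padding
#' residue \code{"X"} as the 21st symbol.
#'
#' @param include_pad logical; if \code{TRUE} (default) append the padding
#'   symbol \code{"X"} as the last letter.
#' @return character vector of length 20 or 21.
#' @examples
#' aa_alphabet()        # 21 letters, "A" first, "X" last
#' aa_alphabet(FALSE)   # the 20 standard amino acids
#' @export
aa_alphabet <- function(include_pad = TRUE) {
  if (include_pad) .AA21 else .AA20
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards.  Seeds are mandatory arguments across the package; no function
# mutates the global stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Coerce a label vector (0/1 numeric, logical, or "positive"/"negative"
# character/factor) to integer 0/1.
as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    ok <- labels %in% c("positive", "negative")
    if (!all(ok)) {
      stop("character labels must be 'positive' or 'negative'; got: ",
           paste(unique(labels[!ok]), collapse = ", "))
    }
    return(as.integer(labels == "positive"))
  }
  labels <- as.integer(labels)
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1)")
  }
  labels
}
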