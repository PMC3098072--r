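# Feature encoding: one-hot ("binary") window vectors and normalized PSSM
# profile vectors.  Every encoding of an L-residue window has length L x 21
# (357 for the default 17-residue window), one 21-entry block per position
# in the fixed alphabet order of aa_alphabet().

#' One-hot encode a window string
#'
#' Each window position becomes a 21-entry indicator block in the fixed
#' alphabet order (A first, the dummy padding residue X last), concatenated
#' into a single vector of length \code{nchar(window) * 21}.
#'
#' @param window string over the 21-letter alphabet (20 amino acids + X).
#' @return numeric 0/1 vector of length \code{nchar(window) * 21}; every
#'   21-block sums to exactly 1.
#' @examples
#' binary_encode("A")[1:21]  # 1, then twenty 0s
#' length(binary_encode(strrep("G", 17)))  # 357
#' @export
binary_encode <- function(window) {
  stopifnot(is.character(window), length(window) == 1L, nchar(window) > 0L)
  letters <- strsplit(window, "", fixed = TRUE)[[1]]
  idx <- match(letters, .AA21)
  if (anyNA(idx)) {
    stop("window contains letter(s) outside the 21-letter alphabet: ",
         paste(unique(letters[is.na(idx)]), collapse = ", "))
  }
  v <- numeric(length(letters) * 21L)
  v[(seq_along(letters) - 1L) * 21L + idx] <- 1
  v
}

#' Normalize a raw PSSM to a [0,1] profile
#'
#' Applies the elementwise logistic transform \eqn{1/(1+e^{-x})} to the raw
#' integer log-odds scores and appends an all-zero 21st column for the dummy
#' padding residue X.  The logistic is dataset-independent (unlike min-max
#' scaling it cannot leak information across cross-validation folds) and
#' strictly monotone, so score ordering is preserved.
#'
#' @param raw a \code{pssm_raw} object from \code{\link{read_psiblast_pssm}}
#'   or \code{\link{generate_profile}}, or a plain N x 20 numeric matrix with
#'   columns in alphabetical residue order.
#' @param method "logistic" (default) or "minmax" (columnwise-free global
#'   min-max over the matrix).
#' @return object of class \code{pssm_profile}: list with \code{chain_id},
#'   \code{residues} and \code{matrix} (N x 21, values in [0,1], X column
#'   all zero).
#' @examples
#' normalize_pssm(matrix(0L, 1, 20))$matrix[1, 1:3]  # 0.5 0.5 0.5
#' @export
normalize_pssm <- function(raw, method = c("logistic", "minmax")) {
  method <- match.arg(method)
  if (inherits(raw, "pssm_raw")) {
    chain_id <- raw$chain_id
    residues <- raw$residues
    m <- raw$scores
  } else {
    chain_id <- NA_character_
    residues <- NULL
    m <- raw
  }
  stopifnot(is.matrix(m), ncol(m) == 20L)
  m <- switch(method,
    logistic = 1 / (1 + exp(-m)),
    minmax = if (diff(range(m)) == 0) matrix(0.5, nrow(m), ncol(m))
             else (m - min(m)) / (max(m) - min(m)))
  m <- cbind(m, 0)
  colnames(m) <- .AA21
  structure(list(chain_id = chain_id, residues = residues, matrix = m,
                 normalization = method),
            class = "pssm_profile")
}

#' PSSM-encode a single pattern
#'
#' For each window position the corresponding row of the normalized profile
#' is taken; terminal-padding positions (X) contribute an all-zero 21-entry
#' block, so padding stays distinguishable from a raw log-odds score of 0
#' (which the logistic maps to 0.5).  Blocks are concatenated into a vector
#' of length L x 21, identical in layout to \code{\link{binary_encode}}.
#'
#' @param profile a \code{pssm_profile} for the pattern's chain.
#' @param pattern one row of a pattern data frame (see
#'   \code{\link{extract_patterns}}).
#' @return numeric vector of length \code{pattern$L * 21}, values in [0,1].
#' @export
pssm_encode <- function(profile, pattern) {
  stopifnot(inherits(profile, "pssm_profile"),
            is.data.frame(pattern), nrow(pattern) == 1L)
  n <- nrow(profile$matrix)
  L <- pattern$L
  left <- (L - pattern$k) %/% 2L
  chain_pos <- pattern$center_start - left + seq_len(L) - 1L
  if (pattern$center_start + pattern$k - 1L > n) {
    stop("pattern center (", pattern$center_start, "+", pattern$k - 1L,
         ") lies beyond profile length ", n,
         " for chain '", pattern$chain_id, "'")
  }
  v <- numeric(L * 21L)
  inside <- chain_pos >= 1L & chain_pos <= n
  for (j in which(inside)) {
    v[((j - 1L) * 21L + 1L):(j * 21L)] <- profile$matrix[chain_pos[j], ]
  }
  v
}

#' Encode a set of patterns as a feature matrix
#'
#' @param patterns pattern data frame (single technique/window length), or a
#'   \code{pattern_dataset}.
#' @param encoding "binary" (one-hot) or "pssm".
#' @param profiles for \code{encoding = "pssm"}: named list of
#'   \code{pssm_profile} objects keyed by chain id.
#' @return numeric matrix with one row per pattern and \code{L * 21}
#'   columns, plus attribute \code{"labels"} (character vector) when the
#'   patterns carry labels.
#' @export
encode_patterns <- function(patterns, encoding = c("binary", "pssm"),
                            profiles = NULL) {
  encoding <- match.arg(encoding)
  if (inherits(patterns, "pattern_dataset")) patterns <- patterns$patterns
  stopifnot(is.data.frame(patterns), nrow(patterns) > 0L)
  L <- unique(patterns$L)
  if (length(L) != 1L) stop("patterns mix window lengths: ",
                            paste(L, collapse = ", "))
  if (encoding == "binary") {
    x <- t(vapply(patterns$window, binary_encode, numeric(L * 21L),
                  USE.NAMES = FALSE))
  } else {
    if (is.null(profiles)) stop("PSSM encoding requires 'profiles'")
    x <- matrix(0, nrow(patterns), L * 21L)
    for (i in seq_len(nrow(patterns))) {
      id <- patterns$chain_id[i]
      prof <- profiles[[id]]
      if (is.null(prof)) stop("no PSSM profile supplied for chain '", id, "'")
      x[i, ] <- pssm_encode(prof, patterns[i, , drop = FALSE])
    }
  }
  if (!is.null(patterns$label)) attr(x, "labels") <- patterns$label
  x
}

#' Export an encoded dataset as a dense TSV
#'
#' One row per pattern: the label in the first column, then the L x 21
#' feature values.  Useful for interop with external SVM tools.
#'
#' @inheritParams encode_patterns
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_feature_tsv <- function(patterns, encoding = c("binary", "pssm"),
                              profiles = NULL, path) {
  x <- encode_patterns(patterns, encoding, profiles)
  labels <- attr(x, "labels")
  if (is.null(labels)) labels <- rep(NA_character_, nrow(x))
  utils::write.table(data.frame(label = labels, x, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
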