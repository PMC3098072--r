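# Window-pattern generation around single residues (SRT), dipeptides (DPT)
# and tripeptides (TPT), and assembly of balanced ("main") or naturally
# imbalanced ("realistic") pattern datasets.

# Default window length per technique and the center width k.
technique_params <- function(technique, L = NULL) {
  technique <- match.arg(technique, c("SRT", "DPT", "TPT"))
  k <- switch(technique, SRT = 1L, DPT = 2L, TPT = 3L)
  if (is.null(L)) L <- switch(technique, SRT = 17L, DPT = 16L, TPT = 17L)
  L <- as.integer(L)
  if (L < k) stop("window length L = ", L, " is shorter than center width k = ", k)
  list(technique = technique, L = L, k = k,
       left = (L - k) %/% 2L,           # residues left of the center block
       pad = pad_amounts(L))
}

# Padding per terminus for a window of length L: (L-1)/2 on each side for
# odd L; for even L one fewer at the N-terminus (L/2 - 1) than at the
# C-terminus (L/2), so every adjacent pair owns a full window.
pad_amounts <- function(L) {
  L <- as.integer(L)
  if (L < 1L) stop("window length must be >= 1")
  if (L %% 2L == 1L) c(n = (L - 1L) %/% 2L, c = (L - 1L) %/% 2L)
  else c(n = L %/% 2L - 1L, c = L %/% 2L)
}

#' Pad a sequence with terminal dummy residues
#'
#' Adds the dummy residue "X" at both termini so that every residue
#' (or k-mer) owns a full-length window: for an odd window length L,
#' (L-1)/2 copies per terminus (8 per side for the default L = 17); for an
#' even L, L/2 - 1 at the N-terminus and L/2 at the C-terminus.
#'
#' @param sequence amino-acid string (non-empty).
#' @param L window length.
#' @return the padded string, of length \code{nchar(sequence) + L - 1}.
#' @examples
#' pad_sequence("ACD", 3)   # "XACDX"
#' nchar(pad_sequence("ACD", 17))  # 3 + 16
#' @export
pad_sequence <- function(sequence, L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("cannot pad an empty sequence")
  p <- pad_amounts(L)
  paste0(strrep(.PAD, p[["n"]]), sequence, strrep(.PAD, p[["c"]]))
}

#' Extract overlapping window patterns from a labeled chain
#'
#' Slides a fixed-length window over the padded chain and labels each
#' pattern by its central k residues: k = 1 for the single-residue technique
#' (SRT, window 17), k = 2 for the dipeptide technique (DPT, window 16),
#' k = 3 for the tripeptide technique (TPT, window 17).  A pattern is
#' positive when \emph{all} k center residues are GTP-interacting and
#' negative when all are non-interacting; windows whose center mixes both
#' labels are excluded entirely.
#'
#' A chain of length N therefore yields exactly N SRT patterns, and up to
#' N-1 DPT / N-2 TPT patterns (fewer when mixed-label centers are dropped).
#'
#' @param chain a \code{\link{labeled_chain}}.
#' @param technique one of "SRT", "DPT", "TPT".
#' @param L optional window-length override (defaults: 17, 16, 17).
#' @return data frame with columns \code{technique}, \code{chain_id},
#'   \code{center_start} (1-based position of the first center residue),
#'   \code{k}, \code{L}, \code{label} ("positive"/"negative") and
#'   \code{window} (length-L string over the 21-letter alphabet).
#' @export
extract_patterns <- function(chain, technique = c("SRT", "DPT", "TPT"),
                             L = NULL) {
  stopifnot(inherits(chain, "labeled_chain"))
  tp <- technique_params(match.arg(technique), L)
  n <- nchar(chain$sequence)
  if (n < tp$k) {
    stop("chain '", chain$id, "' (length ", n,
         ") is too short for technique ", tp$technique, " (needs >= ", tp$k, ")")
  }
  padded <- pad_sequence(chain$sequence, tp$L)
  starts <- seq_len(n - tp$k + 1L)
  center_sum <- vapply(starts, function(i) sum(chain$labels[i:(i + tp$k - 1L)]),
                       integer(1))
  keep <- center_sum == 0L | center_sum == tp$k
  starts <- starts[keep]
  if (length(starts) == 0L) {  # every center mixes both labels
    return(data.frame(technique = character(0), chain_id = character(0),
                      center_start = integer(0), k = integer(0),
                      L = integer(0), label = character(0),
                      window = character(0), stringsAsFactors = FALSE))
  }
  # residue i sits at padded index i + pad_n; the window places `left`
  # positions before the center block
  win_from <- starts + tp$pad[["n"]] - tp$left
  windows <- substring(padded, win_from, win_from + tp$L - 1L)
  data.frame(technique = tp$technique,
             chain_id = chain$id,
             center_start = starts,
             k = tp$k,
             L = tp$L,
             label = ifelse(center_sum[keep] == tp$k, "positive", "negative"),
             window = windows,
             stringsAsFactors = FALSE)
}

#' Extract patterns from a list of chains
#'
#' @param chains list of \code{\link{labeled_chain}}.
#' @inheritParams extract_patterns
#' @return row-bound data frame of patterns (see \code{\link{extract_patterns}}).
#' @export
extract_patterns_all <- function(chains, technique = c("SRT", "DPT", "TPT"),
                                 L = NULL) {
  technique <- match.arg(technique)
  do.call(rbind, lapply(chains, extract_patterns, technique = technique, L = L))
}

#' Assemble a main (balanced) or realistic (imbalanced) pattern dataset
#'
#' Duplicate windows are collapsed first: identical (window, technique)
#' pairs keep their first occurrence, and a window that occurs with both
#' labels is removed from both classes with a warning.  The \code{main}
#' regime then pairs all unique positives with an equal-size uniform random
#' sample of the unique negatives.  The \code{realistic} regime keeps all
#' negatives for SRT, and for DPT/TPT samples 10x the positive count (or
#' all negatives, if fewer).  Sampling is deterministic given \code{seed}.
#'
#' @param patterns pattern data frame from \code{\link{extract_patterns}} /
#'   \code{\link{extract_patterns_all}} (a single technique).
#' @param regime "main" or "realistic".
#' @param seed integer seed for negative sampling (mandatory).
#' @return object of class \code{pattern_dataset}: list with
#'   \code{patterns} (data frame, positives first), \code{technique},
#'   \code{regime}, \code{seed}, \code{n_pos}, \code{n_neg}.
#' @export
build_dataset <- function(patterns, regime = c("main", "realistic"), seed) {
  regime <- match.arg(regime)
  stopifnot(is.data.frame(patterns), nrow(patterns) > 0L)
  technique <- unique(patterns$technique)
  if (length(technique) != 1L) {
    stop("build_dataset expects patterns from a single technique; got: ",
         paste(technique, collapse = ", "))
  }
  # dedup identical windows within class, keeping first occurrence
  patterns <- patterns[!duplicated(paste(patterns$window, patterns$label)), ,
                       drop = FALSE]
  pos <- patterns[patterns$label == "positive", , drop = FALSE]
  neg <- patterns[patterns$label == "negative", , drop = FALSE]
  both <- intersect(pos$window, neg$window)
  if (length(both) > 0L) {
    warning(length(both), " window(s) occur in both classes; removed from both")
    pos <- pos[!pos$window %in% both, , drop = FALSE]
    neg <- neg[!neg$window %in% both, , drop = FALSE]
  }
  n_pos <- nrow(pos)
  if (n_pos == 0L) stop("no positive patterns after deduplication")

  n_neg_target <- switch(regime,
    main = n_pos,
    realistic = if (technique == "SRT") nrow(neg) else min(10L * n_pos, nrow(neg)))
  if (regime == "main" && nrow(neg) < n_neg_target) {
    stop("only ", nrow(neg), " unique negative patterns available but ",
         n_neg_target, " required for the main regime; ",
         "use regime = 'realistic' instead")
  }
  neg_keep <- if (n_neg_target == nrow(neg)) neg else
    neg[sort(with_seed(seed, sample.int(nrow(neg), n_neg_target))), , drop = FALSE]

  out <- rbind(pos, neg_keep)
  rownames(out) <- NULL
  structure(list(patterns = out, technique = technique, regime = regime,
                 seed = as.integer(seed), n_pos = n_pos, n_neg = nrow(neg_keep)),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat(sprintf("<pattern_dataset> %s/%s: %d positive, %d negative (seed %d)\n",
              x$technique, x$regime, x$n_pos, x$n_neg, x$seed))
  invisible(x)
}

#' Write a pattern dataset as TSV plus a JSON sidecar
#'
#' @param dataset a \code{pattern_dataset}.
#' @param tsv_path output TSV (technique, chain_id, center_start, label, window).
#' @param json_path output JSON sidecar with regime, seed and counts; defaults
#'   to \code{tsv_path} with extension \code{.json}.
#' @return invisibly, \code{tsv_path}.
#' @export
write_dataset <- function(dataset, tsv_path, json_path = NULL) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  if (is.null(json_path)) json_path <- sub("\\.[^.]*$", ".json", tsv_path)
  cols <- c("technique", "chain_id", "center_start", "label", "window")
  utils::write.table(dataset$patterns[, cols], tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(technique = dataset$technique,
                            regime = dataset$regime, seed = dataset$seed,
                            n_pos = dataset$n_pos, n_neg = dataset$n_neg),
                       json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(tsv_path)
}
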