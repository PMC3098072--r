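# Synthetic benchmark generator: labeled chains carrying a planted
# Walker-A-like nucleotide-binding motif, and simulated evolutionary
# profiles peaked at the interacting positions.  Gives every pipeline stage
# a self-contained, seeded test bed with the statistical structure the
# method assumes (conserved interacting sites on a variable background).

# Approximate background amino-acid frequencies of globular proteins
# (UniProt-like), alphabetical order.
.BG_FREQ <- c(A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86, G = 7.07,
              H = 2.27, I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06,
              P = 4.70, Q = 3.93, R = 5.53, S = 6.64, T = 5.34, V = 6.87,
              W = 1.08, Y = 2.92) / 100

#' Configuration for the synthetic chain/profile generator
#'
#' Each generated chain is drawn from background residue frequencies and
#' receives one (or more) planted copies of a Walker-A-like motif; motif
#' wildcard positions ("X" in the motif string) stay background.  The
#' motif's fixed residues, widened by \code{neighbor_radius} on each side,
#' are labeled GTP-interacting; everything else is non-interacting.
#'
#' @param n_chains number of chains (default 100).
#' @param length_range inclusive chain-length range (default 80-150).
#' @param motif motif string; "X" marks wildcard positions (default
#'   "GXXXXGKT", the canonical P-loop phosphate-binding element).
#' @param neighbor_radius residues on each side of a fixed motif position
#'   that are also labeled interacting (default 1).
#' @param motifs_per_chain planted motif copies per chain (default 1).
#' @param decoys_per_chain additional motif copies per chain that are
#'   \emph{not} labeled interacting and \emph{not} conserved in the
#'   simulated profile (default 1).  Decoys mimic chance occurrences of the
#'   motif string in non-binding contexts, so sequence identity alone
#'   cannot separate the classes while evolutionary conservation can.
#' @param background named length-20 probability vector over the standard
#'   amino acids (alphabetical); defaults to natural frequencies.
#' @param peakedness multiplier (> 0) on the profile log-odds of the true
#'   residue at interacting positions; 1 makes interacting rows
#'   indistinguishable from background rows, larger values make them more
#'   conserved (default 4).
#' @param noise_sd standard deviation of the integer Gaussian noise added
#'   to every profile score (default 1).
#' @param seed integer seed (mandatory).
#' @return object of class \code{generator_config}.
#' @export
generator_config <- function(n_chains = 100L, length_range = c(80L, 150L),
                             motif = "GXXXXGKT", neighbor_radius = 1L,
                             motifs_per_chain = 1L, decoys_per_chain = 1L,
                             background = .BG_FREQ,
                             peakedness = 4, noise_sd = 1, seed) {
  stopifnot(n_chains >= 1L, length(length_range) == 2L,
            length_range[1] <= length_range[2],
            is.character(motif), nchar(motif) >= 1L,
            neighbor_radius >= 0L, motifs_per_chain >= 1L,
            decoys_per_chain >= 0L, peakedness > 0, noise_sd >= 0)
  if (missing(seed)) stop("a seed is mandatory")
  background <- background / sum(background)
  if (length(background) != 20L) stop("background must have 20 entries")
  motif_letters <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(motif_letters), .AA21)
  if (length(bad)) stop("motif contains invalid letter(s): ",
                        paste(bad, collapse = ", "))
  if (nchar(motif) > length_range[1]) {
    stop("motif (", nchar(motif), ") is longer than the minimum chain length (",
         length_range[1], ")")
  }
  structure(list(n_chains = as.integer(n_chains),
                 length_range = as.integer(length_range),
                 motif = toupper(motif),
                 neighbor_radius = as.integer(neighbor_radius),
                 motifs_per_chain = as.integer(motifs_per_chain),
                 decoys_per_chain = as.integer(decoys_per_chain),
                 background = background,
                 peakedness = peakedness, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate labeled synthetic chains
#'
#' Deterministic given the config's seed.  Every chain carries at least one
#' motif instance; labels follow the config's interacting-site rule (fixed
#' motif positions plus \code{neighbor_radius} flanking residues).
#'
#' @param config a \code{\link{generator_config}}.
#' @return list of \code{\link{labeled_chain}} with ids "syn_001", ...
#' @export
generate_chains <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  motif_letters <- strsplit(config$motif, "", fixed = TRUE)[[1]]
  m <- length(motif_letters)
  fixed <- which(motif_letters != .PAD)
  with_seed(config$seed, {
    lapply(seq_len(config$n_chains), function(i) {
      n <- sample(config$length_range[1]:config$length_range[2], 1L)
      seq_letters <- sample(.AA20, n, replace = TRUE, prob = config$background)
      labels <- integer(n)
      for (copy in seq_len(config$motifs_per_chain)) {
        start <- sample.int(n - m + 1L, 1L)
        at <- start + fixed - 1L
        seq_letters[at] <- motif_letters[fixed]
        for (p in at) {
          lo <- max(1L, p - config$neighbor_radius)
          hi <- min(n, p + config$neighbor_radius)
          labels[lo:hi] <- 1L
        }
      }
      # Decoys: chance motif occurrences without binding -- same letters,
      # no interaction labels, and (being label-driven) no conservation in
      # the simulated profile.  Placed clear of labeled residues.
      if (config$decoys_per_chain > 0L) {
        for (copy in seq_len(config$decoys_per_chain)) {
          for (try in 1:25) {
            start <- sample.int(n - m + 1L, 1L)
            span <- start:(start + m - 1L)
            if (!any(labels[span] == 1L)) {
              seq_letters[start + fixed - 1L] <- motif_letters[fixed]
              break
            }
          }
        }
      }
      labeled_chain(sprintf("syn_%03d", i),
                    paste(seq_letters, collapse = ""), labels)
    })
  })
}

#' Generate a simulated raw profile for a chain
#'
#' Emulates an iterative-search evolutionary profile on the integer
#' log-odds scale of the PSI-BLAST ascii dialect (clamped to [-10, 10]):
#' background rows score their own residue at a base log-odds of +2 and all
#' other residues at -1.  At interacting (conserved) positions the row is
#' sharpened by the config's \code{peakedness}: the own-residue score is
#' multiplied by it and the remaining residues are depressed to
#' \code{-round(peakedness)}, mirroring the high information content of a
#' conserved alignment column.  Integer Gaussian noise of sd
#' \code{noise_sd} is then added to every entry.  With peakedness 1 a
#' conserved row is indistinguishable from a background row of the same
#' residue.  The result feeds \code{\link{normalize_pssm}}.
#'
#' @param chain a \code{\link{labeled_chain}}.
#' @param config a \code{\link{generator_config}}.
#' @param seed seed for the profile noise; defaults to the config seed
#'   combined with a hash of the chain id.
#' @return a \code{pssm_raw} object (see \code{\link{read_psiblast_pssm}}).
#' @export
generate_profile <- function(chain, config, seed = NULL) {
  stopifnot(inherits(chain, "labeled_chain"),
            inherits(config, "generator_config"))
  if (is.null(seed)) {
    seed <- (config$seed + sum(utf8ToInt(chain$id))) %% .Machine$integer.max
  }
  letters <- strsplit(chain$sequence, "", fixed = TRUE)[[1]]
  n <- length(letters)
  res_idx <- match(letters, .AA20)
  conserved <- chain$labels == 1L
  off <- ifelse(conserved, -round(config$peakedness), -1)
  scores <- matrix(rep(off, 20L), n, 20L, dimnames = list(NULL, .AA20))
  scores[cbind(seq_len(n), res_idx)] <- ifelse(conserved,
                                               round(2 * config$peakedness), 2)
  if (config$noise_sd > 0) {
    noise <- with_seed(seed, {
      matrix(as.integer(round(stats::rnorm(n * 20L, 0, config$noise_sd))),
             n, 20L)
    })
    scores <- scores + noise
  }
  scores[] <- pmax(pmin(scores, 10L), -10L)
  storage.mode(scores) <- "integer"
  structure(list(chain_id = chain$id, residues = letters, scores = scores),
            class = "pssm_raw")
}

#' Generate profiles for a list of chains
#'
#' @param chains list of \code{\link{labeled_chain}}.
#' @param config a \code{\link{generator_config}}.
#' @param normalized if TRUE (default) return \code{pssm_profile} objects
#'   ready for encoding; otherwise the raw integer profiles.
#' @return named list keyed by chain id.
#' @export
generate_profiles <- function(chains, config, normalized = TRUE) {
  out <- lapply(chains, function(ch) {
    raw <- generate_profile(ch, config)
    if (normalized) normalize_pssm(raw) else raw
  })
  stats::setNames(out, vapply(chains, function(ch) ch$id, ""))
}

#' Write a complete simulated study to disk
#'
#' Emits a FASTA file, the matching label sidecar and one PSI-BLAST-dialect
#' ascii PSSM file per chain (under \code{<dir>/pssm/<id>.pssm}), plus the
#' generator configuration as YAML.
#'
#' @param config a \code{\link{generator_config}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the list of generated chains.
#' @export
write_simulation <- function(config, dir) {
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE, recursive = TRUE)
  chains <- generate_chains(config)
  write_labeled_chains(chains, file.path(dir, "chains.fasta"),
                       file.path(dir, "labels.txt"))
  for (ch in chains) {
    write_psiblast_pssm(generate_profile(ch, config),
                        file.path(dir, "pssm", paste0(ch$id, ".pssm")))
  }
  cfg <- unclass(config)
  cfg$background <- as.list(cfg$background)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(chains)
}
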