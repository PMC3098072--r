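# Input/output of labeled protein chains, PSI-BLAST profiles and
# structure-derived interaction labels.

#' Construct a labeled protein chain
#'
#' A labeled chain couples an amino-acid sequence with a per-residue binary
#' interaction label: 1 marks a GTP-interacting residue, 0 a non-interacting
#' one.  Residue numbering is 1-based and sequential.
#'
#' @param id chain identifier string.
#' @param sequence string over the 20 standard amino-acid one-letter codes
#'   (the padding symbol "X" is never allowed in input chains).
#' @param labels integer/logical vector of 0/1 with one entry per residue.
#' @return an object of class \code{labeled_chain} with fields \code{id},
#'   \code{sequence} and \code{labels}.
#' @examples
#' labeled_chain("c1", "GKT", c(0, 1, 1))
#' @export
labeled_chain <- function(id, sequence, labels) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("chain '", id, "': empty sequence")
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(letters), .AA20)
  if (length(bad) > 0L) {
    stop("chain '", id, "': sequence contains non-standard residue letter(s): ",
         paste(bad, collapse = ", "))
  }
  labels <- as_binary_labels(labels)
  if (length(labels) != nchar(sequence)) {
    stop("chain '", id, "': label length (", length(labels),
         ") does not match sequence length (", nchar(sequence), ")")
  }
  structure(list(id = id, sequence = sequence, labels = labels),
            class = "labeled_chain")
}

#' @export
print.labeled_chain <- function(x, ...) {
  cat(sprintf("<labeled_chain> %s: %d residues, %d interacting\n",
              x$id, nchar(x$sequence), sum(x$labels)))
  invisible(x)
}

#' Read labeled chains from FASTA plus a label sidecar file
#'
#' The sidecar is plain text with one line per chain: the chain id, white
#' space, then a 0/1 string with one digit per residue (1 = GTP-interacting).
#' Every FASTA record must have a matching sidecar line of the same length.
#'
#' @param fasta_path path to a (multi-record) FASTA file.
#' @param labels_path path to the label sidecar.
#' @return list of \code{\link{labeled_chain}}, in FASTA record order.
#' @seealso \code{\link{write_labeled_chains}}
#' @export
read_labeled_chains <- function(fasta_path, labels_path) {
  stopifnot(file.exists(fasta_path), file.exists(labels_path))
  lines <- readLines(fasta_path, warn = FALSE)
  if (!any(startsWith(lines, ">"))) return(list())
  seqs <- seqinr::read.fasta(fasta_path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  lab_lines <- readLines(labels_path, warn = FALSE)
  lab_lines <- lab_lines[nzchar(trimws(lab_lines))]
  toks <- strsplit(trimws(lab_lines), "\\s+")
  bad <- lengths(toks) != 2L
  if (any(bad)) {
    stop("label sidecar '", labels_path, "': malformed line(s): ",
         paste(which(bad), collapse = ", "))
  }
  lab_map <- stats::setNames(vapply(toks, `[[`, "", 2L),
                             vapply(toks, `[[`, "", 1L))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    if (!id %in% names(lab_map)) {
      stop("chain '", id, "': no record in label sidecar '", labels_path, "'")
    }
    lab_str <- lab_map[[id]]
    if (grepl("[^01]", lab_str)) {
      stop("chain '", id, "': label string contains characters other than 0/1")
    }
    labels <- as.integer(strsplit(lab_str, "", fixed = TRUE)[[1]])
    out[[i]] <- labeled_chain(id, toupper(seqs[[i]]), labels)
  }
  out
}

#' Write labeled chains as FASTA plus a label sidecar file
#'
#' @param chains list of \code{\link{labeled_chain}}.
#' @param fasta_path,labels_path output paths.
#' @return invisibly, the list of chains.
#' @export
write_labeled_chains <- function(chains, fasta_path, labels_path) {
  stopifnot(is.list(chains))
  seqinr::write.fasta(sequences = lapply(chains, function(ch) ch$sequence),
                      names = vapply(chains, function(ch) ch$id, ""),
                      file.out = fasta_path, as.string = TRUE, nbchar = 60)
  writeLines(vapply(chains, function(ch) {
    paste(ch$id, paste(ch$labels, collapse = ""))
  }, ""), labels_path)
  invisible(chains)
}

#' Read a PSI-BLAST ascii PSSM file
#'
#' Parses the dialect written by \code{psiblast -out_ascii_pssm}: three
#' header lines (a blank line, a title, and the column-letter header),
#' followed by one row per residue carrying the residue index, the residue
#' letter, 20 integer log-odds columns and then weighted-frequency columns,
#' which are ignored.  Columns are reordered from PSI-BLAST order to the
#' package's alphabetical residue order (see \code{\link{aa_alphabet}}).
#'
#' @param pssm_path path to the ascii PSSM file.
#' @param sequence optional chain sequence; if given, the per-row residue
#'   letters must match it exactly.
#' @param chain_id optional identifier stored on the result; defaults to the
#'   file name without extension.
#' @return object of class \code{pssm_raw}: list with \code{chain_id},
#'   \code{residues} (character vector) and \code{scores} (N x 20 integer
#'   matrix, columns in alphabetical order).  Feed to
#'   \code{\link{normalize_pssm}} before encoding.
#' @export
read_psiblast_pssm <- function(pssm_path, sequence = NULL, chain_id = NULL) {
  stopifnot(file.exists(pssm_path))
  if (is.null(chain_id)) {
    chain_id <- sub("\\.[^.]*$", "", basename(pssm_path))
  }
  lines <- readLines(pssm_path, warn = FALSE)
  # Locate the column header: the first line whose leading tokens are 20
  # single amino-acid letters.
  header_at <- NA_integer_
  col_order <- NULL
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) >= 20L && all(toks[1:20] %in% .AA20)) {
      header_at <- i
      col_order <- toks[1:20]
      break
    }
  }
  if (is.na(header_at)) {
    stop("'", pssm_path, "': no PSSM column header found")
  }
  residues <- character(0)
  rows <- list()
  for (i in seq(header_at + 1L, length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break  # blank line terminates the matrix block
    toks <- strsplit(ln, "\\s+")[[1]]
    if (length(toks) < 22L) {
      stop("'", pssm_path, "' line ", i, ": expected index, residue and 20 scores")
    }
    res <- toks[2]
    if (!res %in% .AA20) {
      stop("'", pssm_path, "' line ", i, ": unexpected residue letter '", res, "'")
    }
    vals <- suppressWarnings(as.integer(toks[3:22]))
    if (any(is.na(vals))) {
      stop("'", pssm_path, "' line ", i, ": non-integer log-odds score")
    }
    residues <- c(residues, res)
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L) stop("'", pssm_path, "': no PSSM rows found")
  scores <- do.call(rbind, rows)
  colnames(scores) <- col_order
  scores <- scores[, .AA20, drop = FALSE]
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != length(residues)) {
      stop("'", pssm_path, "': profile has ", length(residues),
           " rows but sequence has ", nchar(sequence), " residues")
    }
    seq_letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
    mism <- which(seq_letters != residues)
    if (length(mism) > 0L) {
      stop("'", pssm_path, "': residue letter mismatch with sequence at position(s) ",
           paste(utils::head(mism, 5), collapse = ", "))
    }
  }
  structure(list(chain_id = chain_id, residues = residues, scores = scores),
            class = "pssm_raw")
}

#' Write a raw PSSM in the PSI-BLAST ascii dialect
#'
#' Emits the same layout \code{read_psiblast_pssm} parses: three header
#' lines, then one row per residue with 20 integer log-odds columns in
#' PSI-BLAST column order followed by 20 zero frequency columns.
#' \code{read_psiblast_pssm(write_psiblast_pssm(x, f))} recovers \code{x}'s
#' scores and residues exactly.
#'
#' @param raw a \code{pssm_raw} object (see \code{\link{read_psiblast_pssm}}).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_psiblast_pssm <- function(raw, path) {
  stopifnot(inherits(raw, "pssm_raw"))
  scores <- raw$scores[, .PSIBLAST_ORDER, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("", con)
  writeLines("Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts", con)
  writeLines(paste0("           ",
                    paste(sprintf("%3s", .PSIBLAST_ORDER), collapse = ""), "  ",
                    paste(sprintf("%3s", .PSIBLAST_ORDER), collapse = "")), con)
  for (i in seq_along(raw$residues)) {
    writeLines(paste0(sprintf("%5d %s ", i, raw$residues[i]),
                      paste(sprintf("%3d", scores[i, ]), collapse = ""), "  ",
                      paste(sprintf("%3d", rep(0L, 20)), collapse = "")), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Derive interaction labels from a PDB structure by distance cutoff
#'
#' Labels a residue as ligand-interacting when any of its heavy (non-hydrogen)
#' atoms lies within \code{cutoff} angstroms of any heavy atom of the named
#' HETATM ligand.  This is a simple geometric contact criterion; the cutoff
#' is exposed because contact-assignment software differs in its definition.
#'
#' @param pdb_path path to a PDB file (ATOM/HETATM records).
#' @param chain chain identifier to extract.
#' @param ligand_code HETATM residue code of the ligand (default "GTP").
#' @param cutoff heavy-atom distance cutoff in angstroms (default 4.0).
#' @return a \code{\link{labeled_chain}} whose id is
#'   \code{"<file>_<chain>"}; residues are numbered sequentially in file
#'   order.  Non-standard residues are skipped with a warning.
#' @export
annotate_from_structure <- function(pdb_path, chain, ligand_code = "GTP",
                                    cutoff = 4.0) {
  stopifnot(file.exists(pdb_path), cutoff >= 0)
  pdb <- bio3d::read.pdb(pdb_path)
  atoms <- pdb$atom
  lig <- atoms[atoms$type == "HETATM" & atoms$resid == ligand_code, , drop = FALSE]
  if (nrow(lig) == 0L) {
    het <- unique(atoms$resid[atoms$type == "HETATM"])
    stop("ligand '", ligand_code, "' not found in '", pdb_path,
         "'; available HET codes: ",
         if (length(het)) paste(het, collapse = ", ") else "(none)")
  }
  prot <- atoms[atoms$type == "ATOM" & atoms$chain == chain, , drop = FALSE]
  if (nrow(prot) == 0L) {
    stop("chain '", chain, "' not found in '", pdb_path, "'; available chains: ",
         paste(unique(atoms$chain[atoms$type == "ATOM"]), collapse = ", "))
  }
  is_h <- function(df) !is.na(df$elesy) & toupper(trimws(df$elesy)) == "H"
  prot <- prot[!is_h(prot), , drop = FALSE]
  lig <- lig[!is_h(lig), , drop = FALSE]

  aa1 <- bio3d::aa321(prot$resid)
  nonstd <- is.na(aa1) | !(aa1 %in% .AA20)
  if (any(nonstd)) {
    skipped <- unique(prot$resid[nonstd])
    warning("chain '", chain, "': skipping non-standard residue(s): ",
            paste(skipped, collapse = ", "))
    prot <- prot[!nonstd, , drop = FALSE]
    aa1 <- aa1[!nonstd]
  }
  if (nrow(prot) == 0L) stop("chain '", chain, "': no standard residues left")

  # sequential residue index in file order (author numbering discarded)
  res_key <- paste(prot$resno, prot$insert)
  res_idx <- match(res_key, unique(res_key))
  n_res <- max(res_idx)
  sequence <- paste(aa1[!duplicated(res_idx)], collapse = "")

  labels <- integer(n_res)
  if (cutoff > 0) {
    px <- as.matrix(prot[, c("x", "y", "z")])
    lx <- as.matrix(lig[, c("x", "y", "z")])
    # squared distance of every protein atom to its nearest ligand atom
    d2 <- vapply(seq_len(nrow(px)), function(i) {
      min(colSums((t(lx) - px[i, ])^2))
    }, numeric(1))
    hit <- unique(res_idx[d2 <= cutoff^2])
    labels[hit] <- 1L
  }
  labeled_chain(paste0(sub("\\.[^.]*$", "", basename(pdb_path)), "_", chain),
                sequence, labels)
}
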