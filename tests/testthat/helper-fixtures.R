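# Shared fixtures and independent oracles for the test suite.
# All fixtures are built in code; nothing is read from disk.

# A tiny deterministic labeled chain with a planted G/K/T-rich island.
toy_chain <- function(id = "toy", sequence = "ACDEFGKTGKTMNPQ",
                      labels = c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0)) {
  labeled_chain(id, sequence, labels)
}

# Separable toy pattern set: positive windows drawn from {G,K,T}, negative
# windows from {A,L,V}.
separable_patterns <- function(n_per_class = 30, L = 17L, seed = 1) {
  gtppred:::with_seed(seed, {
    pos <- replicate(n_per_class,
                     paste(sample(c("G", "K", "T"), L, TRUE), collapse = ""))
    neg <- replicate(n_per_class,
                     paste(sample(c("A", "L", "V"), L, TRUE), collapse = ""))
    data.frame(technique = "SRT", chain_id = "sep",
               center_start = seq_len(2 * n_per_class), k = 1L, L = L,
               label = rep(c("positive", "negative"), each = n_per_class),
               window = c(pos, neg), stringsAsFactors = FALSE)
  })
}

separable_dataset <- function(...) build_dataset(separable_patterns(...),
                                                 "main", seed = 99)

# Separable dataset for the dipeptide/tripeptide techniques (window 16/17).
make_kmer_dataset <- function(technique, n_per_class = 30, seed = 1) {
  L <- if (technique == "DPT") 16L else 17L
  k <- if (technique == "DPT") 2L else 3L
  pats <- separable_patterns(n_per_class, L = L, seed = seed)
  pats$technique <- technique
  pats$k <- k
  build_dataset(pats, "main", seed = 99)
}

# Independent brute-force metric oracle: explicit item-by-item confusion
# counting and direct textbook formulas.  Shares no code with the package.
oracle_metrics <- function(scores, labels, threshold) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(scores)) {
    called_pos <- scores[i] >= threshold
    if (called_pos && labels[i] == 1) tp <- tp + 1
    if (called_pos && labels[i] == 0) fp <- fp + 1
    if (!called_pos && labels[i] == 0) tn <- tn + 1
    if (!called_pos && labels[i] == 1) fn <- fn + 1
  }
  sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else 0
  acc <- 100 * (tp + tn) / (tp + fp + tn + fn)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  list(tp = tp, fp = fp, tn = tn, fn = fn, sensitivity = sn, specificity = sp,
       accuracy = acc, precision = prec, f1 = f1, mcc = mcc)
}

# Count positive k-mer patterns by directly scanning the 0/1 label string
# for runs of k consecutive 1s (the brute-force counting oracle).
oracle_kmer_positives <- function(labels, k) {
  count <- 0
  for (i in seq_len(length(labels) - k + 1)) {
    if (all(labels[i:(i + k - 1)] == 1)) count <- count + 1
  }
  count
}

# Minimal fixed-width PDB writer for structure-annotation tests.
pdb_atom_line <- function(type, serial, name, resn, chain, resno, x, y, z,
                          element) {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, resn, chain, resno, x, y, z, 1.0, 0.0, element)
}

# Toy complex: chain A = GLY/ALA/SER CA atoms on the x axis, one GTP
# phosphorus atom at the origin.  Residue distances to the ligand: 3.5,
# 12.0 and 20.0 angstroms.
write_toy_pdb <- function(path, res_x = c(3.5, 12.0, 20.0)) {
  resn <- c("GLY", "ALA", "SER")
  lines <- character(0)
  for (i in seq_along(res_x)) {
    lines <- c(lines, pdb_atom_line("ATOM", i, "CA", resn[i], "A", i,
                                    res_x[i], 0, 0, "C"))
  }
  lines <- c(lines,
             pdb_atom_line("HETATM", 10L, "PA", "GTP", "B", 101L, 0, 0, 0, "P"),
             "END")
  writeLines(lines, path)
  path
}

# Small-but-informative generator configuration for pipeline tests.
small_config <- function(seed, n_chains = 20L) {
  generator_config(n_chains = n_chains, length_range = c(60L, 90L), seed = seed)
}

# The 11-row printed ANN threshold-sweep tables (single-sequence and
# PSSM-profile variants) used by the threshold-selection checks.
ann_sweep_single <- function() {
  data.frame(
    threshold = seq(0, 1, by = 0.1),
    sensitivity = c(100, 59.02, 45.78, 36.76, 29.11, 23.29, 18.15, 12.79,
                    8.11, 3.42, 0),
    specificity = c(0, 63.93, 76.83, 83.68, 89.04, 91.89, 94.75, 97.37,
                    98.74, 99.54, 100),
    accuracy = c(50.00, 61.47, 61.3, 60.22, 59.08, 57.59, 56.45, 55.08,
                 53.42, 51.48, 50.00),
    mcc = c(0, 0.23, 0.24, 0.23, 0.23, 0.21, 0.2, 0.19, 0.16, 0.11, 0))
}

ann_sweep_pssm <- function() {
  data.frame(
    threshold = seq(0, 1, by = 0.1),
    sensitivity = c(100, 65.33, 58.58, 53.89, 50.00, 46.80, 42.56, 39.02,
                    32.49, 22.88, 0),
    specificity = c(0, 70.48, 79.18, 82.95, 86.04, 88.33, 90.27, 92.11,
                    95.08, 97.03, 100),
    accuracy = c(50.00, 67.91, 68.88, 68.42, 68.02, 67.56, 66.42, 65.56,
                 63.79, 59.95, 50),
    mcc = c(0, 0.36, 0.39, 0.39, 0.39, 0.39, 0.37, 0.37, 0.35, 0.3, 0))
}
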