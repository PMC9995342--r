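# Independent oracles used across the test suite. These deliberately share
# no code with the package: masses come from elemental formulas and CODATA
# isotope masses, digestion from brute-force substring enumeration.

# -- elemental-composition mass oracle --------------------------------------

element_masses <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
                    O = 15.9949146196, S = 31.97207100)

formula_mass <- function(formula) {
  toks <- regmatches(formula,
                     gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  toks <- toks[nzchar(toks)]
  total <- 0
  for (tok in toks) {
    el <- gsub("[0-9]", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    total <- total + element_masses[[el]] * n
  }
  total
}

# residue (dehydrated) elemental formulas of the 20 canonical amino acids
residue_formulas <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",  T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO", N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",  R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O")

monosaccharide_formulas <- c(
  HexNAc = "C8H13NO5", Hex = "C6H10O5", Fuc = "C6H10O4",
  NeuAc = "C11H17NO8", Acetyl = "C2H2O")

# neutral peptide mass from elemental formulas: residues + one water,
# plus carbamidomethyl (C2H3NO) per cysteine when cam = TRUE
oracle_peptide_mass <- function(sequence, cam = TRUE) {
  res <- strsplit(sequence, "")[[1]]
  m <- sum(vapply(residue_formulas[res], formula_mass, numeric(1))) +
    formula_mass("H2O")
  if (cam) m <- m + sum(res == "C") * formula_mass("C2H3NO")
  m
}

# -- brute-force digestion oracle -------------------------------------------

# every substring that is fully specific at both termini with at most
# max_missed internal cleavable boundaries
oracle_digest <- function(protein, cleave_after, blocked_by_next = "P",
                          max_missed = 2L) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  cleavable <- function(i) {
    i >= 1L && i < n && res[i] %in% cleave_after &&
      !(res[i + 1L] %in% blocked_by_next)
  }
  sites <- Filter(cleavable, seq_len(n))
  rows <- list()
  for (start in seq_len(n)) for (end in start:n) {
    if (!(start == 1L || (start - 1L) %in% sites)) next
    if (!(end == n || end %in% sites)) next
    internal <- sum(sites >= start & sites < end)
    if (internal > max_missed) next
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = paste(res[start:end], collapse = ""),
      start = start, end = end, missed_cleavages = internal,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

# -- small shared fixtures ---------------------------------------------------

target_gp <- function() {
  glycopeptide(peptide("HCSLNENITVPDTK", start = 32L, end = 45L),
               site = 38L, glycan = "_6_7_1_4")
}

random_protein <- function(len) {
  paste(sample(names(episial::amino_acid_masses), len, replace = TRUE),
        collapse = "")
}
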