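# Mass constants and monoisotopic mass arithmetic for peptides, glycans and
# glycopeptides. All masses are monoisotopic and in Dalton.

#' Physical mass constants
#'
#' Monoisotopic mass constants used throughout the package: the mass of a
#' water molecule (added once per peptide chain), the mass of a proton
#' (charge carrier for positive-mode electrospray), and the mass difference
#' between 13C and 12C (isotopologue spacing).
#'
#' @format Named numeric vector with elements `water`, `proton`, `c13_minus_c12`.
#' @export
mass_constants <- c(
  water         = 18.010565,
  proton        = 1.007276,
  c13_minus_c12 = 1.003355
)

#' Monoisotopic residue masses of the 20 canonical amino acids
#'
#' Residue masses (amino acid minus one water, i.e. the mass contributed to a
#' peptide chain). Fixed modifications such as carbamidomethyl-Cys are *not*
#' included here; they are carried by [peptide()] objects.
#'
#' @format Named numeric vector, one element per one-letter residue symbol.
#' @export
amino_acid_masses <- c(
  G =  57.021464, A =  71.037114, S =  87.032028, P =  97.052764,
  V =  99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Monoisotopic residue masses of glycan monosaccharide classes
#'
#' Dehydrated monomer (residue) masses for the monosaccharide classes used to
#' describe N-glycan compositions: N-acetylhexosamine (HexNAc), hexose (Hex),
#' fucose (Fuc, a deoxyhexose), N-acetylneuraminic acid (NeuAc, sialic acid)
#' and an O-acetyl group (Acetyl) occasionally found on sialic acids.
#'
#' @format Named numeric vector, one element per monosaccharide class.
#' @export
monosaccharide_masses <- c(
  HexNAc = 203.079373,
  Hex    = 162.052824,
  Fuc    = 146.057909,
  NeuAc  = 291.095417,
  Acetyl =  42.010565
)

#' Default fixed modifications
#'
#' Carbamidomethylation of cysteine (+57.021464 Da) from chloroacetamide
#' alkylation during sample preparation. This is the package-wide default
#' fixed-modification set.
#'
#' @export
default_fixed_mods <- c(C = 57.021464)

.glycan_classes <- names(monosaccharide_masses)

# ---------------------------------------------------------------------------
# Glycan compositions
# ---------------------------------------------------------------------------

#' Construct a glycan composition
#'
#' A glycan composition is a vector of non-negative residue counts over the
#' monosaccharide classes HexNAc, Hex, Fuc, NeuAc and Acetyl. Order of
#' arguments does not matter; unmentioned classes are zero.
#'
#' @param HexNAc,Hex,Fuc,NeuAc,Acetyl Non-negative integer residue counts.
#' @return An object of class `glycan_composition` (named integer vector).
#' @examples
#' glycan_composition(HexNAc = 6, Hex = 7, Fuc = 1, NeuAc = 4)
#' @export
glycan_composition <- function(HexNAc = 0L, Hex = 0L, Fuc = 0L, NeuAc = 0L,
                               Acetyl = 0L) {
  counts <- c(HexNAc = HexNAc, Hex = Hex, Fuc = Fuc, NeuAc = NeuAc,
              Acetyl = Acetyl)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("glycan composition counts must be non-negative integers")
  structure(as.integer(counts), names = .glycan_classes,
            class = "glycan_composition")
}

#' Parse a glycan composition string
#'
#' Accepts two notations:
#' * parenthesised: `"HexNAc(6)Hex(7)Fuc(1)NeuAc(4)"`
#' * underscore (glycopeptide-name suffix): `"_6_7_1_4"` or `"6_7_1_4"`,
#'   where the digit positions are HexNAc, Hex, Fuc, NeuAc in that order
#'   (a fifth position, if present, is Acetyl).
#'
#' @param text A single composition string in either notation.
#' @return A [glycan_composition()].
#' @examples
#' parse_glycan_composition("HexNAc(6)Hex(7)Fuc(1)NeuAc(4)")
#' parse_glycan_composition("_6_7_1_4")
#' @export
parse_glycan_composition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (grepl("^_?[0-9]+(_[0-9]+)+$", text)) {
    digits <- as.integer(strsplit(sub("^_", "", text), "_", fixed = TRUE)[[1]])
    if (length(digits) < 4L || length(digits) > 5L)
      stop("underscore notation needs 4 (or 5) fields, got ", length(digits),
           " in ", sQuote(text))
    digits <- c(digits, rep(0L, 5L - length(digits)))
    return(glycan_composition(HexNAc = digits[1], Hex = digits[2],
                              Fuc = digits[3], NeuAc = digits[4],
                              Acetyl = digits[5]))
  }
  m <- gregexpr("([A-Za-z]+)\\(([0-9]+)\\)", text, perl = TRUE)[[1]]
  if (m[1] == -1L)
    stop("cannot parse glycan composition ", sQuote(text))
  tokens <- regmatches(text, gregexpr("([A-Za-z]+)\\(([0-9]+)\\)", text))[[1]]
  if (sum(nchar(tokens)) != nchar(text))
    stop("malformed glycan composition ", sQuote(text))
  counts <- stats::setNames(rep(0L, length(.glycan_classes)), .glycan_classes)
  for (tok in tokens) {
    cls <- sub("\\(.*", "", tok)
    n <- as.integer(sub(".*\\(([0-9]+)\\)", "\\1", tok))
    if (!cls %in% .glycan_classes)
      stop("unknown monosaccharide class ", sQuote(cls))
    counts[cls] <- counts[cls] + n
  }
  do.call(glycan_composition, as.list(counts))
}

#' Format a glycan composition
#'
#' @param g A [glycan_composition()].
#' @param notation `"parenthesised"` (default) or `"underscore"`.
#' @return A single character string; the canonical class order is
#'   HexNAc, Hex, Fuc, NeuAc, Acetyl and zero-count classes are omitted in
#'   the parenthesised notation.
#' @export
format_glycan_composition <- function(g, notation = c("parenthesised",
                                                      "underscore")) {
  notation <- match.arg(notation)
  stopifnot(inherits(g, "glycan_composition"))
  if (notation == "underscore") {
    n <- if (g[["Acetyl"]] > 0L) 5L else 4L
    return(paste0("_", paste(unclass(g)[seq_len(n)], collapse = "_")))
  }
  keep <- g > 0L
  if (!any(keep)) return("")
  paste0(names(g)[keep], "(", unclass(g)[keep], ")", collapse = "")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan_composition> ", format_glycan_composition(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a glycan composition
#'
#' Sum of dehydrated-residue masses. No water is added: for a glycan attached
#' to a peptide the reducing end is engaged in the glycosidic bond to Asn.
#'
#' @param g A [glycan_composition()].
#' @return Mass in Da; 0 for the empty composition.
#' @export
glycan_mass <- function(g) {
  stopifnot(inherits(g, "glycan_composition"))
  sum(as.numeric(g) * monosaccharide_masses[names(g)])
}

# ---------------------------------------------------------------------------
# Peptides
# ---------------------------------------------------------------------------

#' Construct a peptide
#'
#' @param sequence Upper-case one-letter amino-acid string (20 canonical
#'   residues).
#' @param fixed_mods Named numeric vector of fixed modification masses keyed
#'   by residue symbol; default carbamidomethyl on Cys.
#' @param start,end 1-based inclusive coordinates in the parent protein
#'   (optional; `NA` when the peptide is free-standing).
#' @param missed_cleavages Number of internal missed cleavage sites
#'   (informational; filled by [digest()]).
#' @return An object of class `peptide`.
#' @export
peptide <- function(sequence, fixed_mods = default_fixed_mods,
                    start = NA_integer_, end = NA_integer_,
                    missed_cleavages = NA_integer_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("peptide sequence must be non-empty")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% names(amino_acid_masses))
  if (length(bad))
    stop("unknown residue symbol ", sQuote(res[bad[1]]),
         " at position ", bad[1], " of ", sQuote(sequence))
  if (!is.na(start) && !is.na(end) && (end - start + 1L) != nchar(sequence))
    stop("start/end coordinates inconsistent with sequence length")
  structure(list(sequence = sequence, fixed_mods = fixed_mods,
                 start = as.integer(start), end = as.integer(end),
                 missed_cleavages = as.integer(missed_cleavages)),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", x$sequence,
      if (!is.na(x$start)) sprintf(" [%d-%d]", x$start, x$end),
      if (!is.na(x$missed_cleavages)) sprintf(" (missed: %d)",
                                              x$missed_cleavages),
      "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue masses plus one water, plus fixed modification masses for
#' every matching residue.
#'
#' @param p A [peptide()] or a plain sequence string (then `fixed_mods`
#'   applies).
#' @param fixed_mods Fixed modifications used when `p` is a string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("G")                 # glycine: 75.03203
#' peptide_mass("HCSLNENITVPDTK")    # carbamidomethyl-Cys included by default
#' @export
peptide_mass <- function(p, fixed_mods = default_fixed_mods) {
  if (is.character(p)) p <- peptide(p, fixed_mods = fixed_mods)
  stopifnot(inherits(p, "peptide"))
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  m <- sum(amino_acid_masses[res]) + mass_constants[["water"]]
  if (length(p$fixed_mods)) {
    hits <- table(res[res %in% names(p$fixed_mods)])
    if (length(hits))
      m <- m + sum(p$fixed_mods[names(hits)] * as.numeric(hits))
  }
  unname(m)
}

# ---------------------------------------------------------------------------
# Glycopeptides
# ---------------------------------------------------------------------------

#' Construct a glycopeptide
#'
#' A peptide carrying a single N-linked glycan at an Asn position. When the
#' peptide carries protein coordinates, `site` is the 1-based protein
#' position of the glycosylated Asn; otherwise it is the 1-based position
#' within the peptide.
#'
#' @param peptide A [peptide()] (or sequence string).
#' @param site Position of the glycosylated Asn (protein coordinates when
#'   available, else peptide coordinates).
#' @param glycan A [glycan_composition()] or a composition string.
#' @return An object of class `glycopeptide`.
#' @export
glycopeptide <- function(peptide, site, glycan) {
  if (is.character(peptide)) peptide <- episial::peptide(peptide)
  if (is.character(glycan)) glycan <- parse_glycan_composition(glycan)
  stopifnot(inherits(peptide, "peptide"), inherits(glycan, "glycan_composition"))
  if (sum(glycan) < 1L)
    stop("an attached glycan must contain at least one residue")
  site <- as.integer(site)
  local_pos <- if (!is.na(peptide$start)) site - peptide$start + 1L else site
  n <- nchar(peptide$sequence)
  if (local_pos < 1L || local_pos > n)
    stop("glycosylation site ", site, " lies outside the peptide")
  res <- strsplit(peptide$sequence, "", fixed = TRUE)[[1]]
  if (res[local_pos] != "N")
    stop("residue at glycosylation site is ", sQuote(res[local_pos]),
         ", expected N")
  # sequon check only when the two following residues are visible
  if (local_pos + 2L <= n) {
    if (res[local_pos + 1L] == "P" || !res[local_pos + 2L] %in% c("S", "T"))
      stop("site ", site, " is not part of an N-X-[S/T] sequon (X != P)")
  }
  structure(list(peptide = peptide, site = site, glycan = glycan),
            class = "glycopeptide")
}

#' @export
print.glycopeptide <- function(x, ...) {
  cat("<glycopeptide> ", x$peptide$sequence,
      format_glycan_composition(x$glycan, "underscore"),
      " (site ", x$site, ")\n", sep = "")
  invisible(x)
}

#' Neutral monoisotopic mass of a glycopeptide
#'
#' Exactly `peptide_mass(peptide) + glycan_mass(glycan)`.
#'
#' @param gp A [glycopeptide()].
#' @return Mass in Da.
#' @export
glycopeptide_mass <- function(gp) {
  stopifnot(inherits(gp, "glycopeptide"))
  peptide_mass(gp$peptide) + glycan_mass(gp$glycan)
}

#' m/z of a (glyco)peptide ion
#'
#' Computes the m/z of the protonated ion at a given charge state and
#' monitored isotopologue. The isotopologue index counts 13C substitutions:
#' index 0 is the monoisotopic peak, index k adds `k * 1.003355` Da to the
#' neutral mass. Targeted SIM assays on large glycopeptides typically centre
#' the quadrupole on an isotopologue above the monoisotopic peak because the
#' isotope envelope maximum moves up with mass.
#'
#' @param gp A [glycopeptide()], [peptide()], or a neutral mass in Da.
#' @param charge Positive integer charge state.
#' @param isotopologue Non-negative integer 13C isotopologue index
#'   (default 0, the monoisotopic peak).
#' @return m/z value.
#' @examples
#' gp <- glycopeptide("HCSLNENITVPDTK", site = 7, glycan = "_6_7_1_4")
#' glycopeptide_mz(gp, charge = 4)                   # monoisotopic, 1323.52
#' glycopeptide_mz(gp, charge = 4, isotopologue = 2) # SIM target, 1324.02
#' @export
glycopeptide_mz <- function(gp, charge, isotopologue = 0L) {
  charge <- as.integer(charge)
  isotopologue <- as.integer(isotopologue)
  if (is.na(charge) || charge < 1L)
    stop("charge must be a positive integer")
  if (is.na(isotopologue) || isotopologue < 0L)
    stop("isotopologue index must be a non-negative integer")
  mass <- if (inherits(gp, "glycopeptide")) glycopeptide_mass(gp)
          else if (inherits(gp, "peptide")) peptide_mass(gp)
          else as.numeric(gp)
  (mass + isotopologue * mass_constants[["c13_minus_c12"]] +
     charge * mass_constants[["proton"]]) / charge
}
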