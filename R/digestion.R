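# In-silico protease digestion, N-glycosylation sequon discovery and
# candidate glycopeptide enumeration.

#' Define an enzyme cleavage rule
#'
#' Cleavage is C-terminal to any residue in `cleave_after`, suppressed when
#' the following residue is in `blocked_by_next` (the classical proline rule).
#'
#' @param name Rule name (informational).
#' @param cleave_after Character vector of residue symbols cleaved after.
#' @param blocked_by_next Character vector of residues that block cleavage
#'   when they follow the cleavage site; usually `"P"` or empty.
#' @param max_missed Maximum number of missed cleavages (non-negative).
#' @return An object of class `enzyme_rule`.
#' @export
enzyme_rule <- function(name, cleave_after, blocked_by_next = character(),
                        max_missed = 2L) {
  stopifnot(length(cleave_after) >= 1L, max_missed >= 0L)
  structure(list(name = name,
                 cleave_after = unique(toupper(cleave_after)),
                 blocked_by_next = unique(toupper(blocked_by_next)),
                 max_missed = as.integer(max_missed)),
            class = "enzyme_rule")
}

#' Preset enzyme rules
#'
#' `"trypsin"` cleaves after K/R, `"gluc"` (Glu-C in ammonium bicarbonate
#' style buffers) after E/D, and `"gluc+trypsin"` models the combined
#' multi-enzyme digest as cleavage after any of E, D, R, K. The proline rule
#' is on by default and can be disabled.
#'
#' @param name One of `"trypsin"`, `"gluc"`, `"gluc+trypsin"`.
#' @param max_missed Maximum missed cleavages (default 2).
#' @param proline_rule Apply the proline blocking rule (default `TRUE`).
#' @return An [enzyme_rule()].
#' @export
enzyme_preset <- function(name = c("gluc+trypsin", "trypsin", "gluc"),
                          max_missed = 2L, proline_rule = TRUE) {
  name <- match.arg(name)
  sites <- switch(name,
                  "trypsin" = c("K", "R"),
                  "gluc" = c("E", "D"),
                  "gluc+trypsin" = c("E", "D", "R", "K"))
  enzyme_rule(name, sites,
              blocked_by_next = if (proline_rule) "P" else character(),
              max_missed = max_missed)
}

# Cleavage boundaries: positions i such that the bond after residue i is cut.
.cleavage_sites <- function(residues, rule) {
  n <- length(residues)
  if (n < 2L) return(integer())
  i <- seq_len(n - 1L)
  hit <- residues[i] %in% rule$cleave_after
  if (length(rule$blocked_by_next))
    hit <- hit & !(residues[i + 1L] %in% rule$blocked_by_next)
  which(hit)
}

#' Digest a protein sequence in silico
#'
#' Produces all fully specific peptides with between 0 and
#' `rule$max_missed` internal missed-cleavage sites. Each peptide carries
#' its 1-based protein coordinates and missed-cleavage count. The
#' 0-missed-cleavage peptides partition the protein. Glycosylation does not
#' alter cleavage: enzymes are applied to the unmodified sequence.
#'
#' @param protein Protein sequence string (upper-case one-letter).
#' @param rule An [enzyme_rule()] or preset name accepted by
#'   [enzyme_preset()].
#' @param fixed_mods Fixed modifications attached to emitted peptides.
#' @return List of [peptide()] objects ordered by start then end.
#' @examples
#' digest("AAKAA", enzyme_preset("trypsin", max_missed = 0))
#' @export
digest <- function(protein, rule = enzyme_preset("gluc+trypsin"),
                   fixed_mods = default_fixed_mods) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (!nzchar(protein)) stop("protein sequence must be non-empty")
  if (is.character(rule)) rule <- enzyme_preset(rule)
  stopifnot(inherits(rule, "enzyme_rule"))
  protein <- toupper(protein)
  residues <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(residues)
  bounds <- c(0L, .cleavage_sites(residues, rule), n)  # bond indices
  nb <- length(bounds)
  out <- list()
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + rule$max_missed)) {
      start <- bounds[i] + 1L
      end <- bounds[j]
      out[[length(out) + 1L]] <- peptide(
        substr(protein, start, end), fixed_mods = fixed_mods,
        start = start, end = end, missed_cleavages = j - i - 1L)
    }
  }
  out
}

#' Export a peptide list as a table
#'
#' @param peptides List of [peptide()] objects, e.g. from [digest()].
#' @return `data.frame` with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`, `mass`.
#' @export
peptide_table <- function(peptides) {
  data.frame(
    sequence = vapply(peptides, function(p) p$sequence, character(1)),
    start = vapply(peptides, function(p) p$start, integer(1)),
    end = vapply(peptides, function(p) p$end, integer(1)),
    missed_cleavages = vapply(peptides, function(p) p$missed_cleavages,
                              integer(1)),
    mass = vapply(peptides, peptide_mass, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Find N-glycosylation sequons
#'
#' Reports every N-X-\[S/T\] motif (X any residue except proline) as a
#' candidate N-glycosylation site.
#'
#' @param protein Protein sequence string.
#' @return `data.frame` with columns `position` (1-based Asn index) and
#'   `sequon` (the 3-residue motif); zero rows when none found.
#' @examples
#' find_sequons("NIT")   # position 1
#' find_sequons("NPT")   # none: proline blocks
#' @export
find_sequons <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  protein <- toupper(protein)
  m <- gregexpr("N(?=[^P][ST])", protein, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(position = integer(), sequon = character(),
                      stringsAsFactors = FALSE))
  pos <- as.integer(m)
  data.frame(position = pos,
             sequon = substring(protein, pos, pos + 2L),
             stringsAsFactors = FALSE)
}

#' Enumerate candidate glycopeptides
#'
#' Crosses peptides that cover an annotated glycosylation site with a list
#' of glycan compositions. Sites covered by no peptide are reported via the
#' `uncovered_sites` attribute (and a warning), never dropped silently.
#'
#' @param peptides List of [peptide()] objects with protein coordinates.
#' @param sites Integer vector of 1-based Asn protein positions, or the
#'   `data.frame` returned by [find_sequons()].
#' @param glycans List of [glycan_composition()] objects or composition
#'   strings.
#' @return List of [glycopeptide()] objects with attribute
#'   `uncovered_sites`.
#' @export
enumerate_candidates <- function(peptides, sites, glycans) {
  if (is.data.frame(sites)) sites <- sites$position
  if (!length(glycans)) stop("glycan list must be non-empty")
  glycans <- lapply(glycans, function(g)
    if (is.character(g)) parse_glycan_composition(g) else g)
  out <- list()
  covered <- logical(length(sites))
  for (p in peptides) {
    if (is.na(p$start)) next
    for (k in seq_along(sites)) {
      s <- sites[k]
      if (s >= p$start && s <= p$end) {
        covered[k] <- TRUE
        for (g in glycans)
          out[[length(out) + 1L]] <- glycopeptide(p, site = s, glycan = g)
      }
    }
  }
  uncovered <- sites[!covered]
  if (length(uncovered))
    warning("glycosylation site(s) not covered by any peptide: ",
            paste(uncovered, collapse = ", "))
  attr(out, "uncovered_sites") <- uncovered
  out
}

# ---------------------------------------------------------------------------
# FASTA input and the packaged EPO sequence
# ---------------------------------------------------------------------------

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] returning plain
#' character sequences.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names from headers).
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(toupper(as.character(aa)), names(aa))
}

#' Mature human erythropoietin sequence
#'
#' The 165-residue mature chain of human erythropoietin (signal peptide and
#' C-terminal arginine removed, as in the circulating and recombinant
#' protein), read from the packaged FASTA fixture. Numbering of the
#' N-glycosylation sites on this chain is Asn24, Asn38 and Asn83.
#'
#' @return Single character string of length 165.
#' @export
epo_mature_sequence <- function() {
  path <- system.file("extdata", "epo_mature.fasta", package = "episial",
                      mustWork = TRUE)
  unname(read_protein_fasta(path)[1])
}
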