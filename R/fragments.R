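# Fragment-ion generation: oxonium diagnostics, peptide backbone b/y series,
# glycan-trimmed Y-ladder ions, isotopologue clusters, and transition lists.

.fragment_ion <- function(kind, label, mz, charge = 1L, index = NA_integer_) {
  data.frame(kind = kind, label = label, mz = mz, charge = as.integer(charge),
             index = as.integer(index), stringsAsFactors = FALSE)
}

.empty_fragments <- function() {
  data.frame(kind = character(0), label = character(0), mz = numeric(0),
             charge = integer(0), index = integer(0),
             stringsAsFactors = FALSE)
}

#' Diagnostic oxonium ions of a glycan composition
#'
#' Singly protonated low-mass glycan fragments: one ion per monosaccharide
#' class present, the water-loss ion of NeuAc, and the di-/tri-saccharide
#' combinations HexNAc+Hex and HexNAc+Hex+NeuAc when the composition allows
#' them. Ions are named by their computed composition. (Published transition
#' tables occasionally carry informal labels for these masses; this package
#' always labels by composition: 204.087 is the HexNAc oxonium, 366.139 is
#' HexNAc+Hex, and so on.)
#'
#' @param g A [glycan_composition()] or composition string.
#' @return `data.frame` of fragment ions (kind `"oxonium"`), columns
#'   `kind`, `label`, `mz`, `charge`, `index`. Empty composition gives zero
#'   rows.
#' @examples
#' oxonium_ions("_6_7_1_4")
#' @export
oxonium_ions <- function(g) {
  if (is.character(g)) g <- parse_glycan_composition(g)
  stopifnot(inherits(g, "glycan_composition"))
  proton <- mass_constants[["proton"]]
  out <- list()
  add <- function(label, residue_mass_sum)
    out[[length(out) + 1L]] <<- .fragment_ion("oxonium", label,
                                              residue_mass_sum + proton)
  for (cls in names(g))
    if (g[[cls]] >= 1L) add(cls, monosaccharide_masses[[cls]])
  if (g[["NeuAc"]] >= 1L)
    add("NeuAc-H2O",
        monosaccharide_masses[["NeuAc"]] - mass_constants[["water"]])
  if (g[["HexNAc"]] >= 1L && g[["Hex"]] >= 1L)
    add("HexNAc+Hex",
        monosaccharide_masses[["HexNAc"]] + monosaccharide_masses[["Hex"]])
  if (g[["HexNAc"]] >= 1L && g[["Hex"]] >= 1L && g[["NeuAc"]] >= 1L)
    add("HexNAc+Hex+NeuAc",
        monosaccharide_masses[["HexNAc"]] + monosaccharide_masses[["Hex"]] +
          monosaccharide_masses[["NeuAc"]])
  if (!length(out)) return(.empty_fragments())
  do.call(rbind, out)
}

#' Peptide backbone fragment ions (b / y series)
#'
#' Full b or y ladder of the unglycosylated peptide (the usual glycan-free
#' backbone convention for glycopeptide MS2: under collisional activation
#' the glycan is lost before backbone cleavage). Fixed modifications carried
#' by the peptide are included.
#'
#' b_i = sum of the i N-terminal residues + z protons;
#' y_i = sum of the i C-terminal residues + water + z protons.
#'
#' @param p A [peptide()] or sequence string.
#' @param series `"b"` or `"y"`.
#' @param charge Positive integer product charge (default 1).
#' @return `data.frame` of fragment ions with `index` the ladder index
#'   (1 .. length-1).
#' @examples
#' backbone_ions("HCSLNENITVPDTK", "y")   # y6 (TVPDTK) at 660.356
#' @export
backbone_ions <- function(p, series = c("b", "y"), charge = 1L) {
  series <- match.arg(series)
  if (is.character(p)) p <- peptide(p)
  stopifnot(inherits(p, "peptide"))
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  masses <- amino_acid_masses[res]
  mod <- rep(0, length(res))
  for (sym in names(p$fixed_mods)) mod[res == sym] <- p$fixed_mods[[sym]]
  masses <- masses + mod
  n <- length(res)
  if (n < 2L) return(.empty_fragments())
  idx <- seq_len(n - 1L)
  frag_mass <- if (series == "b") cumsum(masses)[idx]
               else cumsum(rev(masses))[idx] + mass_constants[["water"]]
  mz <- (frag_mass + charge * mass_constants[["proton"]]) / charge
  .fragment_ion(series, paste0(series, idx,
                               if (charge > 1L) paste0("^", charge, "+") else ""),
                mz, charge = charge, index = idx)
}

#' Glycan-trimmed Y-ion ladder of a glycopeptide
#'
#' Y-ions retain the intact peptide plus a partial glycan. The ladder runs
#' from the bare peptide (Y0) up to the full composition, attaching one
#' residue per step in the canonical order core-first: HexNAc residues,
#' then Hex, then Fuc, then NeuAc last (equivalently: NeuAc is trimmed
#' first). Downstream matching requires only set membership, not this order.
#'
#' @param gp A [glycopeptide()].
#' @param charge Positive integer charge (default 1).
#' @return `data.frame` of fragment ions (kind `"Y"`), `index` = number of
#'   glycan residues retained; `length = total residues + 1` rows.
#' @export
y_ladder <- function(gp, charge = 1L) {
  stopifnot(inherits(gp, "glycopeptide"))
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  build_order <- c("HexNAc", "Hex", "Fuc", "NeuAc", "Acetyl")
  steps <- unlist(lapply(build_order, function(cls)
    rep(monosaccharide_masses[[cls]], gp$glycan[[cls]])))
  cum <- c(0, cumsum(steps))
  mass <- peptide_mass(gp$peptide) + cum
  mz <- (mass + charge * mass_constants[["proton"]]) / charge
  .fragment_ion("Y", paste0("Y", seq_along(cum) - 1L), mz,
                charge = charge, index = seq_along(cum) - 1L)
}

#' Isotopologue cluster of an ion
#'
#' 13C isotopologue m/z positions and relative intensities for a neutral
#' mass at a given charge. Peaks are spaced by `1.003355 / charge`.
#' Intensities follow a binomial model over the carbons of an
#' averagine-style estimate of elemental composition (carbon count
#' `mass / 111.1254 * 4.9384`, 13C abundance 1.07%), normalised so the
#' tallest peak is 1. This captures the envelope-maximum shift with mass
#' that makes SIM assays monitor an isotopologue above the monoisotopic
#' peak for large glycopeptides.
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge.
#' @param n_peaks Number of isotopologues to return (index 0 ..
#'   `n_peaks - 1`).
#' @return `data.frame` with columns `isotopologue`, `mz`,
#'   `relative_intensity`.
#' @export
isotope_cluster <- function(mass, charge, n_peaks = 5L) {
  charge <- as.integer(charge)
  n_peaks <- as.integer(n_peaks)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  if (is.na(n_peaks) || n_peaks < 1L) stop("n_peaks must be >= 1")
  n_carbon <- max(1L, round(mass / 111.1254 * 4.9384))
  k <- seq_len(n_peaks) - 1L
  inten <- stats::dbinom(k, size = n_carbon, prob = 0.0107)
  inten <- inten / max(inten)
  mz <- (mass + k * mass_constants[["c13_minus_c12"]] +
           charge * mass_constants[["proton"]]) / charge
  data.frame(isotopologue = k, mz = mz, relative_intensity = inten)
}

# ---------------------------------------------------------------------------
# Transition entries and lists
# ---------------------------------------------------------------------------

#' Construct a transition entry
#'
#' The machine-readable form of one row of a targeted-assay transition
#' table: a glycopeptide precursor (charge + monitored isotopologue) with
#' its product-ion list and retention-time window.
#'
#' @param gp A [glycopeptide()].
#' @param charge Precursor charge state.
#' @param isotopologue Monitored 13C isotopologue index (default 2: for a
#'   ~5 kDa glycopeptide the envelope maximum sits near M+2).
#' @param products `data.frame` of product ions (e.g. from
#'   [oxonium_ions()]); must be non-empty.
#' @param rt_window Numeric length-2 retention-time window in minutes.
#' @param extra_product_mz Optional numeric vector of additional monitored
#'   product m/z values kept verbatim (labelled `"extra"`); they are not
#'   counted towards oxonium-based detection policies.
#' @return Object of class `transition_entry`.
#' @export
transition_entry <- function(gp, charge = 4L, isotopologue = 2L,
                             products = oxonium_ions(gp$glycan),
                             rt_window = c(0, Inf),
                             extra_product_mz = numeric()) {
  stopifnot(inherits(gp, "glycopeptide"))
  if (!nrow(products)) stop("product-ion list must be non-empty")
  if (length(extra_product_mz))
    products <- rbind(products,
                      .fragment_ion("extra",
                                    sprintf("extra_%.2f", extra_product_mz),
                                    extra_product_mz))
  structure(list(
    glycopeptide = gp,
    charge = as.integer(charge),
    isotopologue = as.integer(isotopologue),
    precursor_mz = glycopeptide_mz(gp, charge, isotopologue),
    products = products,
    rt_window = as.numeric(rt_window)),
    class = "transition_entry")
}

#' @export
print.transition_entry <- function(x, ...) {
  cat(sprintf("<transition> %s%s  precursor %.4f (z=%d, iso %d)  %d products\n",
              x$glycopeptide$peptide$sequence,
              format_glycan_composition(x$glycopeptide$glycan, "underscore"),
              x$precursor_mz, x$charge, x$isotopologue, nrow(x$products)))
  invisible(x)
}

#' Default transition for the rEPO tetra-sialylated target
#'
#' Convenience constructor for the assay's target: the Asn38 glycopeptide
#' HCSLNENITVPDTK carrying HexNAc(6)Hex(7)Fuc(1)NeuAc(4), monitored at
#' charge 4 on the M+2 isotopologue (precursor near m/z 1324.02), with the
#' five composition-derived oxonium/di-/tri-saccharide products.
#'
#' @param rt_window Retention-time window in minutes (default `c(14, 16)`,
#'   matching the package's synthetic-run default elution apex at 15 min).
#' @param extra_product_mz Extra monitored product m/z values (default
#'   none).
#' @return A [transition_entry()].
#' @export
target_transition <- function(rt_window = c(14, 16),
                              extra_product_mz = numeric()) {
  pep <- peptide("HCSLNENITVPDTK", start = 32L, end = 45L,
                 missed_cleavages = 2L)
  gp <- glycopeptide(pep, site = 38L, glycan = "_6_7_1_4")
  transition_entry(gp, charge = 4L, isotopologue = 2L,
                   rt_window = rt_window,
                   extra_product_mz = extra_product_mz)
}

#' Build a transition list from candidate glycopeptides
#'
#' One entry per candidate x charge. Duplicate entries (same peptide,
#' glycan, site and charge) are collapsed with a warning.
#'
#' @param candidates List of [glycopeptide()] objects.
#' @param charges Integer vector of precursor charges.
#' @param isotopologue Monitored isotopologue index (default 2).
#' @param rt_window Retention-time window applied to every entry.
#' @return List of [transition_entry()] objects.
#' @export
build_transition_list <- function(candidates, charges = 4L,
                                  isotopologue = 2L, rt_window = c(0, Inf)) {
  if (!length(candidates)) stop("candidate list must be non-empty")
  out <- list()
  seen <- character()
  for (gp in candidates) for (z in charges) {
    key <- paste(gp$peptide$sequence,
                 format_glycan_composition(gp$glycan, "underscore"),
                 gp$site, z, sep = "|")
    if (key %in% seen) {
      warning("duplicate transition collapsed: ", key)
      next
    }
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- transition_entry(
      gp, charge = z, isotopologue = isotopologue, rt_window = rt_window)
  }
  out
}

# full-precision number serialisation so CSV round-trips are exact
.num_chr <- function(x) vapply(x, function(v) format(v, digits = 17),
                               character(1))

#' Write a transition list to CSV
#'
#' Vendor-neutral inclusion-list schema: one row per transition with the
#' product m/z values and labels semicolon-joined. Numbers are written at
#' full double precision so that write -> read reproduces the list exactly.
#'
#' @param transitions List of [transition_entry()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transition_csv <- function(transitions, path) {
  rows <- lapply(transitions, function(tr) data.frame(
    peptide = tr$glycopeptide$peptide$sequence,
    glycan = format_glycan_composition(tr$glycopeptide$glycan, "underscore"),
    site = tr$glycopeptide$site,
    precursor_mz = .num_chr(tr$precursor_mz),
    z = tr$charge,
    isotopologue = tr$isotopologue,
    rt_start = .num_chr(tr$rt_window[1]),
    rt_end = .num_chr(tr$rt_window[2]),
    product_mz = paste(.num_chr(tr$products$mz), collapse = ";"),
    product_labels = paste(tr$products$label, collapse = ";"),
    product_kinds = paste(tr$products$kind, collapse = ";"),
    stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a transition list from CSV
#'
#' Inverse of [write_transition_csv()].
#'
#' @param path CSV path.
#' @return List of [transition_entry()] objects.
#' @export
read_transition_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    pep <- peptide(row$peptide)
    # site is stored in protein coordinates and the CSV does not carry the
    # parent-protein context, so rebuild the glycopeptide without the
    # peptide-local site validation
    gp <- structure(list(peptide = pep, site = as.integer(row$site),
                         glycan = parse_glycan_composition(row$glycan)),
                    class = "glycopeptide")
    products <- data.frame(
      kind = strsplit(row$product_kinds, ";", fixed = TRUE)[[1]],
      label = strsplit(row$product_labels, ";", fixed = TRUE)[[1]],
      mz = as.numeric(strsplit(row$product_mz, ";", fixed = TRUE)[[1]]),
      charge = 1L, index = NA_integer_, stringsAsFactors = FALSE)
    tr <- structure(list(
      glycopeptide = gp,
      charge = as.integer(row$z),
      isotopologue = as.integer(row$isotopologue),
      precursor_mz = as.numeric(row$precursor_mz),
      products = products,
      rt_window = c(as.numeric(row$rt_start), as.numeric(row$rt_end))),
      class = "transition_entry")
    tr
  })
}
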