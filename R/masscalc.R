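# Monoisotopic mass arithmetic: residue masses, modifications, peptide masses,
# and in-silico tryptic digestion. Everything downstream (flank verification,
# the simulator) builds on these sums, so masses are monoisotopic throughout
# and frozen at full precision.

#' The 20 canonical amino-acid one-letter codes
#' @keywords internal
CANONICAL_RESIDUES <- c(
  "A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Frozen monoisotopic residue masses (Da): peptide-bond residue masses, i.e.
# amino acid minus water. I and L are isomers and share one mass.
.RESIDUE_MASS <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Monoisotopic residue mass table
#'
#' Returns the monoisotopic masses (Da) of the 20 canonical amino-acid
#' residues (residue = amino acid minus water). Isoleucine and leucine are
#' isobaric and share one mass.
#'
#' @return Named numeric vector, one entry per one-letter residue code.
#' @examples
#' residue_masses()[["G"]]  # glycine, 57.02146
#' @export
residue_masses <- function() .RESIDUE_MASS

#' Mass constants used in flank-mass arithmetic
#'
#' Flanking fragment-ion masses are residue sums plus a series-dependent
#' offset. By default the N-terminal flank follows the b-ion convention
#' (offset = one proton) and the C-terminal flank the y-ion convention
#' (offset = water + proton). Both offsets are configurable because
#' different tag generators reference their ion ladders differently.
#'
#' @param proton Proton mass (Da).
#' @param water Monoisotopic water mass (Da).
#' @param n_flank_offset Offset added to the N-side residue sum (Da).
#' @param c_flank_offset Offset added to the C-side residue sum (Da).
#' @return A list of class `mass_constants`.
#' @export
mass_constants <- function(proton = 1.00727646,
                           water = 18.0105646,
                           n_flank_offset = proton,
                           c_flank_offset = water + proton) {
  stopifnot(is.finite(proton), is.finite(water),
            is.finite(n_flank_offset), is.finite(c_flank_offset))
  structure(list(proton = proton, water = water,
                 n_flank_offset = n_flank_offset,
                 c_flank_offset = c_flank_offset),
            class = "mass_constants")
}

#' Define an amino-acid modification
#'
#' @param name Modification name (free text).
#' @param target One-letter code of the residue the modification applies to.
#' @param delta Monoisotopic mass shift (Da).
#' @return A list of class `modification`.
#' @export
modification <- function(name, target, delta) {
  if (!is.character(target) || nchar(target) != 1L ||
      !(target %in% CANONICAL_RESIDUES)) {
    stop("modification target must be a single canonical residue code, got '",
         target, "'")
  }
  stopifnot(is.finite(delta))
  structure(list(name = as.character(name), target = target,
                 delta = as.numeric(delta)),
            class = "modification")
}

#' Default modification set
#'
#' Carbamidomethylation of cysteine (+57.02146 Da) and oxidation of
#' methionine (+15.99491 Da), the two modifications routinely carried by
#' tryptic shotgun data. The integer "+57"/"+16" shorthands seen in search
#' engine settings are nominal labels; full-precision deltas are used here.
#'
#' @return List of [modification()] objects.
#' @export
default_modifications <- function() {
  list(
    modification("carbamidomethyl", "C", 57.02146),
    modification("oxidation", "M", 15.99491)
  )
}

.check_residues <- function(seq) {
  if (length(seq) != 1L || !is.character(seq)) {
    stop("sequence must be a single character string")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), CANONICAL_RESIDUES)
  if (length(bad)) {
    stop("unknown residue character(s): ", paste(bad, collapse = ", "))
  }
  chars
}

.mod_deltas <- function(seq_chars, applied_mods) {
  if (is.null(applied_mods) || NROW(applied_mods) == 0L) return(0)
  if (inherits(applied_mods, "modification")) applied_mods <- list(applied_mods)
  if (is.data.frame(applied_mods)) {
    stopifnot(all(c("position", "target", "delta") %in% names(applied_mods)))
    pos <- applied_mods$position
    target <- applied_mods$target
    delta <- applied_mods$delta
  } else {
    pos <- vapply(applied_mods, function(m) as.integer(m$position %||% NA_integer_), 1L)
    target <- vapply(applied_mods, function(m) m$target, "")
    delta <- vapply(applied_mods, function(m) m$delta, 1)
  }
  if (anyNA(pos) || any(pos < 1L) || any(pos > length(seq_chars))) {
    stop("modification position out of range")
  }
  if (!all(seq_chars[pos] == target)) {
    stop("modification target residue does not match sequence at its position")
  }
  sum(delta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sum of monoisotopic residue masses
#'
#' Adds the residue masses of `seq` plus the deltas of any applied
#' modifications. This is the quantity fragment-ion ladders are built from;
#' add [mass_constants()]`$water` for the neutral peptide mass.
#'
#' @param seq Residue string (canonical one-letter codes).
#' @param applied_mods Optional modifications with positions: a data.frame
#'   with columns `position` (1-based), `target`, `delta`, or a list of
#'   [modification()] objects each carrying a `position` element.
#' @return Mass in Da.
#' @examples
#' sum_residue_masses("DD")  # 230.05
#' sum_residue_masses("ET")  # 230.09
#' @export
sum_residue_masses <- function(seq, applied_mods = NULL) {
  chars <- .check_residues(seq)
  if (length(chars) == 0L) return(0 + .mod_deltas(chars, applied_mods))
  sum(.RESIDUE_MASS[chars]) + .mod_deltas(chars, applied_mods)
}

#' Neutral monoisotopic peptide mass
#'
#' Residue-mass sum plus one water (the condensation water regained at the
#' termini of a free peptide).
#'
#' @inheritParams sum_residue_masses
#' @param constants A [mass_constants()] object.
#' @return Mass in Da.
#' @export
peptide_neutral_mass <- function(seq, applied_mods = NULL,
                                 constants = mass_constants()) {
  sum_residue_masses(seq, applied_mods) + constants$water
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K/R (optionally not before proline) and returns all
#' peptides carrying at most `missed_cleavages` internal cleavage sites,
#' with their 1-based inclusive coordinates in the protein.
#'
#' @param protein Residue string.
#' @param missed_cleavages Maximum internal K/R sites per peptide.
#' @param proline_rule If TRUE (default), K/R followed by P is not cleaved.
#' @return data.frame with columns `peptide`, `start`, `end`,
#'   `n_missed` (internal cleavage sites).
#' @examples
#' tryptic_digest("AAKGGRCC")$peptide            # "AAK" "GGR" "CC"
#' tryptic_digest("AAKGGRCC", missed_cleavages = 1)
#' @export
tryptic_digest <- function(protein, missed_cleavages = 0L,
                           proline_rule = TRUE) {
  chars <- .check_residues(protein)
  n <- length(chars)
  if (n == 0L) stop("protein must be non-empty")
  stopifnot(missed_cleavages >= 0L)
  # cleavage boundaries: position after residue i (i.e. peptide bonds cut)
  cut_after <- which(chars %in% c("K", "R"))
  if (proline_rule) {
    cut_after <- cut_after[!(cut_after < n & chars[cut_after + 1L] == "P")]
  }
  cut_after <- cut_after[cut_after < n]
  bounds <- c(0L, cut_after, n)  # peptide [bounds[i]+1, bounds[j]]
  nb <- length(bounds)
  out <- list()
  k <- 0L
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + missed_cleavages)
    for (j in (i + 1L):jmax) {
      k <- k + 1L
      out[[k]] <- c(bounds[i] + 1L, bounds[j], j - i - 1L)
    }
  }
  m <- do.call(rbind, out)
  data.frame(
    peptide = substring(protein, m[, 1L], m[, 2L]),
    start = m[, 1L], end = m[, 2L], n_missed = m[, 3L],
    stringsAsFactors = FALSE
  )
}

# Count internal tryptic sites within chars[from..to] (1-based, inclusive),
# excluding the final residue. Shared by flank verification and the oracle-ish
# helpers.
.internal_cleavages <- function(chars, from, to, proline_rule = TRUE) {
  if (to <= from) return(0L)
  idx <- from:(to - 1L)
  sites <- idx[chars[idx] %in% c("K", "R")]
  if (proline_rule && length(sites)) {
    sites <- sites[chars[sites + 1L] != "P"]
  }
  length(sites)
}
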