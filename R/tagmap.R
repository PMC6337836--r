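# Locating peptide sequence tags (PSTs) on translated segments and verifying
# both flanking fragment-ion masses under tryptic constraints. This is the
# heart of the mapper: a tag match alone is cheap evidence; a hit requires
# the N- and C-flank masses to be explained by surrounding residues within
# tolerance, anchored at tryptic boundaries.

#' Mapping parameters
#'
#' @param tolerance Absolute mass tolerance for flank verification (Da).
#'   Default 0.5 Da, appropriate for ion-trap fragment spectra.
#' @param max_mods Maximum number of modifications used to explain the two
#'   flank masses of one placement (default 1).
#' @param il_equivalent Treat I and L as equivalent during tag matching
#'   (they are isobaric); default TRUE.
#' @param missed_cleavages Maximum internal K/R sites in the inferred
#'   peptide (default 1).
#' @param proline_rule K/R followed by P is not a cleavage boundary
#'   (default TRUE).
#' @param constants [mass_constants()] giving the flank-mass offsets.
#' @param modifications List of [modification()]s that may be invoked;
#'   default [default_modifications()].
#' @return List of class `map_params`.
#' @export
map_params <- function(tolerance = 0.5, max_mods = 1L, il_equivalent = TRUE,
                       missed_cleavages = 1L, proline_rule = TRUE,
                       constants = mass_constants(),
                       modifications = default_modifications()) {
  stopifnot(tolerance > 0, max_mods >= 0L, missed_cleavages >= 0L)
  structure(list(tolerance = tolerance, max_mods = as.integer(max_mods),
                 il_equivalent = isTRUE(il_equivalent),
                 missed_cleavages = as.integer(missed_cleavages),
                 proline_rule = isTRUE(proline_rule),
                 constants = constants, modifications = modifications),
            class = "map_params")
}

#' Construct a PST table
#'
#' A PST is the unit of evidence: a 3-5 residue tag read de novo from an
#' MS/MS spectrum plus the masses of the fragment ions flanking it on the
#' N side (`mn`) and C side (`mc`).
#'
#' @param spectrum_id Character vector of spectrum identifiers.
#' @param tag Character vector of tags (length 3-5, canonical residues).
#' @param mn,mc Numeric flank masses (Da).
#' @return data.frame with the four columns, validated.
#' @export
pst_table <- function(spectrum_id, tag, mn, mc) {
  x <- data.frame(spectrum_id = as.character(spectrum_id),
                  tag = as.character(tag),
                  mn = as.numeric(mn), mc = as.numeric(mc),
                  stringsAsFactors = FALSE)
  .validate_psts(x)
  x
}

.validate_psts <- function(x, where = "PST table") {
  lens <- nchar(x$tag)
  bad <- which(lens < 3L | lens > 5L)
  if (length(bad)) {
    stop(where, ": tag length outside 3-5 at entry ", bad[1L],
         " ('", x$tag[bad[1L]], "')")
  }
  for (tg in unique(x$tag)) .check_residues(tg)
  if (anyNA(x$mn) || anyNA(x$mc)) stop(where, ": non-numeric flank mass")
  invisible(x)
}

#' Read / write PST files
#'
#' Tab-separated, one PST per line (`spectrum_id`, `tag`, `mn`, `mc`);
#' lines starting with `#` are comments/header. Write-then-read is the
#' identity.
#'
#' @param path File path.
#' @return `read_psts`: validated PST data.frame.
#' @export
read_psts <- function(path) {
  if (!file.exists(path)) stop("PST file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(pst_table(character(), character(), numeric(), numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L)) {
    i <- which(nf != 4L)[1L]
    stop("malformed PST line ", lineno[i], ": expected 4 tab-separated ",
         "fields, got ", nf[i])
  }
  m <- do.call(rbind, parts)
  mn <- suppressWarnings(as.numeric(m[, 3L]))
  mc <- suppressWarnings(as.numeric(m[, 4L]))
  if (anyNA(mn) || anyNA(mc)) {
    i <- which(is.na(mn) | is.na(mc))[1L]
    stop("malformed PST line ", lineno[i], ": non-numeric flank mass")
  }
  pst_table(m[, 1L], m[, 2L], mn, mc)
}

#' @param psts PST data.frame as from [pst_table()].
#' @rdname read_psts
#' @export
write_psts <- function(psts, path) {
  .validate_psts(psts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# spectrum_id\ttag\tmn\tmc", con)
  if (nrow(psts)) {
    writeLines(sprintf("%s\t%s\t%.5f\t%.5f",
                       psts$spectrum_id, psts$tag, psts$mn, psts$mc), con)
  }
  invisible(path)
}

.il_norm <- function(x) chartr("I", "L", x)

#' Find all (overlapping) tag occurrences in a segment
#'
#' @param tag Residue string, length 3-5.
#' @param segment_aa Residue string of a translated segment (or any protein
#'   string).
#' @param il_equivalent Match I and L as equivalent (default TRUE).
#' @return Integer vector of 1-based match start positions.
#' @export
find_tag <- function(tag, segment_aa, il_equivalent = TRUE) {
  if (il_equivalent) {
    tag <- .il_norm(tag)
    segment_aa <- .il_norm(segment_aa)
  }
  if (nchar(tag) > nchar(segment_aa)) return(integer())
  m <- Biostrings::matchPattern(tag, Biostrings::AAString(segment_aa))
  as.integer(BiocGenerics::start(m))
}

# Feasible modification-count/delta combinations for a region.
# counts: named integer vector, eligible residues per modification.
# Returns data.frame(n_mods, delta) including the 0-mod row, all
# combinations with total count <= max_mods.
.mod_combos <- function(counts, deltas, max_mods) {
  combos <- data.frame(n_mods = 0L, delta = 0)
  if (max_mods == 0L || !length(deltas)) return(combos)
  grids <- lapply(seq_along(deltas), function(i) 0:min(counts[i], max_mods))
  grid <- do.call(expand.grid, grids)
  tot <- rowSums(grid)
  keep <- tot > 0L & tot <= max_mods
  if (any(keep)) {
    grid <- grid[keep, , drop = FALSE]
    combos <- rbind(combos, data.frame(
      n_mods = as.integer(rowSums(grid)),
      delta = as.numeric(as.matrix(grid) %*% deltas)
    ))
  }
  unique(combos)
}

# Candidate boundaries on one side of a tag. Walks outward from the tag
# accumulating residue mass; at each valid tryptic boundary, records every
# modification combination that explains the flank mass within tolerance.
# side = "n": positions b (peptide start) in seq of chars; flank residues
# are chars[b .. tag_start-1]. side = "c": positions e (peptide end);
# flank residues are chars[tag_end+1 .. e].
.flank_candidates <- function(chars, tag_start, tag_end, flank_mass, offset,
                              params) {
  rm <- .RESIDUE_MASS
  tol <- params$tolerance
  mods <- params$modifications
  mod_targets <- vapply(mods, function(m) m$target, "")
  mod_deltas <- vapply(mods, function(m) m$delta, 1)
  res <- list()
  add <- function(pos, n_mods) res[[length(res) + 1L]] <<- c(pos, n_mods)

  n <- length(chars)
  # residue-sum budget: a flank can only overshoot its mass by the tolerance
  # plus whatever negative modification deltas could compensate
  max_extra <- if (params$max_mods > 0L && length(mod_deltas)) {
    params$max_mods * max(0, -min(mod_deltas))
  } else 0
  budget <- flank_mass - offset + tol + max_extra + 1e-9

  check <- function(pos, region) {
    base <- if (length(region)) sum(rm[chars[region]]) else 0
    if (base > budget) return(invisible(NULL))
    counts <- vapply(mod_targets, function(t) sum(chars[region] == t), 1L)
    combos <- .mod_combos(counts, mod_deltas, params$max_mods)
    ok <- abs(flank_mass - (base + offset + combos$delta)) <= tol
    if (any(ok)) {
      for (nm in unique(combos$n_mods[ok])) add(pos, nm)
    }
    invisible(NULL)
  }

  is_start_boundary <- function(b) {
    b == 1L || (chars[b - 1L] %in% c("K", "R") &&
                  !(params$proline_rule && chars[b] == "P"))
  }
  is_end_boundary <- function(e) {
    e == n || (chars[e] %in% c("K", "R") &&
                 !(params$proline_rule && chars[e + 1L] == "P"))
  }

  side_n <- !is.null(tag_start)
  if (side_n) {
    cum <- 0
    b <- tag_start
    repeat {
      if (is_start_boundary(b)) check(b, if (b <= tag_start - 1L) b:(tag_start - 1L) else integer())
      if (b == 1L) break
      cum <- cum + rm[[chars[b - 1L]]]
      if (cum > budget) break
      b <- b - 1L
    }
  } else {
    cum <- 0
    e <- tag_end
    repeat {
      if (is_end_boundary(e)) check(e, if (e >= tag_end + 1L) (tag_end + 1L):e else integer())
      if (e == n) break
      cum <- cum + rm[[chars[e + 1L]]]
      if (cum > budget) break
      e <- e + 1L
    }
  }
  if (!length(res)) {
    return(data.frame(pos = integer(), n_mods = integer()))
  }
  m <- do.call(rbind, res)
  data.frame(pos = m[, 1L], n_mods = m[, 2L])
}

#' Verify the flanking masses of a tag occurrence
#'
#' Extends leftward and rightward from a tag match, looking for tryptic
#' peptide boundaries whose intervening residue masses (plus the configured
#' flank offsets, plus at most `max_mods` modification deltas over both
#' flanks) explain the PST's `mn` and `mc` within tolerance. Segment ends
#' count as boundaries (a stop codon truncates the frame). Internal K/R
#' sites in the inferred peptide are capped at `missed_cleavages`.
#'
#' @param segment One row of [six_frame_translate()] output (or any list
#'   with an `aa` string).
#' @param tag_pos 1-based tag match position within `segment$aa`.
#' @param pst One-row PST data.frame (or list with `tag`, `mn`, `mc`).
#' @param params [map_params()].
#' @return data.frame with columns `peptide`, `aa_start` (1-based position
#'   of the peptide in the segment), `n_mods` — empty if nothing verifies.
#'   Multiple boundary pairs may verify; duplicates at identical
#'   coordinates keep the fewest modifications.
#' @export
verify_flanks <- function(segment, tag_pos, pst, params = map_params()) {
  aa <- segment$aa
  chars <- strsplit(aa, "", fixed = TRUE)[[1L]]
  tlen <- nchar(pst$tag)
  tag_end <- tag_pos + tlen - 1L
  stopifnot(tag_pos >= 1L, tag_end <= length(chars))

  nc <- .flank_candidates(chars, tag_start = tag_pos, tag_end = NULL,
                          flank_mass = pst$mn,
                          offset = params$constants$n_flank_offset,
                          params = params)
  if (!nrow(nc)) return(.empty_verify())
  cc <- .flank_candidates(chars, tag_start = NULL, tag_end = tag_end,
                          flank_mass = pst$mc,
                          offset = params$constants$c_flank_offset,
                          params = params)
  if (!nrow(cc)) return(.empty_verify())

  out <- list()
  for (i in seq_len(nrow(nc))) {
    for (j in seq_len(nrow(cc))) {
      n_mods <- nc$n_mods[i] + cc$n_mods[j]
      if (n_mods > params$max_mods) next
      b <- nc$pos[i]; e <- cc$pos[j]
      if (.internal_cleavages(chars, b, e, params$proline_rule) >
          params$missed_cleavages) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(aa, b, e), aa_start = b, n_mods = n_mods,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_verify())
  res <- do.call(rbind, out)
  # identical coordinates: prefer fewer modifications
  res <- res[order(res$aa_start, nchar(res$peptide), res$n_mods), ]
  res[!duplicated(res[c("aa_start", "peptide")]), , drop = FALSE]
}

.empty_verify <- function() {
  data.frame(peptide = character(), aa_start = integer(),
             n_mods = integer(), stringsAsFactors = FALSE)
}

.empty_hits <- function() {
  data.frame(spectrum_id = character(), tag = character(),
             contig = character(), strand = character(), frame = integer(),
             peptide = character(), start = integer(), end = integer(),
             n_mods = integer(), stringsAsFactors = FALSE)
}

#' Map PSTs onto translated segments
#'
#' For every PST, locates its tag (I/L-blind by default) in every segment,
#' verifies both flank masses with [verify_flanks()], and reports each
#' verified placement as a hit with forward-strand genomic coordinates
#' covering the full inferred peptide. Placements duplicated at the same
#' genomic interval for the same spectrum are collapsed, keeping the
#' fewest-modification explanation. Output order is deterministic
#' (contig, start, end, spectrum_id).
#'
#' @param psts PST data.frame ([pst_table()] / [read_psts()]).
#' @param segments [six_frame_translate()] output.
#' @param params [map_params()].
#' @return Hits data.frame: `spectrum_id`, `tag`, `contig`, `strand`,
#'   `frame`, `peptide`, `start`, `end` (1-based inclusive), `n_mods`.
#' @export
map_psts <- function(psts, segments, params = map_params()) {
  .validate_psts(psts)
  if (!nrow(psts) || !nrow(segments)) return(.empty_hits())
  seg_aa <- if (params$il_equivalent) .il_norm(segments$aa) else segments$aa
  subject <- Biostrings::AAStringSet(seg_aa)
  tags_norm <- if (params$il_equivalent) .il_norm(psts$tag) else psts$tag

  hits <- list()
  for (tg in unique(tags_norm)) {
    pst_rows <- which(tags_norm == tg)
    m <- Biostrings::vmatchPattern(tg, subject)
    seg_idx <- which(lengths(m) > 0L)
    if (!length(seg_idx)) next
    for (si in seg_idx) {
      starts <- BiocGenerics::start(m[[si]])
      seg <- segments[si, ]
      for (pos in starts) {
        for (pr in pst_rows) {
          v <- verify_flanks(seg, pos, psts[pr, ], params)
          if (!nrow(v)) next
          for (k in seq_len(nrow(v))) {
            plen <- nchar(v$peptide[k])
            g <- segment_to_genomic(seg, v$aa_start[k],
                                    v$aa_start[k] + plen - 1L)
            hits[[length(hits) + 1L]] <- data.frame(
              spectrum_id = psts$spectrum_id[pr], tag = psts$tag[pr],
              contig = g$contig, strand = g$strand, frame = seg$frame,
              peptide = v$peptide[k], start = g$start, end = g$end,
              n_mods = v$n_mods[k], stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(hits)) return(.empty_hits())
  h <- do.call(rbind, hits)
  # collapse duplicate placements (same spectrum, same interval): min mods
  h <- h[order(h$contig, h$start, h$end, h$spectrum_id, h$n_mods), ]
  key <- paste(h$spectrum_id, h$contig, h$strand, h$start, h$end, sep = "\r")
  h <- h[!duplicated(key), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Read / write hit files
#'
#' Tab-separated hit tables (`spectrum_id`, `tag`, `contig`, `strand`,
#' `frame`, `peptide`, `start`, `end`, `n_mods`), 1-based inclusive
#' coordinates, `#`-prefixed header. Write-then-read is the identity.
#'
#' @param path File path.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("hits file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(.empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L)) stop("malformed hits file: ", path)
  m <- do.call(rbind, parts)
  data.frame(spectrum_id = m[, 1L], tag = m[, 2L], contig = m[, 3L],
             strand = m[, 4L], frame = as.integer(m[, 5L]),
             peptide = m[, 6L], start = as.integer(m[, 7L]),
             end = as.integer(m[, 8L]), n_mods = as.integer(m[, 9L]),
             stringsAsFactors = FALSE)
}

#' @param hits Hits data.frame from [map_psts()].
#' @rdname read_hits
#' @export
write_hits <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# spectrum_id\ttag\tcontig\tstrand\tframe\tpeptide",
                    "\tstart\tend\tn_mods"), con)
  if (nrow(hits)) {
    writeLines(sprintf("%s\t%s\t%s\t%s\t%d\t%s\t%d\t%d\t%d",
                       hits$spectrum_id, hits$tag, hits$contig, hits$strand,
                       hits$frame, hits$peptide, hits$start, hits$end,
                       hits$n_mods), con)
  }
  invisible(path)
}
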