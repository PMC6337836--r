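# Independent oracles used by the tests. These deliberately recompute
# quantities by brute force / from first principles, on paths disjoint from
# the package implementation.

# --- residue masses from atomic composition -------------------------------
# Monoisotopic atom masses (CODATA/AME) and residue elemental formulas.
.ATOM <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
           O = 15.9949146221, S = 31.97207069)

.RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2), D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2), K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1), F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

oracle_residue_mass <- function(residue) {
  f <- .RESIDUE_FORMULA[[residue]]
  sum(.ATOM[names(f)] * f)
}

oracle_peptide_neutral_mass <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  water <- 2 * .ATOM[["H"]] + .ATOM[["O"]]
  sum(vapply(chars, oracle_residue_mass, 1)) + water
}

# --- naive six-frame translator -------------------------------------------
# Explicit codon loop over the standard code; segments broken at stops and
# at codons containing N. Returns the same columns as six_frame_translate.
oracle_six_frame <- function(contig_id, seq) {
  gc <- Biostrings::GENETIC_CODE
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  out <- list()
  L <- nchar(seq)
  for (strand in c("+", "-")) {
    work <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      n_codons <- (L - frame) %/% 3
      if (n_codons <= 0) next
      aa <- character(n_codons)
      for (j in seq_len(n_codons)) {
        codon <- substr(work, frame + 3 * j - 2, frame + 3 * j)
        aa[j] <- if (grepl("N", codon)) "#" else gc[[codon]]
      }
      j <- 1
      while (j <= n_codons) {
        if (aa[j] %in% c("*", "#")) { j <- j + 1; next }
        j0 <- j
        while (j <= n_codons && !(aa[j] %in% c("*", "#"))) j <- j + 1
        j1 <- j - 1
        if (strand == "+") {
          gstart <- frame + 3 * (j0 - 1) + 1; gend <- frame + 3 * j1
        } else {
          gstart <- L - frame - 3 * j1 + 1; gend <- L - frame - 3 * (j0 - 1)
        }
        out[[length(out) + 1]] <- data.frame(
          contig = contig_id, strand = strand, frame = frame,
          aa = paste(aa[j0:j1], collapse = ""),
          gstart = gstart, gend = gend, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# --- exhaustive tag-mapping oracle ----------------------------------------
# Enumerates every tryptic peptide of every segment (segment ends count as
# boundaries), every tag window inside it, and every modification
# assignment with total count <= max_mods, and intersects with the PST
# list. Independent of verify_flanks/map_psts.
oracle_map_psts <- function(psts, segments, params) {
  rm <- residue_masses()
  tol <- params$tolerance
  mods <- params$modifications
  mod_t <- vapply(mods, function(m) m$target, "")
  mod_d <- vapply(mods, function(m) m$delta, 1)
  iln <- function(x) chartr("I", "L", x)
  hits <- list()

  for (si in seq_len(nrow(segments))) {
    seg <- segments[si, ]
    chars <- strsplit(seg$aa, "")[[1]]
    n <- length(chars)
    sites <- which(chars %in% c("K", "R"))
    if (params$proline_rule) {
      sites <- sites[!(sites < n & chars[sites + 1] == "P")]
    }
    sites <- sites[sites < n]
    bounds <- c(0, sites, n)
    nb <- length(bounds)
    for (i in seq_len(nb - 1)) {
      for (j in (i + 1):min(nb, i + 1 + params$missed_cleavages)) {
        s <- bounds[i] + 1; e <- bounds[j]
        pep <- substr(seg$aa, s, e)
        plen <- e - s + 1
        for (pr in seq_len(nrow(psts))) {
          tlen <- nchar(psts$tag[pr])
          if (plen < tlen) next
          tagn <- if (params$il_equivalent) iln(psts$tag[pr]) else psts$tag[pr]
          for (off in 0:(plen - tlen)) {
            w <- s + off
            win <- substr(seg$aa, w, w + tlen - 1)
            if (params$il_equivalent) win <- iln(win)
            if (win != tagn) next
            pre_r <- if (w > s) chars[s:(w - 1)] else character()
            suf_r <- if (w + tlen <= e) chars[(w + tlen):e] else character()
            pre_m <- if (length(pre_r)) sum(rm[pre_r]) else 0
            suf_m <- if (length(suf_r)) sum(rm[suf_r]) else 0
            cnt_pre <- vapply(mod_t, function(t) sum(pre_r == t), 1L)
            cnt_suf <- vapply(mod_t, function(t) sum(suf_r == t), 1L)
            # exhaustive distribution of `total` mods over (mod, side) cells
            found_n <- NA_integer_
            for (total in 0:params$max_mods) {
              ok <- FALSE
              # distribute `total` across (mod, side) cells
              cells <- expand.grid(rep(list(0:total),
                                       2 * length(mod_d)))
              if (length(mod_d) == 0) cells <- data.frame(x = 0)[, 0]
              use <- rowSums(cells) == total
              for (ri in which(use)) {
                alloc <- as.numeric(cells[ri, ])
                pre_alloc <- alloc[seq_along(mod_d)]
                suf_alloc <- alloc[length(mod_d) + seq_along(mod_d)]
                if (any(pre_alloc > cnt_pre) || any(suf_alloc > cnt_suf)) next
                d_pre <- sum(pre_alloc * mod_d)
                d_suf <- sum(suf_alloc * mod_d)
                if (abs(psts$mn[pr] - (pre_m + d_pre +
                                       params$constants$n_flank_offset)) <= tol &&
                    abs(psts$mc[pr] - (suf_m + d_suf +
                                       params$constants$c_flank_offset)) <= tol) {
                  ok <- TRUE; break
                }
              }
              if (ok) { found_n <- total; break }
            }
            if (is.na(found_n)) next
            if (seg$strand == "+") {
              gs <- seg$gstart + 3 * (s - 1); ge <- seg$gstart + 3 * e - 1
            } else {
              gs <- seg$gend - 3 * e + 1; ge <- seg$gend - 3 * (s - 1)
            }
            hits[[length(hits) + 1]] <- data.frame(
              spectrum_id = psts$spectrum_id[pr], contig = seg$contig,
              strand = seg$strand, start = gs, end = ge, peptide = pep,
              n_mods = found_n, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(spectrum_id = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), peptide = character(),
                      n_mods = integer(), stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, hits)
  h <- h[order(h$spectrum_id, h$contig, h$strand, h$start, h$end, h$n_mods), ]
  h[!duplicated(h[c("spectrum_id", "contig", "strand", "start", "end")]), ,
    drop = FALSE]
}

# canonical form for comparing hit sets
hit_key <- function(h) {
  sort(paste(h$spectrum_id, h$contig, h$strand, h$start, h$end, h$peptide,
             h$n_mods, sep = "|"))
}

# --- transitive-closure clustering oracle ---------------------------------
# Union-find over the pairwise relation gap(i, j) <= maxdist, per
# contig/strand; returns the partition as a sorted list of sorted index
# vectors (no minhit/minpep filtering).
oracle_cluster <- function(hits, maxdist, strand_aware = TRUE) {
  n <- nrow(hits)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  grp <- if (strand_aware) paste(hits$contig, hits$strand) else hits$contig
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j || grp[i] != grp[j]) next
      gap <- max(hits$start[i], hits$start[j]) -
        min(hits$end[i], hits$end[j]) - 1
      if (gap <= maxdist) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comps <- split(seq_len(n), roots)
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, 1L))]
}

# --- misc fixture builders -------------------------------------------------
random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_peptide <- function(n) {
  paste(sample(names(residue_masses()), n, replace = TRUE), collapse = "")
}

# a minimal gene/mRNA/CDS GFF3 file; intervals are 1-based inclusive
write_mini_gff3 <- function(path, rows) {
  lines <- c("##gff-version 3", rows)
  writeLines(lines, path)
  path
}

gff3_feature <- function(contig, type, start, end, strand, id = NULL,
                         parent = NULL) {
  attrs <- c(if (!is.null(id)) paste0("ID=", id),
             if (!is.null(parent)) paste0("Parent=", parent))
  paste(contig, "test", type, start, end, ".", strand, ".",
        paste(attrs, collapse = ";"), sep = "\t")
}
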