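# Shared fixture builders (constructed with the package's mass table; the
# *placement logic* they exercise is checked against independent oracles).

# flank masses for a tag window inside a peptide
flanks_for <- function(peptide, tag_start, tag_len, co = mass_constants()) {
  rm <- residue_masses()
  chars <- strsplit(peptide, "")[[1]]
  pre <- if (tag_start > 1) sum(rm[chars[1:(tag_start - 1)]]) else 0
  from <- tag_start + tag_len
  post <- if (from <= length(chars)) sum(rm[chars[from:length(chars)]]) else 0
  c(mn = pre + co$n_flank_offset, mc = post + co$c_flank_offset)
}

# a random genome whose segments provide true PSTs (optionally with
# modification-shifted variants), plus random decoys
make_mapping_case <- function(n_bases = 900, n_true = 6, n_decoy = 3,
                              params = map_params(), with_mods = FALSE) {
  dna <- random_dna_string(n_bases)
  segments <- six_frame_translate(c(g1 = dna))
  co <- params$constants
  psts <- list()
  k <- 0
  long <- segments[nchar(segments$aa) >= 8, ]
  for (i in sample(nrow(long), min(n_true * 3, nrow(long)))) {
    if (k >= n_true) break
    seg <- long[i, ]
    d <- tryptic_digest(seg$aa, missed_cleavages = params$missed_cleavages)
    d <- d[nchar(d$peptide) >= 4, , drop = FALSE]
    if (!nrow(d)) next
    j <- sample(nrow(d), 1)
    pep <- d$peptide[j]
    tlen <- sample(3:min(5, nchar(pep)), 1)
    t0 <- sample(nchar(pep) - tlen + 1, 1)
    fl <- flanks_for(pep, t0, tlen, co)
    k <- k + 1
    psts[[length(psts) + 1]] <- data.frame(
      spectrum_id = sprintf("true%02d", k),
      tag = substr(pep, t0, t0 + tlen - 1),
      mn = fl[["mn"]], mc = fl[["mc"]], stringsAsFactors = FALSE)
    if (with_mods && runif(1) < 0.5) {
      # shift one flank by a modification delta; verifies only where an
      # eligible residue sits in that flank (the oracle decides too)
      delta <- sample(c(15.99491, 57.02146), 1)
      side <- sample(c("mn", "mc"), 1)
      v <- psts[[length(psts)]]
      v$spectrum_id <- paste0(v$spectrum_id, "_mod")
      v[[side]] <- v[[side]] + delta
      psts[[length(psts) + 1]] <- v
    }
  }
  for (dcy in seq_len(n_decoy)) {
    psts[[length(psts) + 1]] <- data.frame(
      spectrum_id = sprintf("decoy%02d", dcy), tag = random_peptide(4),
      mn = runif(1, 10, 600), mc = runif(1, 25, 600),
      stringsAsFactors = FALSE)
  }
  list(psts = do.call(rbind, psts), segments = segments)
}
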