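# Six-frame translation of genomic sequence into stop-free segments with an
# exact residue -> genome coordinate map. Segments, not ORFs: every maximal
# stretch of a reading frame free of stop codons and of codons containing N
# is reported, and the tag mapper decides what is real.

#' Read a genomic FASTA file
#'
#' Sequences are upper-cased; characters outside A/C/G/T/N are replaced by N
#' with a warning. Duplicate record ids and empty files are errors.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(x) <- ids
  seqs <- toupper(as.character(x))
  n_bad <- sum(vapply(seqs, function(s) {
    nchar(gsub("[ACGTN]", "", s))
  }, 1L))
  if (n_bad > 0L) {
    warning(n_bad, " non-ACGTN character(s) replaced by N")
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), "")
  }
  Biostrings::DNAStringSet(seqs)
}

# Translate one frame of one strand and emit stop/N-free runs with forward
# strand coordinates. seq_chr: forward-strand contig string. Returns a
# data.frame (possibly 0-row).
.translate_frame <- function(contig_id, seq_chr, strand, frame) {
  L <- nchar(seq_chr)
  work <- if (strand == "+") seq_chr else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_chr)))
  n_codons <- (nchar(work) - frame) %/% 3L
  if (n_codons <= 0L) return(NULL)
  sub <- substr(work, frame + 1L, frame + 3L * n_codons)
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(sub),
                          if.fuzzy.codon = "X", no.init.codon = TRUE)
  ))
  # '*' (stop) and 'X' (codon containing N / ambiguity) break segments
  runs <- gregexpr("[^*X]+", aa)[[1L]]
  if (runs[1L] == -1L) return(NULL)
  j0 <- as.integer(runs)                          # 1-based aa index in frame
  j1 <- j0 + attr(runs, "match.length") - 1L
  if (strand == "+") {
    gstart <- frame + 3L * (j0 - 1L) + 1L
    gend <- frame + 3L * j1
  } else {
    # codon j (1-based, in reverse-complement reading order) occupies
    # forward-strand bases [L - frame - 3j + 1, L - frame - 3(j-1)]
    gstart <- L - frame - 3L * j1 + 1L
    gend <- L - frame - 3L * (j0 - 1L)
  }
  data.frame(contig = contig_id, strand = strand, frame = frame,
             aa = substring(aa, j0, j1), gstart = gstart, gend = gend,
             stringsAsFactors = FALSE)
}

#' Six-frame translation into stop-free segments
#'
#' Translates every contig in all six reading frames with the standard
#' genetic code. Each frame's translation is split at stop codons and at
#' codons containing N; the resulting segments carry forward-strand 1-based
#' inclusive coordinates of the bases they cover, so any residue range can
#' be mapped back to the genome with [segment_to_genomic()].
#'
#' @param contigs A [Biostrings::DNAStringSet] (e.g. from
#'   [read_genome_fasta()]), or a named character vector of DNA strings.
#' @return data.frame with columns `contig`, `strand` (+/-), `frame`
#'   (0/1/2), `aa` (residue string, no stops), `gstart`, `gend`.
#' @export
six_frame_translate <- function(contigs) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  ids <- names(contigs)
  if (is.null(ids)) stop("contigs must be named")
  out <- vector("list", 6L * length(contigs))
  k <- 0L
  for (i in seq_along(contigs)) {
    s <- as.character(contigs[[i]])
    for (strand in c("+", "-")) {
      for (frame in 0:2) {
        k <- k + 1L
        out[[k]] <- .translate_frame(ids[i], s, strand, frame)
      }
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(contig = character(), strand = character(),
                      frame = integer(), aa = character(),
                      gstart = integer(), gend = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map a residue range of a segment to genomic coordinates
#'
#' @param segment One row of the data.frame returned by
#'   [six_frame_translate()] (a list or 1-row data.frame).
#' @param aa_from,aa_to 1-based inclusive residue range within the segment.
#' @return List with `contig`, `strand`, `start`, `end` (forward-strand,
#'   1-based inclusive; `end - start + 1 == 3 * (aa_to - aa_from + 1)`).
#' @export
segment_to_genomic <- function(segment, aa_from, aa_to) {
  len <- nchar(segment$aa)
  if (aa_from < 1L || aa_to > len || aa_from > aa_to) {
    stop("residue range [", aa_from, ", ", aa_to,
         "] out of segment bounds (1..", len, ")")
  }
  if (segment$strand == "+") {
    start <- segment$gstart + 3L * (aa_from - 1L)
    end <- segment$gstart + 3L * aa_to - 1L
  } else {
    start <- segment$gend - 3L * aa_to + 1L
    end <- segment$gend - 3L * (aa_from - 1L)
  }
  list(contig = segment$contig, strand = segment$strand,
       start = as.integer(start), end = as.integer(end))
}
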