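# Sensitivity/selectivity evaluation of mapping and clustering against an
# expected protein set: sensitivity = true_pos/nref (expected proteins
# recovered), selectivity = true_pos/nfound (recovered proteins that were
# expected).

#' Match proteins by hit support
#'
#' A protein is matched when at least `min_valid_hits` hits fall fully
#' within its coding intervals (same contig and strand).
#'
#' @param hits Hits data.frame from [map_psts()].
#' @param protein_index data.frame with columns `protein_id`, `contig`,
#'   `strand`, `start`, `end` — one row per coding interval (1-based
#'   inclusive), several rows per multi-exon protein.
#' @param min_valid_hits Minimum supporting hits (default 2).
#' @return Character vector of matched protein ids.
#' @export
match_proteins_by_hits <- function(hits, protein_index, min_valid_hits = 2L) {
  stopifnot(min_valid_hits >= 1L)
  if (!nrow(hits) || !nrow(protein_index)) return(character())
  hg <- .hits_granges(hits)
  pg <- GenomicRanges::GRanges(
    protein_index$contig,
    IRanges::IRanges(protein_index$start, protein_index$end),
    strand = protein_index$strand)
  ov <- GenomicRanges::findOverlaps(hg, pg, type = "within")
  if (!length(ov)) return(character())
  # count distinct hits per protein (a hit within two intervals of the same
  # protein counts once)
  df <- unique(data.frame(
    hit = S4Vectors::queryHits(ov),
    protein = protein_index$protein_id[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE))
  tab <- table(df$protein)
  names(tab)[tab >= min_valid_hits]
}

#' Match proteins by IN/CROSS cluster overlap
#'
#' Cluster-level evaluation: a protein counts as matched when an IN or
#' CROSS cluster overlaps its mRNA. Returns the parent gene ids of the
#' overlapped mRNAs (falling back to the mRNA ID when no parent is
#' recorded).
#'
#' @param qualified [qualify_clusters()] output.
#' @param annotation [parse_gff3()] output.
#' @param ignore_strand Compare irrespective of strand (default FALSE).
#' @return Character vector of matched gene ids.
#' @export
match_proteins_by_clusters <- function(qualified, annotation,
                                       ignore_strand = FALSE) {
  if (!nrow(qualified)) return(character())
  sel <- qualified$category %in% c("IN", "CROSS")
  if (!any(sel)) return(character())
  cl <- .clusters_granges(qualified[sel, , drop = FALSE])
  ov <- GenomicRanges::findOverlaps(cl, annotation$mrna,
                                    ignore.strand = ignore_strand)
  if (!length(ov)) return(character())
  m <- annotation$mrna[S4Vectors::subjectHits(ov)]
  ids <- ifelse(is.na(m$gene), m$ID, m$gene)
  unique(ids)
}

#' Sensitivity and selectivity of a found set against an expected set
#'
#' @param found Character vector of recovered ids.
#' @param expected Character vector of expected ids (non-empty).
#' @return List of class `eval_result`: `true_pos`, `nref`, `nfound`,
#'   `sensitivity` (= true_pos/nref), `selectivity` (= true_pos/nfound;
#'   NA when nothing was found).
#' @examples
#' evaluate(letters[1:20], letters[1:10])  # sens 1.0, sel 0.5
#' @export
evaluate <- function(found, expected) {
  expected <- unique(expected)
  found <- unique(found)
  if (!length(expected)) stop("expected set must be non-empty")
  tp <- length(intersect(found, expected))
  structure(list(
    true_pos = tp, nref = length(expected), nfound = length(found),
    sensitivity = tp / length(expected),
    selectivity = if (length(found)) tp / length(found) else NA_real_),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("true_pos %d / nref %d / nfound %d\n", x$true_pos, x$nref,
              x$nfound))
  cat(sprintf("sensitivity %.3f  selectivity %s\n", x$sensitivity,
              ifelse(is.na(x$selectivity), "NA",
                     sprintf("%.3f", x$selectivity))))
  invisible(x)
}

#' Write an evaluation report TSV
#'
#' @param result [evaluate()] output.
#' @param path File path.
#' @param percent Also include percent-formatted columns (default TRUE).
#' @export
write_eval_report <- function(result, path, percent = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- "# true_pos\tnref\tnfound\tsensitivity\tselectivity"
  line <- sprintf("%d\t%d\t%d\t%.4f\t%.4f", result$true_pos, result$nref,
                  result$nfound, result$sensitivity, result$selectivity)
  if (percent) {
    header <- paste0(header, "\tsensitivity_pct\tselectivity_pct")
    line <- sprintf("%s\t%.1f\t%.1f", line, 100 * result$sensitivity,
                    100 * result$selectivity)
  }
  writeLines(c(header, line), con)
  invisible(path)
}
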