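# Single-linkage chaining of nearby same-strand hits into candidate coding
# regions. Clusters bridge introns (frames may differ within a cluster); the
# gap threshold is what keeps neighbouring genes apart.

#' Clustering parameters
#'
#' @param maxdist Maximum number of nucleotides separating two consecutive
#'   hits for them to join one cluster (default 5000).
#' @param minhit Minimum number of hits per emitted cluster (default 3).
#' @param minpep Minimum number of distinct peptides (I/L-normalized
#'   peptide strings) per emitted cluster (default 2).
#' @param strand_aware If TRUE (default), hits on opposite strands never
#'   co-cluster.
#' @return List of class `cluster_params`.
#' @export
cluster_params <- function(maxdist = 5000L, minhit = 3L, minpep = 2L,
                           strand_aware = TRUE) {
  stopifnot(maxdist >= 0L, minhit >= 1L, minpep >= 1L)
  structure(list(maxdist = as.integer(maxdist), minhit = as.integer(minhit),
                 minpep = as.integer(minpep),
                 strand_aware = isTRUE(strand_aware)),
            class = "cluster_params")
}

#' Cluster hits into candidate coding regions
#'
#' Per contig (and strand, unless `strand_aware = FALSE`), hits sorted by
#' start are chained while the gap to the running cluster end — the number
#' of bases strictly between the cluster's rightmost base and the next
#' hit's first base — is at most `maxdist`. Chains failing `minhit` or
#' `minpep` are discarded. Cluster ids are deterministic: contigs in sorted
#' order, then span start.
#'
#' @param hits Hits data.frame from [map_psts()].
#' @param params [cluster_params()].
#' @return data.frame with columns `cluster_id`, `contig`, `strand`,
#'   `start`, `end`, `n_hits`, `n_peptides`, `n_spectra`, and a list column
#'   `hit_rows` holding the row indices of member hits in `hits`.
#' @export
cluster_hits <- function(hits, params = cluster_params()) {
  empty <- data.frame(cluster_id = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), n_hits = integer(),
                      n_peptides = integer(), n_spectra = integer(),
                      stringsAsFactors = FALSE)
  empty$hit_rows <- list()
  if (is.null(hits) || !nrow(hits)) return(empty)

  grp <- if (params$strand_aware) paste(hits$contig, hits$strand) else
    hits$contig
  clusters <- list()
  for (g in unique(grp)) {
    rows <- which(grp == g)
    o <- rows[order(hits$start[rows], hits$end[rows])]
    cur <- o[1L]
    cur_end <- hits$end[o[1L]]
    for (i in seq_along(o)[-1L]) {
      r <- o[i]
      gap <- hits$start[r] - cur_end - 1L
      if (gap <= params$maxdist) {
        cur <- c(cur, r)
        cur_end <- max(cur_end, hits$end[r])
      } else {
        clusters[[length(clusters) + 1L]] <- cur
        cur <- r
        cur_end <- hits$end[r]
      }
    }
    clusters[[length(clusters) + 1L]] <- cur
  }

  keep <- list()
  for (members in clusters) {
    n_pep <- length(unique(.il_norm(hits$peptide[members])))
    if (length(members) < params$minhit || n_pep < params$minpep) next
    keep[[length(keep) + 1L]] <- list(
      contig = hits$contig[members[1L]],
      strand = if (params$strand_aware) hits$strand[members[1L]] else "*",
      start = min(hits$start[members]), end = max(hits$end[members]),
      n_hits = length(members), n_peptides = n_pep,
      n_spectra = length(unique(hits$spectrum_id[members])),
      hit_rows = members)
  }
  if (!length(keep)) return(empty)
  res <- data.frame(
    cluster_id = NA_character_,
    contig = vapply(keep, `[[`, "", "contig"),
    strand = vapply(keep, `[[`, "", "strand"),
    start = vapply(keep, `[[`, 1L, "start"),
    end = vapply(keep, `[[`, 1L, "end"),
    n_hits = vapply(keep, `[[`, 1L, "n_hits"),
    n_peptides = vapply(keep, `[[`, 1L, "n_peptides"),
    n_spectra = vapply(keep, `[[`, 1L, "n_spectra"),
    stringsAsFactors = FALSE)
  res$hit_rows <- lapply(keep, `[[`, "hit_rows")
  res <- res[order(res$contig, res$start, res$end, res$strand), ]
  res$cluster_id <- sprintf("cluster_%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' Write a cluster summary TSV
#'
#' Columns: cluster_id, contig, strand, from, to, tot_hit, n_peptides,
#' n_spectra (1-based inclusive coordinates).
#'
#' @param clusters [cluster_hits()] output.
#' @param path File path.
#' @export
write_clusters <- function(clusters, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cluster_id\tcontig\tstrand\tfrom\tto\ttot_hit\tn_peptides\tn_spectra",
             con)
  if (nrow(clusters)) {
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d",
                       clusters$cluster_id, clusters$contig, clusters$strand,
                       clusters$start, clusters$end, clusters$n_hits,
                       clusters$n_peptides, clusters$n_spectra), con)
  }
  invisible(path)
}
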