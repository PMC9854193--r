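#' Find clusters of near-identical k-mer repeats within one transcript
#'
#' Searches a transcript (sense strand; dCas13 targets the mRNA, so the
#' reverse complement is never scanned) for groups of length-\code{k}
#' fragments that are identical or differ by at most \code{max_mismatch}
#' substitutions, the criterion that makes a transcript targetable by a
#' single guide RNA at multiple copies.
#'
#' Two mismatch topologies are supported. \code{"pairwise"} (default)
#' requires every pair of fragments in a cluster to be within
#' \code{max_mismatch}; for \code{max_mismatch = 1} such a cluster is
#' exactly a set of fragments identical outside a single variable column,
#' so clusters are found by hashing each k-mer \code{k} times with one
#' position masked. \code{"star"} only requires every fragment to be
#' within \code{max_mismatch} of the cluster's seed fragment, so two
#' members may differ at two positions.
#'
#' Within each cluster, occurrences are made non-overlapping by greedy
#' left-to-right selection (ties broken by smaller start); the cluster
#' motif is the sequence of the first retained occurrence. \code{U} is
#' read as \code{T}; windows containing \code{N} (or any other ambiguity
#' code) are skipped, since \code{N} never matches.
#'
#' @param sequence nucleotide string (sense strand).
#' @param transcript_id identifier attached to the clusters.
#' @param k motif length, nt (>= 8).
#' @param max_mismatch maximum allowed Hamming distance (0 or 1).
#' @param topology \code{"pairwise"} or \code{"star"} (see Details).
#' @return list of clusters; each cluster is a list with
#'   \code{transcript_id}, \code{motif}, \code{k}, \code{starts} (0-based,
#'   sorted, non-overlapping), \code{occ_seqs}, \code{mismatches}
#'   (per-occurrence Hamming distance to the motif) and
#'   \code{max_pairwise_mismatch}.
#' @examples
#' s <- paste0(strrep("A", 30), strrep("ACGTTGCA", 3), strrep("C", 30))
#' find_repeat_clusters(s, "tx", k = 8)
#' @export
find_repeat_clusters <- function(sequence, transcript_id = "tx", k = 20L,
                                 max_mismatch = 1L,
                                 topology = c("pairwise", "star")) {
  topology <- match.arg(topology)
  if (!max_mismatch %in% c(0L, 1L))
    stop("'max_mismatch' must be 0 or 1", call. = FALSE)
  if (k < 8) stop("'k' must be >= 8", call. = FALSE)
  sequence <- gsub("U", "T", toupper(sequence))
  n <- nchar(sequence)
  if (n == 0) stop("empty sequence", call. = FALSE)
  if (n < k) {
    warning("sequence shorter than k; no clusters possible", call. = FALSE)
    return(list())
  }

  starts0 <- 0:(n - k)                       # 0-based
  kmers <- substring(sequence, starts0 + 1L, starts0 + k)
  ok <- grepl("^[ACGT]+$", kmers)
  starts0 <- starts0[ok]; kmers <- kmers[ok]
  if (length(starts0) < 2) return(list())

  groups <- if (max_mismatch == 0L) {
    g <- split(starts0, kmers)
    g[lengths(g) >= 2]
  } else if (topology == "pairwise") {
    out <- list()
    for (i in seq_len(k)) {
      key <- paste0(substr(kmers, 1, i - 1L), "*", substr(kmers, i + 1L, k))
      g <- split(starts0, key)
      out <- c(out, unname(g[lengths(g) >= 2]))
    }
    out
  } else { # star: union of the seed's masked groups, per distinct seed
    key_map <- new.env(parent = emptyenv())
    keys_of <- vector("list", k)
    for (i in seq_len(k)) {
      key <- paste0(substr(kmers, 1, i - 1L), "*", substr(kmers, i + 1L, k))
      keys_of[[i]] <- key
      sp <- split(starts0, key)
      for (nm in names(sp)) {
        prev <- key_map[[nm]]
        key_map[[nm]] <- if (is.null(prev)) sp[[nm]] else c(prev, sp[[nm]])
      }
    }
    seed_idx <- which(!duplicated(kmers))
    out <- lapply(seed_idx, function(j) {
      members <- unlist(lapply(seq_len(k),
                               function(i) key_map[[keys_of[[i]][j]]]))
      sort(unique(members))
    })
    out[lengths(out) >= 2]
  }
  if (!length(groups)) return(list())

  # greedy non-overlapping selection, left to right
  kmer_at <- function(s) substring(sequence, s + 1L, s + k)
  selected <- lapply(groups, function(g) {
    g <- sort(unique(g))
    keep <- g[1]; last <- g[1]
    for (s in g[-1]) if (s >= last + k) { keep <- c(keep, s); last <- s }
    keep
  })
  selected <- selected[lengths(selected) >= 2]
  if (!length(selected)) return(list())

  # dedupe identical occurrence sets, then drop subsets of larger clusters
  key <- vapply(selected, function(s) paste(s, collapse = ","), "")
  selected <- selected[!duplicated(key)]
  if (length(selected) > 1) {
    is_sub <- vapply(seq_along(selected), function(i) {
      any(vapply(seq_along(selected), function(j)
        j != i && length(selected[[j]]) > length(selected[[i]]) &&
          all(selected[[i]] %in% selected[[j]]), TRUE))
    }, TRUE)
    selected <- selected[!is_sub]
  }

  lapply(selected, function(st) {
    seqs <- kmer_at(st)
    motif <- seqs[1]
    mm <- vapply(seqs, hamming, 0L, b = motif, USE.NAMES = FALSE)
    max_pw <- if (length(seqs) > 2 || topology == "star") {
      max(vapply(seq_along(seqs), function(i)
        max(vapply(seqs, hamming, 0L, b = seqs[i])), 0L))
    } else max(mm)
    list(transcript_id = transcript_id, motif = motif, k = as.integer(k),
         starts = st, occ_seqs = seqs, mismatches = mm,
         max_pairwise_mismatch = max_pw)
  })
}

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Screen a transcriptome for repeat-containing transcripts
#'
#' Runs \code{\link{find_repeat_clusters}} on every transcript and
#' assembles a \code{screen_result} that the uniqueness filter and
#' candidate selection operate on.
#'
#' @param sequences named character vector of transcript sequences (or a
#'   FASTA path).
#' @param gene_map optional data frame with columns \code{transcript_id},
#'   \code{gene_id}; transcripts without an entry are their own gene.
#' @param k,max_mismatch,topology passed to
#'   \code{\link{find_repeat_clusters}}.
#' @return A \code{screen_result}: list with \code{clusters} (list of
#'   cluster objects, each carrying \code{gene_id}), \code{transcripts}
#'   (per-transcript summary data frame) and \code{params}.
#' @export
screen_transcriptome <- function(sequences, gene_map = NULL, k = 20L,
                                 max_mismatch = 1L,
                                 topology = c("pairwise", "star")) {
  topology <- match.arg(topology)
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- read_fasta(sequences)
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named", call. = FALSE)
  gene_of <- setNames(ids, ids)
  if (!is.null(gene_map)) {
    stopifnot(all(c("transcript_id", "gene_id") %in% names(gene_map)))
    gene_of[gene_map$transcript_id] <- gene_map$gene_id
  }
  clusters <- list()
  for (id in ids) {
    cl <- find_repeat_clusters(sequences[[id]], transcript_id = id, k = k,
                               max_mismatch = max_mismatch,
                               topology = topology)
    for (c_i in seq_along(cl)) cl[[c_i]]$gene_id <- unname(gene_of[id])
    clusters <- c(clusters, cl)
  }
  res <- structure(list(clusters = clusters,
                        transcripts = data.frame(
                          transcript_id = ids,
                          gene_id = unname(gene_of[ids]),
                          stringsAsFactors = FALSE),
                        params = list(k = k, max_mismatch = max_mismatch,
                                      topology = topology)),
                   class = "screen_result")
  refresh_screen_summary(res)
}

refresh_screen_summary <- function(res) {
  tx <- res$transcripts
  n_cl <- integer(nrow(tx)); max_occ <- integer(nrow(tx))
  for (cl in res$clusters) {
    i <- match(cl$transcript_id, tx$transcript_id)
    n_cl[i] <- n_cl[i] + 1L
    max_occ[i] <- max(max_occ[i], length(cl$starts))
  }
  tx$n_clusters <- n_cl
  tx$max_occurrences <- max_occ
  res$transcripts <- tx
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d transcript(s), %d cluster(s) (k = %d, max mismatch = %d, %s)\n",
              nrow(x$transcripts), length(x$clusters), x$params$k,
              x$params$max_mismatch, x$params$topology))
  if (!is.null(x$transcripts$candidate))
    cat(sprintf("  candidates at min_repeats = %d: %d (>=2 repeats: %d)\n",
                x$params$min_repeats, sum(x$transcripts$candidate),
                sum(x$transcripts$max_occurrences >= 2)))
  invisible(x)
}

#' Remove repeat clusters whose motif occurs in more than one gene
#'
#' A repeat unit shared between genes cannot give a gene-specific guide
#' RNA, so every cluster whose occurrence sequences also appear (exactly,
#' or within Hamming distance 1 when \code{tolerant}) in a cluster of a
#' \emph{different} gene is dropped from the screen. Isoforms of the same
#' gene never trigger removal.
#'
#' @param res a \code{screen_result}.
#' @param tolerant if \code{TRUE} (default), cross-gene matching allows
#'   one mismatch; if \code{FALSE}, only exact motif identity removes.
#' @return the filtered \code{screen_result}.
#' @export
cross_gene_uniqueness_filter <- function(res, tolerant = TRUE) {
  stopifnot(inherits(res, "screen_result"))
  if (!length(res$clusters)) return(res)
  # key -> set of genes carrying an occurrence sequence with that key
  key_genes <- new.env(parent = emptyenv())
  add_key <- function(key, gene) {
    key_genes[[key]] <- union(key_genes[[key]], gene)
  }
  keys_of_seq <- function(s) {
    if (!tolerant) return(s)
    k <- nchar(s)
    c(s, vapply(seq_len(k), function(i)
      paste0(substr(s, 1, i - 1L), "*", substr(s, i + 1L, k)), ""))
  }
  for (cl in res$clusters)
    for (s in unique(cl$occ_seqs))
      for (key in keys_of_seq(s)) add_key(key, cl$gene_id)
  keep <- vapply(res$clusters, function(cl) {
    for (s in unique(cl$occ_seqs))
      for (key in keys_of_seq(s))
        if (length(key_genes[[key]]) > 1L) return(FALSE)
    TRUE
  }, TRUE)
  res$clusters <- res$clusters[keep]
  refresh_screen_summary(res)
}

#' Flag candidate transcripts by repeat copy number
#'
#' A transcript is a labelling candidate when one of its clusters retains
#' at least \code{min_repeats} non-overlapping occurrences, i.e. enough
#' repeat copies for a bright multi-copy dCas13 signal.
#'
#' @param res a \code{screen_result} (ideally already uniqueness-filtered).
#' @param min_repeats minimum occurrences in a single cluster.
#' @return the \code{screen_result} with a logical \code{candidate} column
#'   on \code{$transcripts} and a \code{$summary} list reporting counts at
#'   thresholds 2, 8 and \code{min_repeats}.
#' @export
select_candidates <- function(res, min_repeats = 8L) {
  stopifnot(inherits(res, "screen_result"))
  res <- refresh_screen_summary(res)
  res$transcripts$candidate <- res$transcripts$max_occurrences >= min_repeats
  res$params$min_repeats <- as.integer(min_repeats)
  res$summary <- list(
    n_transcripts = nrow(res$transcripts),
    n_with_2plus = sum(res$transcripts$max_occurrences >= 2),
    n_with_8plus = sum(res$transcripts$max_occurrences >= 8),
    n_candidates = sum(res$transcripts$candidate))
  res
}

#' Mean normalized expression of screened transcripts per cell type
#'
#' Library-size-normalizes a cell-by-gene count table (each cell's counts
#' divided by its total, times \code{scale_factor}) and averages within
#' cell-type labels, the summary used to ask whether a repeat-carrying
#' transcript is expressed in the window of interest.
#'
#' @param counts cell-by-gene matrix or data frame of non-negative counts;
#'   rows are cells.
#' @param cell_labels cell-type label per row of \code{counts}.
#' @param transcripts optional subset of gene columns to report.
#' @param scale_factor normalization scale (default 1: per-cell
#'   proportions).
#' @return matrix of mean normalized expression, cell types x transcripts.
#' @export
expression_summary <- function(counts, cell_labels, transcripts = NULL,
                               scale_factor = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (length(cell_labels) != nrow(counts))
    stop("'cell_labels' must have one label per row of 'counts'",
         call. = FALSE)
  if (is.null(transcripts)) transcripts <- colnames(counts)
  missing_tx <- setdiff(transcripts, colnames(counts))
  if (length(missing_tx))
    stop("transcripts absent from counts: ",
         paste(missing_tx, collapse = ", "), call. = FALSE)
  lib <- rowSums(counts)
  norm <- counts / ifelse(lib == 0, 1, lib) * scale_factor
  norm <- norm[, transcripts, drop = FALSE]
  labs <- sort(unique(cell_labels))
  out <- t(vapply(labs, function(l)
    colMeans(norm[cell_labels == l, , drop = FALSE]),
    numeric(length(transcripts))))
  rownames(out) <- labs
  out
}

#' Write screen clusters as TSV
#'
#' One row per cluster: \code{transcript_id}, \code{gene_id},
#' \code{motif}, \code{n_occurrences}, \code{starts} (1-based, inclusive,
#' semicolon-joined) and \code{max_pairwise_mismatch}.
#'
#' @param res a \code{screen_result}.
#' @param path output TSV path.
#' @return the cluster table, invisibly.
#' @export
write_clusters_tsv <- function(res, path) {
  tab <- clusters_table(res)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' @rdname write_clusters_tsv
#' @export
clusters_table <- function(res) {
  stopifnot(inherits(res, "screen_result"))
  if (!length(res$clusters))
    return(data.frame(transcript_id = character(), gene_id = character(),
                      motif = character(), n_occurrences = integer(),
                      starts = character(),
                      max_pairwise_mismatch = integer()))
  do.call(rbind, lapply(res$clusters, function(cl) data.frame(
    transcript_id = cl$transcript_id, gene_id = cl$gene_id,
    motif = cl$motif, n_occurrences = length(cl$starts),
    starts = paste(cl$starts + 1L, collapse = ";"),  # 1-based in reports
    max_pairwise_mismatch = cl$max_pairwise_mismatch,
    stringsAsFactors = FALSE)))
}
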