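#' Specify a planted repeat cluster
#'
#' Describes a motif to embed several times in one synthetic transcript,
#' optionally with single-base substitutions in chosen copies, for
#' exercising the repeat screen against known ground truth.
#'
#' @param transcript_id transcript name.
#' @param motif repeat unit, sense strand (A/C/G/T/U).
#' @param n_copies number of embedded copies (>= 1).
#' @param mismatch_positions optional data frame with columns \code{copy}
#'   (1-based copy index), \code{offset} (0-based position within the
#'   motif) and \code{base} (substituted base).
#' @param spacing minimum gap between consecutive copies, nt.
#' @param gene_id gene the transcript belongs to (defaults to the
#'   transcript id).
#' @return A \code{planted_repeat_spec} list.
#' @export
planted_repeat_spec <- function(transcript_id, motif, n_copies,
                                mismatch_positions = NULL, spacing = 30,
                                gene_id = transcript_id) {
  motif <- toupper(gsub("U", "T", motif))
  if (!grepl("^[ACGT]+$", motif))
    stop("motif must be A/C/G/T/U only", call. = FALSE)
  if (!is.null(mismatch_positions)) {
    stopifnot(all(c("copy", "offset", "base") %in%
                    names(mismatch_positions)))
    if (any(mismatch_positions$offset >= nchar(motif)))
      stop("mismatch offsets must be < motif length", call. = FALSE)
    if (any(mismatch_positions$copy > n_copies))
      stop("mismatch copy index exceeds n_copies", call. = FALSE)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 motif = motif, n_copies = as.integer(n_copies),
                 mismatch_positions = mismatch_positions,
                 spacing = as.integer(spacing)),
            class = "planted_repeat_spec")
}

#' Simulate a transcriptome with planted repeat clusters
#'
#' Builds random-sequence transcripts, embeds the repeat copies described
#' by each \code{\link{planted_repeat_spec}} at recorded positions, and
#' adds repeat-free decoy transcripts. A chance exact 20-mer repeat within
#' a few-kilobase random sequence is vanishingly unlikely, so decoys are
#' effectively guaranteed clean at the default motif length.
#'
#' @param specs list of \code{\link{planted_repeat_spec}} objects.
#' @param n_decoys number of decoy transcripts.
#' @param length_range range (nt) of transcript lengths, used for decoys
#'   and as the minimum length of planted transcripts.
#' @param seed integer seed.
#' @return list with \code{sequences} (named character vector),
#'   \code{gene_map} (data frame \code{transcript_id}, \code{gene_id}) and
#'   \code{ground_truth} (data frame \code{transcript_id}, \code{gene_id},
#'   \code{copy}, \code{start} (0-based), \code{mismatches}).
#' @examples
#' spec <- planted_repeat_spec("tx1", strrep("ACGT", 5), n_copies = 3)
#' tt <- gen_transcriptome(list(spec), n_decoys = 2,
#'                         length_range = c(300, 400), seed = 1)
#' names(tt$sequences)
#' @export
gen_transcriptome <- function(specs = list(), n_decoys = 0,
                              length_range = c(500, 2000), seed = NULL) {
  with_seed(seed, {
    seqs <- character(0); gt <- list(); gene_map <- list()
    rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")
    for (sp in specs) {
      stopifnot(inherits(sp, "planted_repeat_spec"))
      k <- nchar(sp$motif)
      need <- sp$n_copies * (k + sp$spacing) + sp$spacing
      len <- max(need, round(runif(1, length_range[1], length_range[2])))
      if (k > len)
        stop("motif longer than transcript length", call. = FALSE)
      base <- strsplit(rand_seq(len), "")[[1]]
      # random non-overlapping starts with at least `spacing` nt between
      # copies: distribute the slack among the gaps before each copy
      slack <- len - sp$n_copies * (k + sp$spacing)
      gaps <- sp$spacing + floor(slack * diff(c(0, sort(runif(sp$n_copies)))))
      starts <- cumsum(gaps + k) - k  # 0-based
      mm_counts <- integer(sp$n_copies)
      for (ci in seq_len(sp$n_copies)) {
        unit <- strsplit(sp$motif, "")[[1]]
        if (!is.null(sp$mismatch_positions)) {
          mm <- sp$mismatch_positions[sp$mismatch_positions$copy == ci, ,
                                      drop = FALSE]
          if (nrow(mm)) {
            unit[mm$offset + 1L] <- toupper(gsub("U", "T", mm$base))
            mm_counts[ci] <- nrow(mm)
          }
        }
        base[(starts[ci] + 1L):(starts[ci] + k)] <- unit
      }
      seqs[sp$transcript_id] <- paste(base, collapse = "")
      gene_map[[sp$transcript_id]] <-
        data.frame(transcript_id = sp$transcript_id, gene_id = sp$gene_id)
      gt[[sp$transcript_id]] <- data.frame(
        transcript_id = sp$transcript_id, gene_id = sp$gene_id,
        copy = seq_len(sp$n_copies), start = starts,
        mismatches = mm_counts)
    }
    for (d in seq_len(n_decoys)) {
      id <- sprintf("decoy_%03d", d)
      seqs[id] <- rand_seq(round(runif(1, length_range[1], length_range[2])))
      gene_map[[id]] <- data.frame(transcript_id = id, gene_id = id)
    }
    list(sequences = seqs,
         gene_map = do.call(rbind, unname(gene_map)),
         ground_truth = if (length(gt)) do.call(rbind, unname(gt))
                        else data.frame(transcript_id = character(),
                                        gene_id = character(),
                                        copy = integer(), start = integer(),
                                        mismatches = integer()))
  })
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param sequences named character vector of nucleotide sequences.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(gsub("U", "T", toupper(sequences)))
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(as.character(set), sub("\\s.*$", "", names(set)))
}
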