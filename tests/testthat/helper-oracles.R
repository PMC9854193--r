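# Independent brute-force oracles used across test files.

# MSD by explicit double loop over all frame pairs
oracle_msd <- function(traj, max_lag) {
  x <- traj$x_um; y <- traj$y_um; n <- length(x)
  vapply(seq_len(max_lag), function(l) {
    acc <- 0; cnt <- 0
    for (i in seq_len(n - l)) {
      acc <- acc + (x[i + l] - x[i])^2 + (y[i + l] - y[i])^2
      cnt <- cnt + 1
    }
    acc / cnt
  }, 0)
}

oracle_hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# all k-mer pairs within Hamming <= max_mm, by direct O(n^2 k) comparison
oracle_close_pairs <- function(sequence, k, max_mm = 1) {
  sequence <- gsub("U", "T", toupper(sequence))
  n <- nchar(sequence)
  starts <- 0:(n - k)
  kmers <- substring(sequence, starts + 1, starts + k)
  keep <- grepl("^[ACGT]+$", kmers)
  starts <- starts[keep]; kmers <- kmers[keep]
  pairs <- list()
  for (i in seq_along(starts)) {
    for (j in seq_along(starts)) {
      if (j <= i) next
      if (abs(starts[j] - starts[i]) < k) next  # overlapping
      if (oracle_hamming(kmers[i], kmers[j]) <= max_mm)
        pairs[[length(pairs) + 1L]] <- c(starts[i], starts[j])
    }
  }
  pairs
}

# validity check of reported clusters against direct string comparison
clusters_valid <- function(clusters, sequence, k, max_mm = 1) {
  sequence <- gsub("U", "T", toupper(sequence))
  for (cl in clusters) {
    st <- cl$starts
    if (length(st) < 2) return(FALSE)
    if (is.unsorted(st)) return(FALSE)
    if (any(diff(st) < k)) return(FALSE)            # overlap
    seqs <- substring(sequence, st + 1, st + k)
    for (i in seq_along(seqs))
      for (j in seq_along(seqs))
        if (i < j && oracle_hamming(seqs[i], seqs[j]) > max_mm)
          return(FALSE)
  }
  TRUE
}

# every close non-overlapping pair must appear together in some cluster
# (only guaranteed when repeats are spaced >= k apart)
pairs_covered <- function(clusters, pairs) {
  for (p in pairs) {
    hit <- any(vapply(clusters, function(cl)
      all(p %in% cl$starts), TRUE))
    if (!hit) return(FALSE)
  }
  TRUE
}

# independent reimplementation of pairwise max_mm<=1 clustering by direct
# character comparison (no hashing): for every window and every allowed
# variable column, collect all windows identical outside that column,
# then apply the same greedy/dedupe/maximality rules
oracle_repeat_clusters <- function(sequence, k, max_mm = 1) {
  sequence <- gsub("U", "T", toupper(sequence))
  n <- nchar(sequence)
  if (n < k) return(list())
  starts <- 0:(n - k)
  chars <- strsplit(substring(sequence, starts + 1, starts + k), "")
  keep <- vapply(chars, function(cc) all(cc %in% c("A", "C", "G", "T")), TRUE)
  starts <- starts[keep]; chars <- chars[keep]
  m <- length(starts)
  if (m < 2) return(list())
  M <- do.call(rbind, chars)
  cand <- list()
  for (i in seq_len(m)) {
    diffs <- M != matrix(M[i, ], m, k, byrow = TRUE)
    total <- rowSums(diffs)
    if (max_mm == 0) {
      members <- starts[total == 0]
      if (length(members) >= 2)
        cand[[length(cand) + 1L]] <- sort(unique(members))
    } else {
      for (p in seq_len(k)) {
        members <- starts[total - diffs[, p] == 0]
        if (length(members) >= 2)
          cand[[length(cand) + 1L]] <- sort(unique(members))
      }
    }
  }
  # greedy non-overlap, then dedupe and drop subsets
  sel <- lapply(cand, function(g) {
    kept <- g[1]; last <- g[1]
    for (s in g[-1]) if (s >= last + k) { kept <- c(kept, s); last <- s }
    kept
  })
  sel <- sel[lengths(sel) >= 2]
  sel <- sel[!duplicated(vapply(sel, paste, "", collapse = ","))]
  if (length(sel) > 1) {
    sub <- vapply(seq_along(sel), function(i)
      any(vapply(seq_along(sel), function(j)
        j != i && length(sel[[j]]) > length(sel[[i]]) &&
          all(sel[[i]] %in% sel[[j]]), TRUE)), TRUE)
    sel <- sel[!sub]
  }
  sel
}

cluster_start_sets <- function(clusters) {
  sets <- lapply(clusters, function(cl)
    if (is.list(cl)) cl$starts else cl)
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, paste, "", collapse = ","))]
}

# deterministic random DNA
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
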