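plant_in_random <- function(motif, starts, len, seed) {
  s <- strsplit(random_dna(len, seed), "")[[1]]
  for (st in starts)
    s[(st + 1):(st + nchar(motif))] <- strsplit(motif, "")[[1]]
  paste(s, collapse = "")
}

test_that("exact triple repeat is found as one 3-occurrence cluster", {
  motif <- random_dna(20, seed = 31)
  starts <- c(10L, 110L, 230L)
  s <- plant_in_random(motif, starts, 300, seed = 32)
  cl <- find_repeat_clusters(s, k = 20)
  # windows shifted off the planted frame form their own (1-mismatch,
  # flank-column) clusters; the planted-motif cluster is the exact one
  planted <- Filter(function(x) x$motif == motif, cl)
  expect_length(planted, 1)
  expect_identical(planted[[1]]$starts, starts)
  expect_equal(planted[[1]]$max_pairwise_mismatch, 0L)
  expect_length(Filter(function(x) length(x$starts) > 3, cl), 0)
})

test_that("a copy with two substitutions is excluded from the cluster", {
  motif <- random_dna(20, seed = 33)
  mutate <- function(m, pos) {
    ch <- strsplit(m, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  s <- paste0(substr(random_dna(40, 34), 1, 40), motif,
              substr(random_dna(40, 35), 1, 40), motif,
              substr(random_dna(40, 36), 1, 40), mutate(motif, c(3, 11)),
              substr(random_dna(40, 37), 1, 40))
  cl <- find_repeat_clusters(s, k = 20)
  # no cluster may bridge the double mutant; the planted-motif cluster
  # keeps only the two intact copies
  expect_true(all(vapply(cl, function(x) length(x$starts), 0L) <= 2))
  planted <- Filter(function(x) x$motif == motif, cl)
  expect_length(planted, 1)
  expect_length(planted[[1]]$starts, 2)
})

test_that("single-mismatch copies join the cluster (pairwise rule)", {
  motif <- random_dna(20, seed = 38)
  ch <- strsplit(motif, "")[[1]]
  ch[7] <- setdiff(c("A", "C", "G", "T"), ch[7])[1]
  variant <- paste(ch, collapse = "")
  s <- paste0(random_dna(30, 39), motif, random_dna(30, 40), variant,
              random_dna(30, 41), motif, random_dna(30, 42))
  cl <- find_repeat_clusters(s, k = 20)
  big <- Filter(function(x) length(x$starts) >= 3, cl)
  expect_length(big, 1)
  expect_equal(big[[1]]$max_pairwise_mismatch, 1L)
})

test_that("sequences shorter than 2k with no repeat yield nothing", {
  expect_length(find_repeat_clusters(random_dna(30, 50), k = 20), 0)
  expect_warning(out <- find_repeat_clusters(random_dna(10, 51), k = 20),
                 "shorter")
  expect_length(out, 0)
  expect_error(find_repeat_clusters("", k = 20), "empty")
})

test_that("pairwise and star topologies differ exactly where they should", {
  # A, B differ at position 2; A, C differ at position 5; B-C distance 2
  A <- random_dna(12, seed = 60)
  mk <- function(m, p) {
    ch <- strsplit(m, "")[[1]]
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  B <- mk(A, 2); C <- mk(A, 5)
  s <- paste0(random_dna(20, 61), A, random_dna(20, 62), B,
              random_dna(20, 63), C, random_dna(20, 64))
  pw <- find_repeat_clusters(s, k = 12, topology = "pairwise")
  st <- find_repeat_clusters(s, k = 12, topology = "star")
  expect_true(all(vapply(pw, function(cl) length(cl$starts), 0L) <= 2))
  expect_true(all(vapply(pw, function(cl) cl$max_pairwise_mismatch, 0L)
                  <= 1))
  sizes <- vapply(st, function(cl) length(cl$starts), 0L)
  expect_true(any(sizes == 3))   # star centered on A collects B and C
  star3 <- st[[which(sizes == 3)[1]]]
  expect_equal(star3$max_pairwise_mismatch, 2L)
})

test_that("clustering equals the brute-force oracle on small instances", {
  cases <- list(
    list(seq = random_dna(300, 70), k = 8),
    list(seq = random_dna(500, 71), k = 8),
    list(seq = plant_in_random(random_dna(15, 72), c(20, 60, 130), 200, 73),
         k = 15),
    list(seq = plant_in_random(strrep("AT", 10), c(10, 40, 90, 150), 250,
                               74), k = 20),
    list(seq = strrep("ACGTT", 30), k = 10))
  for (cs in cases) {
    got <- find_repeat_clusters(cs$seq, k = cs$k)
    want <- oracle_repeat_clusters(cs$seq, k = cs$k)
    expect_identical(cluster_start_sets(got), cluster_start_sets(want))
    expect_true(clusters_valid(got, cs$seq, cs$k))
  }
})

test_that("planted repeats with spacing >= k are recovered exactly", {
  for (seed in 1:5) {
    motif <- random_dna(20, seed = 200 + seed)
    spec <- planted_repeat_spec("tx", motif, n_copies = 5, spacing = 30)
    tt <- gen_transcriptome(list(spec), length_range = c(400, 500),
                            seed = 300 + seed)
    gt <- tt$ground_truth
    cl <- find_repeat_clusters(tt$sequences[["tx"]], k = 20)
    planted <- Filter(function(x) x$motif == motif, cl)
    expect_length(planted, 1)
    expect_identical(planted[[1]]$starts, as.integer(sort(gt$start)))
    pairs <- oracle_close_pairs(tt$sequences[["tx"]], 20)
    expect_true(pairs_covered(cl, pairs))
  }
})

test_that("cross-gene uniqueness filter removes shared motifs only", {
  motif <- random_dna(20, seed = 80)
  uniq <- random_dna(20, seed = 81)
  seqs <- c(
    g1_tx1 = plant_in_random(motif, c(10, 60), 150, 82),
    g2_tx1 = plant_in_random(motif, c(20, 70), 150, 83),
    g3_tx1 = plant_in_random(uniq, c(5, 55), 150, 84),
    g3_tx2 = plant_in_random(uniq, c(15, 65), 150, 85))
  gm <- data.frame(transcript_id = names(seqs),
                   gene_id = c("g1", "g2", "g3", "g3"))
  res <- screen_transcriptome(seqs, gene_map = gm, k = 20)
  filt <- cross_gene_uniqueness_filter(res)
  left <- vapply(filt$clusters, `[[`, "", "gene_id")
  expect_false(any(left %in% c("g1", "g2")))  # shared motif: both removed
  expect_true(all(left == "g3"))              # same-gene isoforms retained
})

test_that("tolerant cross-gene matching also catches 1-mismatch motifs", {
  motif <- random_dna(20, seed = 90)
  ch <- strsplit(motif, "")[[1]]
  ch[4] <- setdiff(c("A", "C", "G", "T"), ch[4])[1]
  near <- paste(ch, collapse = "")
  seqs <- c(g1_tx = plant_in_random(motif, c(10, 60), 150, 91),
            g2_tx = plant_in_random(near, c(20, 70), 150, 92))
  gm <- data.frame(transcript_id = names(seqs), gene_id = c("g1", "g2"))
  res <- screen_transcriptome(seqs, gene_map = gm, k = 20)
  motifs_left <- function(r) vapply(r$clusters, `[[`, "", "motif")
  tol <- cross_gene_uniqueness_filter(res, tolerant = TRUE)
  # the planted motif and its 1-mismatch twin are both removed ...
  expect_false(any(motifs_left(tol) %in% c(motif, near)))
  # ... and every survivor is a shifted window, > 1 mismatch from both
  expect_true(all(vapply(motifs_left(tol), function(m)
    min(oracle_hamming(m, motif), oracle_hamming(m, near)) > 1, TRUE)))
  # exact matching sees two different motifs and keeps both
  exact <- cross_gene_uniqueness_filter(res, tolerant = FALSE)
  expect_true(all(c(motif, near) %in% motifs_left(exact)))
})

test_that("candidate selection respects the copy-number threshold", {
  m1 <- random_dna(20, seed = 95); m2 <- random_dna(20, seed = 96)
  tt <- gen_transcriptome(
    list(planted_repeat_spec("tx12", m1, 12, spacing = 25),
         planted_repeat_spec("tx7", m2, 7, spacing = 25)),
    n_decoys = 1, length_range = c(600, 700), seed = 97)
  res <- select_candidates(
    cross_gene_uniqueness_filter(screen_transcriptome(tt$sequences, k = 20)),
    min_repeats = 8)
  tx <- res$transcripts
  expect_true(tx$candidate[tx$transcript_id == "tx12"])
  expect_false(tx$candidate[tx$transcript_id == "tx7"])
  expect_equal(res$summary$n_with_2plus, 2)
  expect_equal(res$summary$n_with_8plus, 1)
})

test_that("raising min_repeats never increases the candidate count", {
  tt <- gen_transcriptome(
    list(planted_repeat_spec("a", random_dna(20, 101), 9, spacing = 22),
         planted_repeat_spec("b", random_dna(20, 102), 4, spacing = 22),
         planted_repeat_spec("c", random_dna(20, 103), 2, spacing = 22)),
    length_range = c(400, 500), seed = 104)
  res <- screen_transcriptome(tt$sequences, k = 20)
  counts <- vapply(c(2, 4, 8, 10), function(mr)
    select_candidates(res, min_repeats = mr)$summary$n_candidates, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("raising max_mismatch never shrinks cluster sizes", {
  motif <- random_dna(20, seed = 110)
  ch <- strsplit(motif, "")[[1]]
  ch[9] <- setdiff(c("A", "C", "G", "T"), ch[9])[1]
  variant <- paste(ch, collapse = "")
  s <- paste0(random_dna(25, 111), motif, random_dna(25, 112), motif,
              random_dna(25, 113), variant, random_dna(25, 114))
  size_at <- function(mm)
    max(vapply(find_repeat_clusters(s, k = 20, max_mismatch = mm),
               function(cl) length(cl$starts), 0L))
  expect_gte(size_at(1), size_at(0))
  expect_equal(size_at(0), 2)  # the exact pair
  expect_equal(size_at(1), 3)  # plus the 1-mismatch copy
})

test_that("expression summary matches hand arithmetic", {
  counts <- matrix(c(10, 0, 5, 5,
                     2, 2, 4, 0,
                     0, 0, 0, 8), nrow = 4,
                   dimnames = list(paste0("cell", 1:4),
                                   c("txA", "txB", "txC")))
  labels <- c("EVL", "EVL", "deep", "deep")
  out <- expression_summary(counts, labels, scale_factor = 1)
  # cell1: totals 12 -> txA 10/12; cell2: 2 -> 0; mean EVL txA = (10/12)/2
  expect_equal(out["EVL", "txA"], (10 / 12 + 0 / 2) / 2)
  expect_equal(out["deep", "txC"], (0 / 9 + 8 / 13) / 2)
  expect_equal(unname(rowSums(out)), c(1, 1))  # proportions sum to 1
  zero <- expression_summary(matrix(0, 2, 2,
                                    dimnames = list(NULL, c("a", "b"))),
                             c("x", "x"))
  expect_true(all(zero == 0))
  one_type <- expression_summary(
    matrix(c(4, 4), 2, 1, dimnames = list(NULL, "a")), c("t", "t"))
  expect_equal(unname(one_type[1, 1]), 1)
  expect_error(expression_summary(counts, labels, transcripts = "nope"),
               "absent")
})
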