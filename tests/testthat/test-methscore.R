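# methscore_core: end counting, the Methscore statistic, classification,
# two-end consensus.

test_that("count_read_ends tallies chosen read ends from SAM records", {
  ref <- rrna_reference("18S", strrep("ACGU", 10))
  sam <- withr::local_tempfile(fileext = ".sam")
  reads <- data.frame(
    qname = c("r1", "r2", "r3", "sec", "unmap", "supp"),
    flag = c(0L, 0L, 0L, 256L, 4L, 2048L),
    pos = c(5L, 5L, 7L, 5L, 5L, 5L),
    cigar = c("16M", "14M", "14M", "16M", "*", "10M"))
  write_sam_fixture(reads, "18S", 40L, sam)
  aln <- read_sam(sam)
  expect_equal(sum(aln$usable), 3)

  p5 <- count_read_ends(aln, ref, end = "5p")
  expect_equal(p5$counts[5], 2L)
  expect_equal(p5$counts[7], 1L)
  expect_equal(sum(p5$counts), 3L)

  p3 <- count_read_ends(aln, ref, end = "3p")
  expect_equal(p3$counts[20], 2L)  # 5 + 16 - 1
  expect_equal(p3$counts[18], 1L)  # 5 + 14 - 1
  expect_equal(sum(p3$counts), 3L)

  # soft clips consume no reference: 3S14M from pos 7 still spans 7..20
  reads2 <- data.frame(qname = "s1", flag = 0L, pos = 7L, cigar = "3S14M2S")
  write_sam_fixture(reads2, "18S", 40L, sam)
  p <- count_read_ends(read_sam(sam), ref, end = "3p")
  expect_equal(p$counts[20], 1L)

  # empty alignment set -> all-zero profile
  write_sam_fixture(reads[0, ], "18S", 40L, sam)
  expect_true(all(count_read_ends(read_sam(sam), ref, "5p")$counts == 0L))

  # unknown reference name -> error naming the record
  reads3 <- data.frame(qname = "bad", flag = 0L, pos = 1L, cigar = "10M")
  write_sam_fixture(reads3, "28S", 40L, sam)
  expect_error(count_read_ends(read_sam(sam), ref, "5p"), "bad")
})

test_that("strand-aware end selection swaps ends for reverse reads", {
  ref <- rrna_reference("18S", strrep("A", 40))
  sam <- withr::local_tempfile(fileext = ".sam")
  reads <- data.frame(qname = "rev", flag = 16L, pos = 5L, cigar = "10M")
  write_sam_fixture(reads, "18S", 40L, sam)
  aln <- read_sam(sam)
  # default: sense-stranded assumption
  expect_equal(count_read_ends(aln, ref, "5p")$counts[5], 1L)
  # strand-aware: 5' end of a reverse read is its rightmost base
  expect_equal(count_read_ends(aln, ref, "5p", strand_aware = TRUE)$counts[14], 1L)
  expect_equal(count_read_ends(aln, ref, "3p", strand_aware = TRUE)$counts[5], 1L)
})

test_that("compute_methscore matches the worked examples", {
  mk <- function(counts) structure(
    list(molecule = "m", end = "3p", counts = as.integer(counts),
         condition = "c", replicate = "r1"),
    class = "end_count_profile")

  flat <- mk(rep(10L, 31))
  tr <- compute_methscore(flat, w = 6, min_neighbor_mean = 5, shift = FALSE)
  expect_true(all(tr$score[7:25] == 0))
  expect_true(all(is.na(tr$score[c(1:6, 26:31)])))

  x <- rep(10L, 31); x[16] <- 0L
  expect_equal(compute_methscore(mk(x), shift = FALSE)$score[16], 1)

  x <- rep(12L, 31); x[16] <- 3L
  expect_equal(compute_methscore(mk(x), shift = FALSE)$score[16], 0.75)

  # clamp rule: c_q = 20 against neighbor mean 10 -> raw -1, reported 0
  x <- rep(10L, 31); x[16] <- 20L
  tr <- compute_methscore(mk(x), shift = FALSE)
  expect_equal(tr$score[16], 0)
  expect_equal(tr$raw[16], -1)

  # neighbor-mean guard
  x <- rep(2L, 31)
  expect_true(all(is.na(compute_methscore(mk(x), min_neighbor_mean = 10,
                                          shift = FALSE)$score)))

  expect_error(compute_methscore(mk(rep(10L, 12)), w = 6), "exceed")
})

test_that("compute_methscore equals the brute-force oracle exactly", {
  set.seed(42)
  for (i in 1:25) {
    L <- sample(30:120, 1)
    counts <- rpois(L, lambda = sample(c(3, 20, 150), 1))
    prof <- structure(list(molecule = "m", end = "3p",
                           counts = as.integer(counts), condition = "c",
                           replicate = "r"),
                      class = "end_count_profile")
    got <- compute_methscore(prof, w = 6, min_neighbor_mean = 10,
                             shift = FALSE)$score
    expect_identical(got, oracle_methscore(counts, 6L, 10))
  }
})

test_that("end-shift convention puts both tracks' peaks on the site", {
  w <- make_world(L = 200, n_full = 1, n_partial = 0, depth = 500,
                  noise_cv = 0, replicates = 1, seed = 21)
  j <- w$truth$sites$position
  p5 <- Filter(function(p) p$end == "5p", w$profiles)[[1]]
  p3 <- Filter(function(p) p$end == "3p", w$profiles)[[1]]
  un5 <- compute_methscore(p5, shift = FALSE)
  un3 <- compute_methscore(p3, shift = FALSE)
  expect_equal(which.max(un5$raw), j + 1L)
  expect_equal(which.max(un3$raw), j)
  sh5 <- compute_methscore(p5)
  sh3 <- compute_methscore(p3)
  expect_equal(which.max(sh5$raw), j)
  expect_equal(which.max(sh3$raw), j)
})

test_that("classification is invariant to uniform count scaling", {
  w <- make_world(seed = 22)
  ref <- w$ref
  for (fac in c(3L, 11L)) {
    for (p in w$profiles[1:4]) {
      t1 <- compute_methscore(p, min_neighbor_mean = 0)
      p2 <- p; p2$counts <- p$counts * fac
      t2 <- compute_methscore(p2, min_neighbor_mean = 0)
      c1 <- classify_sites(t1, ref, keep_none = TRUE)
      c2 <- classify_sites(t2, ref, keep_none = TRUE)
      expect_identical(c1$class, c2$class)
    }
  }
})

test_that("classify_sites applies the threshold and boundary rules", {
  ref <- rrna_reference("18S", strrep("AUGC", 10))
  track <- structure(list(molecule = "18S", end = "5p", condition = "c",
                          replicate = "mean", w = 6L, min_neighbor_mean = 10,
                          shifted = TRUE,
                          score = c(rep(NA, 6), 0.9, 0.75, 0.5, 1.0, 0.85,
                                    0.65, 0.851, rep(NA, 27)),
                          raw = rep(NA_real_, 40)),
                     class = "methscore_track")
  calls <- classify_sites(track, ref, keep_none = TRUE)
  got <- setNames(calls$class, calls$position)
  expect_equal(unname(got["7"]), "full")      # 0.85 < 0.9 < 1
  expect_equal(unname(got["8"]), "partial")   # 0.65 <= 0.75 <= 0.85
  expect_equal(unname(got["9"]), "none")      # 0.5
  expect_equal(unname(got["10"]), "flagged")  # exactly 1: manual review
  expect_equal(unname(got["11"]), "partial")  # boundary 0.85 inclusive
  expect_equal(unname(got["12"]), "partial")  # boundary 0.65 inclusive
  expect_equal(unname(got["13"]), "full")
  # labels carry base + position with U for T
  expect_equal(calls$label[calls$position == 7], "Gm7")
})

test_that("name_site builds Nm labels and checks range", {
  seqs <- paste(rep("ACGT", 8), collapse = "")
  ref <- rrna_reference("18S", seqs)
  expect_equal(name_site(1, ref), "Am1")
  expect_equal(name_site(4, ref), "Um4")  # T reported as U
  expect_equal(name_site(c(2, 3), ref), c("Cm2", "Gm3"))
  expect_error(name_site(0, ref), "range")
  expect_error(name_site(33, ref), "range")
})

test_that("intersect_end_calls takes the weaker class and mean score", {
  mk <- function(pos, cls, m) data.frame(
    molecule = "18S", position = pos, base = "A",
    label = paste0("Am", pos), methscore = m, class = cls,
    stringsAsFactors = FALSE)
  a <- mk(c(28, 755), c("full", "full"), c(0.90, 0.92))
  b <- mk(c(755, 900), c("full", "partial"), c(0.94, 0.70))
  cons <- intersect_end_calls(a, b)
  expect_equal(cons$position, 755)
  expect_equal(cons$class, "full")
  expect_equal(cons$methscore, (0.92 + 0.94) / 2)

  # weaker-class rule
  cons2 <- intersect_end_calls(mk(5, "full", 0.9), mk(5, "partial", 0.8))
  expect_equal(cons2$class, "partial")

  # disjoint call sets
  expect_equal(nrow(intersect_end_calls(mk(1, "full", 0.9),
                                        mk(2, "full", 0.9))), 0)

  # molecule mismatch
  bad <- mk(5, "full", 0.9); bad$molecule <- "28S"
  expect_error(intersect_end_calls(mk(5, "full", 0.9), bad), "molecule")
})

test_that("consensus calling recovers simulated sites end to end", {
  w <- make_world(L = 600, n_full = 5, n_partial = 3, depth = 200,
                  replicates = 6, seed = 23)
  res <- call_consensus_sites(w$profiles, w$ref)
  full_true <- w$truth$sites$position[w$truth$sites$class_label == "full"]
  called_full <- res$calls$position[res$calls$class == "full"]
  expect_true(all(full_true %in% called_full))
  expect_lte(sum(!(called_full %in% full_true)), 1)
})
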