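mutate_at <- function(read, positions) {
  for (p in positions) {
    cur <- substr(read, p, p)
    substr(read, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  read
}

test_that("constant-region matching accepts up to one mismatch, no more", {
  lay <- construct_layout()
  r0 <- build_read()
  p <- parse_construct(r0)
  expect_true(p$accepted)
  expect_equal(p$constant_mismatches, 0L)
  expect_equal(p$umi, "AA")
  expect_equal(p$index, "ATC")
  expect_equal(p$kmer, "ACGTACG")

  # one substitution inside read positions 6-29 is tolerated
  p1 <- parse_construct(mutate_at(r0, 12))
  expect_true(p1$accepted)
  expect_equal(p1$constant_mismatches, 1L)

  # two substitutions are rejected
  p2 <- parse_construct(mutate_at(r0, c(12, 25)))
  expect_false(p2$accepted)
  expect_equal(p2$reason, "constant_mismatch")

  # randomized brute-force oracle over mutation loads 0..3
  set.seed(8)
  for (rep in 1:50) {
    nmut <- sample(0:3, 1)
    pos <- sample(6:29, nmut)
    r <- mutate_at(r0, pos)
    # oracle: character-by-character Hamming distance
    d <- sum(strsplit(substr(r, 6, 29), "")[[1]] !=
               strsplit(lay$constant5, "")[[1]])
    p <- parse_construct(r)
    expect_equal(p$constant_mismatches, d)
    expect_equal(p$accepted, d <= 1)
  }
})

test_that("short reads are rejected with reason too_short", {
  p <- parse_construct(substr(build_read(), 1, 35))
  expect_false(p$accepted)
  expect_equal(p$reason, "too_short")
})

test_that("demultiplexing partitions accepted reads by index", {
  reads <- c(build_read(index = "ATC"), build_read(index = "GTA"),
             build_read(index = "AAA"), build_read(index = "CGA"))
  parsed <- demultiplex(parse_construct(reads), hitseq_indexes())
  expect_equal(as.character(parsed$library),
               c("lib1", "lib8", NA, "lib3"))
  expect_equal(attr(parsed, "unassigned"), 1L)
  # partition property: assigned + unassigned = accepted
  expect_equal(sum(!is.na(parsed$library)) + attr(parsed, "unassigned"),
               sum(parsed$accepted))
  expect_error(demultiplex(parsed, c(a = "ATC", b = "ATC")), "unique")
})

test_that("UMI collapse counts distinct (UMI, 7-mer) pairs", {
  # 5 reads, same UMI, same 7-mer -> 1 molecule
  r <- rep(build_read(umi = "AC", kmer = "GGGCCCA"), 5)
  ct <- dedup_and_count(demultiplex(parse_construct(r), hitseq_indexes()))
  expect_equal(ct$umi_counts["GGGCCCA", "lib1"], 1L)
  expect_equal(ct$counts["GGGCCCA", "lib1"], 5L)

  # 5 reads, 3 distinct UMIs -> 3 molecules
  r <- build_read(umi = c("AA", "AA", "CC", "GG", "GG"), kmer = "GGGCCCA")
  ct <- dedup_and_count(demultiplex(parse_construct(r), hitseq_indexes()))
  expect_equal(ct$umi_counts["GGGCCCA", "lib1"], 3L)
})

test_that("counting is order-independent and conserves read totals", {
  ls <- make_landscape(seed = 6)
  cfg <- simulation_config(depth = 5000, seed = 12)
  comp <- simulate_equilibrium(ls, cfg)
  rs <- sample_reads(comp[, 1:3], config = cfg, indexes = hitseq_indexes(3))
  reads <- unlist(rs$reads, use.names = FALSE)
  parsed <- demultiplex(parse_construct(reads), hitseq_indexes(3))
  ct <- dedup_and_count(parsed)
  expect_equal(sum(ct$totals) + sum(ct$rejected), length(reads))

  set.seed(1)
  shuf <- parsed[sample(nrow(parsed)), ]
  ct2 <- dedup_and_count(shuf)
  expect_identical(ct$counts, ct2$counts)
  expect_identical(ct$umi_counts, ct2$umi_counts)
})

test_that("normalization is control-relative with a pseudocount", {
  counts <- matrix(c(10L, 0L, 40L, 10L, 0L, 10L), nrow = 3,
                   dimnames = list(c("AAAAAAA", "CCCCCCC", "GGGGGGG"),
                                   c("lib1", "lib2")))
  ct <- structure(list(counts = counts, umi_counts = counts,
                       totals = colSums(counts), control_label = "lib1",
                       rejected = c(rejected = 0L)),
                  class = "count_table")
  nrm <- normalize_counts(ct, pseudocount = 0.5)
  expect_equal(unname(nrm[, "lib1"]), rep(1, 3))    # control vs itself
  # absent everywhere -> pseudocount/pseudocount, modulo library totals
  expect_equal(unname(nrm["CCCCCCC", "lib2"]),
               (0.5 / 21.5) / (0.5 / 51.5))
  # depleted variant < 1: oracle by direct ratio arithmetic
  expect_equal(unname(nrm["AAAAAAA", "lib2"]),
               (10.5 / 21.5) / (10.5 / 51.5))
  expect_lt(nrm["GGGGGGG", "lib2"], 1)
  expect_error(normalize_counts(ct, pseudocount = 0), "pseudocount")
})
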