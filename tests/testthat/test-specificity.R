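test_that("affinity histograms conserve the variant total", {
  ls <- make_landscape(seed = 41)
  tab <- true_affinity(ls)
  h <- affinity_histogram(tab, n_bins = 100)
  expect_equal(sum(h$counts), 16384L)
  expect_equal(length(h$counts), 100L)
  expect_equal(max(h$breaks), max(tab$ka_rel))
  # bimodal landscape: occupied bins near 0 and near 1, gap between
  occupied <- which(h$counts > 0)
  expect_true(any(h$mids[occupied] < 0.05) && any(h$mids[occupied] > 0.5))

  all_equal <- as_affinity_table(
    data.frame(variant = all_kmers(7), ka_rel = 0.7))
  h2 <- affinity_histogram(all_equal, n_bins = 50)
  expect_equal(sum(h2$counts > 0), 1L)
  expect_error(affinity_histogram(tab, n_bins = 1), "n_bins")
})

test_that("mixture comparison detects bimodality and its absence", {
  tab <- true_affinity(make_landscape(seed = 42))
  bm <- assess_bimodality(tab)
  expect_equal(bm$preferred, 2L)
  expect_gt(bm$delta_bic, 0)
  # the high-affinity component contains every cognate-motif variant
  cog <- tab$variant[grepl("GCAUG", tab$variant)]
  expect_true(all(cog %in% bm$high_affinity_members))

  null_tab <- true_affinity(
    make_landscape(seed = 43, cognate_motifs = character(0)),
    reference = "AAAAAAA")
  bm0 <- assess_bimodality(null_tab)
  expect_equal(bm0$preferred, 1L)

  const <- as_affinity_table(data.frame(variant = all_kmers(7),
                                        ka_rel = 0.5))
  bmc <- assess_bimodality(const)
  expect_equal(bmc$preferred, 1L)
  expect_match(bmc$note, "degenerate")
})

test_that("top-variant logos span the entropy extremes", {
  # 40 identical sequences: 2 bits everywhere
  tab <- as_affinity_table(data.frame(variant = all_kmers(7),
                                      ka_rel = 0.01))
  tab$ka_rel[tab$variant == "UGCAUGU"] <- 1
  top1 <- top_variants_logo(tab, n = 1)
  expect_equal(unname(top1$information), rep(2, 7))

  # cognate-dominated landscape: GCAUG positions carry the information
  ls <- make_landscape(seed = 44, cognate_motifs = "GCAUG")
  tr <- true_affinity(ls)
  logo <- top_variants_logo(tr, n = 40)
  expect_equal(dim(logo$frequencies), c(4L, 7L))
  expect_equal(unname(colSums(logo$frequencies)), rep(1, 7))
  expect_true(all(logo$information >= 0 & logo$information <= 2))
  # registers vary, but the most informative positions sit inside 1-7
  # with the central positions (always inside the motif) near-pure
  expect_gt(mean(logo$information[3:5]), mean(logo$information[c(1, 7)]))

  # near-uniform top set: information near zero
  set.seed(9)
  unif <- as_affinity_table(data.frame(variant = all_kmers(7),
                                       ka_rel = runif(16384)))
  l0 <- top_variants_logo(unif, n = 4000)
  expect_lt(max(l0$information), 0.05)
  expect_error(top_variants_logo(tr, n = 0), "positive")
})

test_that("percentile ranks use the midrank convention", {
  tab <- as_affinity_table(data.frame(variant = all_kmers(7),
                                      ka_rel = seq_len(16384) / 16384))
  expect_equal(percentile_rank(tab, tab$variant[16384]),
               100 * (16383 + 0.5) / 16384)
  expect_equal(percentile_rank(tab, tab$variant[1]),
               100 * 0.5 / 16384)
  expect_equal(percentile_rank(tab, tab$variant[8192]), 50,
               tolerance = 1e-3)
  # ties: all-equal table puts every variant at the 50th percentile
  const <- as_affinity_table(data.frame(variant = all_kmers(7),
                                        ka_rel = 1))
  expect_equal(percentile_rank(const, "UGCAUGU"), 50)
  expect_error(percentile_rank(tab, "NOPE"), "not in the table")
})

test_that("RBNS R-score normalization maps onto [0, 1] monotonically", {
  r <- c(1, 2, 3)
  nz <- normalize_rbns(r)
  expect_equal(nz[1], 0)
  expect_equal(nz[3], 1)
  expect_equal(nz[2], log((1 + exp(1)) / 2), tolerance = 1e-12)
  set.seed(10)
  x <- sort(rlnorm(100))
  nx <- normalize_rbns(x)
  expect_true(all(diff(nx) > 0))
  expect_true(all(nx >= 0 & nx <= 1))
  expect_error(normalize_rbns(rep(2, 5)), "dynamic range")
})

test_that("specificity ratio is max over median and scale invariant", {
  expect_equal(specificity_ratio(rep(0.3, 10)), 1)
  x <- c(rep(0.01, 999), 1)
  expect_equal(specificity_ratio(x), 100)
  expect_equal(specificity_ratio(x * 7), specificity_ratio(x))
  expect_warning(r <- specificity_ratio(c(0, 0, 1)), "infinite")
  expect_equal(r, Inf)
})
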