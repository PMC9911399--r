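test_that("variant encoding uses reference coding with the expected columns", {
  k5 <- all_kmers(5)
  X <- encode_variants(k5, "GCAUG")
  expect_equal(ncol(X), 15L)                      # 5 positions x 3 letters
  expect_equal(unname(X["GCAUG", ]), rep(0, 15))  # baseline -> zero row
  # indicator oracle on random columns
  expect_equal(unname(X[, "p3.G"]), as.numeric(substr(k5, 3, 3) == "G"))
  expect_equal(unname(X[, "p1.A"]), as.numeric(substr(k5, 1, 1) == "A"))
  Xp <- encode_variants(k5, "GCAUG", pairwise = TRUE)
  expect_equal(ncol(Xp), 15L + 90L)               # + C(5,2) x 3 x 3
  expect_equal(unname(Xp["GCAUG", ]), rep(0, 105))
  expect_equal(unname(Xp[, "p2A:p4G"]),
               as.numeric(substr(k5, 2, 2) == "A" & substr(k5, 4, 4) == "G"))
  expect_error(encode_variants(c("GCAUG", "GCAU"), "GCAUG"), "length")
  expect_error(encode_variants("GCATG", "GCAUG"), "T")
})

test_that("PWM fit recovers an additive ground truth exactly", {
  fx <- additive_5mer_table(seed = 31)
  fit <- fit_pwm(fx$table, baseline = "GCAUG", floor = 0)
  pos <- attr(fx$X, "positional")
  expect_equal(fit$coefficients[cbind(match(pos$nt, c("A","C","G","U")),
                                      pos$pos)],
               unname(fx$beta[pos$col]), tolerance = 1e-10)
  expect_equal(fit$intercept, fx$intercept, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$baseline_residual, 0, tolerance = 1e-10)
  # baseline coefficients are identically zero
  base_nt <- strsplit("GCAUG", "")[[1]]
  expect_equal(unname(fit$coefficients[cbind(match(base_nt, c("A","C","G","U")),
                                             1:5)]),
               rep(0, 5))
  # predictions reproduce the generating log-affinities
  expect_equal(unname(predict(fit, fx$table$kmer5)),
               log(fx$table$ka_rel), tolerance = 1e-10)
})

test_that("PWC fit recovers injected couplings exactly in noise-free data", {
  cpl <- data.frame(col = "p2A:p4G", value = -1.2)
  fx <- additive_5mer_table(seed = 32, couplings = cpl)
  fit <- fit_pwc(fx$table, baseline = "GCAUG", floor = 0)
  it <- fit$interactions
  inj <- it$pos1 == 2 & it$nt1 == "A" & it$pos2 == 4 & it$nt2 == "G"
  expect_equal(it$coefficient[inj], -1.2, tolerance = 1e-9)
  expect_equal(max(abs(it$coefficient[!inj])), 0, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("noisy PWC fits flag injected couplings as significant", {
  cpl <- data.frame(col = "p2A:p4G", value = -1.0)
  fx <- additive_5mer_table(seed = 33, couplings = cpl, noise_sd = 0.1)
  fit <- fit_pwc(fx$table, baseline = "GCAUG", floor = 0)
  it <- fit$interactions
  inj <- it$pos1 == 2 & it$nt1 == "A" & it$pos2 == 4 & it$nt2 == "G"
  expect_true(it$significant[inj])
  expect_gt(abs(it$t[inj]), 20)
  # significance mask is exactly |t| > threshold
  expect_identical(it$significant, abs(it$t) > fit$t_threshold)
})

test_that("PWC variance explained is never below PWM (nested OLS)", {
  fx <- additive_5mer_table(seed = 34, noise_sd = 0.5)
  expect_gte(fit_pwc(fx$table, floor = 0)$r2,
             fit_pwm(fx$table, floor = 0)$r2)
})

test_that("constant affinities give zero coefficients and r2 = 0", {
  tab <- data.frame(kmer5 = all_kmers(5), ka_rel = 0.3)
  fit <- fit_pwm(tab, floor = 0)
  expect_equal(max(abs(fit$coefficients)), 0, tolerance = 1e-12)
  expect_equal(fit$r2, 0)
})

test_that("coefficients are invariant to row order and flag aliased designs", {
  fx <- additive_5mer_table(seed = 35, noise_sd = 0.2)
  set.seed(1)
  shuf <- fx$table[sample(nrow(fx$table)), ]
  f1 <- fit_pwm(fx$table, floor = 0)
  f2 <- fit_pwm(shuf, floor = 0)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  # variants never using A at position 1 -> aliased p1.A column
  sub <- fx$table[substr(fx$table$kmer5, 1, 1) != "A", ]
  expect_error(fit_pwm(sub, floor = 0), "p1.A")
})

test_that("nonpositive affinities demand a detection floor", {
  tab <- data.frame(kmer5 = all_kmers(5), ka_rel = 0.5)
  tab$ka_rel[3] <- 0
  expect_error(fit_pwm(tab, floor = 0), "floor")
  expect_silent(fit_pwm(tab, floor = 1e-4))
})

test_that("model differences isolate a changed coupling", {
  cpl <- data.frame(col = "p2A:p4G", value = -1.0)
  fx0 <- additive_5mer_table(seed = 36)
  fx1 <- additive_5mer_table(seed = 36, couplings = cpl)
  m0 <- fit_pwc(fx0$table, floor = 0)
  m1 <- fit_pwc(fx1$table, floor = 0)
  d <- coefficient_difference(m1, m0)
  expect_equal(max(abs(d$positional)), 0, tolerance = 1e-9)
  it <- d$interactions
  inj <- it$pos1 == 2 & it$nt1 == "A" & it$pos2 == 4 & it$nt2 == "G"
  expect_equal(it$difference[inj], -1.0, tolerance = 1e-9)
  expect_equal(max(abs(it$difference[!inj])), 0, tolerance = 1e-9)
  # self-difference is identically zero
  dd <- coefficient_difference(m0, m0)
  expect_equal(max(abs(dd$positional)), 0)
  expect_equal(max(abs(dd$interactions$difference)), 0)
  # mismatched baselines are refused
  m7 <- fit_pwm(true_affinity(make_landscape(seed = 2)))
  expect_error(coefficient_difference(m7, m0), "baseline")
})

test_that("coupling matrices carry values symmetrically with NA reference cells", {
  fx <- additive_5mer_table(seed = 37, noise_sd = 0.2,
                            couplings = data.frame(col = "p2A:p4G",
                                                   value = -1))
  fit <- fit_pwc(fx$table, floor = 0)
  cm <- coupling_matrix(fit)
  expect_equal(dim(cm), c(20L, 20L))
  expect_equal(cm["2A", "4G"], cm["4G", "2A"])
  it <- fit$interactions
  expect_equal(cm["2A", "4G"],
               it$coefficient[it$pos1 == 2 & it$nt1 == "A" &
                                it$pos2 == 4 & it$nt2 == "G"])
  # baseline states and same-position pairs are NA
  expect_true(is.na(cm["1G", "2C"]))  # G1 is the baseline at position 1
  expect_true(is.na(cm["1A", "1C"]))
})
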