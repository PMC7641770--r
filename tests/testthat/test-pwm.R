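test_that("build_pfm counts residues per column", {
  pfm <- build_pfm(c("RAY", "RAY", "RCY"))
  expect_equal(pfm$width, 3)
  expect_equal(pfm$n_sites, 3)
  expect_equal(unname(pfm$counts["R", 1]), 3L)
  expect_equal(unname(pfm$counts["A", 2]), 2L)
  expect_equal(unname(pfm$counts["C", 2]), 1L)
  expect_equal(unname(pfm$counts["Y", 3]), 3L)
  expect_true(all(colSums(pfm$counts) == pfm$n_sites))

  one <- build_pfm("GSD")
  expect_true(all(colSums(one$counts) == 1))

  expect_error(build_pfm(character(0)), "at least one site")
  expect_error(build_pfm(c("AA", "AAA")), "unequal lengths")
  expect_error(build_pfm("AXB"), "non-canonical")
})

test_that("site frequencies are recovered from sampled sites", {
  set.seed(7)
  true_f <- c(A = 0.6, C = 0.3, D = 0.1)
  n <- 400
  sites <- replicate(n, paste(
    sample(names(true_f), 2, replace = TRUE, prob = true_f), collapse = ""))
  pfm <- build_pfm(sites)
  f_hat <- pfm$counts[names(true_f), ] / n
  # within 4 binomial standard errors
  se <- sqrt(true_f * (1 - true_f) / n)
  expect_true(all(abs(f_hat - true_f) <= 4 * se))
})

test_that("information content matches closed forms", {
  invariant <- build_pfm(c("Y", "Y", "Y"))
  expect_equal(unname(information_content(invariant)), log2(20),
               tolerance = 1e-12)

  uniform_sites <- AA_ALPHABET
  expect_equal(unname(information_content(build_pfm(uniform_sites))), 0,
               tolerance = 1e-12)

  half <- build_pfm(c("A", "C"))
  expect_equal(unname(information_content(half)), log2(20) - 1,
               tolerance = 1e-12)
})

test_that("information content is never negative under a uniform background", {
  set.seed(3)
  for (i in 1:20) {
    sites <- replicate(15, random_protein(4))
    ic <- information_content(build_pfm(sites), pseudocount = 0.5)
    expect_true(all(ic >= -1e-12))
  }
})

test_that("pwm_from_pfm matches the log-odds formula", {
  pfm <- build_pfm(c("AC", "AC", "AD"))
  b <- uniform_background()
  pc <- 0.4
  pwm <- pwm_from_pfm(pfm, b, pc)
  # hand computation for column 1, residue A: counts 3 of 3
  f_A <- (3 + pc / 20) / (3 + pc)
  expect_equal(unname(pwm$log_odds["A", 1]), log2(f_A / (1 / 20)))
  f_C <- (0 + pc / 20) / (3 + pc)
  expect_equal(unname(pwm$log_odds["C", 1]), log2(f_C / (1 / 20)))

  # uniform column: every score 0
  u <- pwm_from_pfm(build_pfm(AA_ALPHABET), pseudocount = 1)
  expect_true(all(abs(u$log_odds) < 1e-12))

  # pseudocount -> 0 limit: consensus approaches log2(20)
  inv <- build_pfm(c("Y", "Y"))
  lo <- pwm_from_pfm(inv, pseudocount = 1e-9)$log_odds
  expect_equal(unname(lo["Y", 1]), log2(20), tolerance = 1e-6)
  expect_lt(unname(lo["A", 1]), -20)

  expect_error(pwm_from_pfm(pfm, b, 0), "pseudocount")
})

test_that("exact p-values match exhaustive enumeration on small widths", {
  set.seed(19)
  for (k in 2:3) {
    sites <- replicate(12, random_protein(k, c("R", "K", "A", "Y")))
    pwm <- pwm_from_pfm(build_pfm(sites), pseudocount = 0.25)
    d <- pwm_score_distribution(pwm)
    oracle <- enumerate_pwm_pvalue(pwm)
    probe <- unique(c(d$score_int, d$score_int + 1L, min(d$score_int) - 5L))
    expect_true(all(abs(d$pvalue(probe) - oracle(probe)) <= 1e-9))
  }
})

test_that("p-values are monotone and reach 1 at the minimum score", {
  set.seed(23)
  sites <- replicate(10, random_protein(5))
  pwm <- pwm_from_pfm(build_pfm(sites), pseudocount = 0.5)
  d <- pwm_score_distribution(pwm)
  pv <- d$pvalue(d$score_int)
  expect_true(all(diff(pv) <= 1e-15))
  expect_equal(d$pvalue(min(d$score_int)), 1)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
})

test_that("pwm_scan reports the closed-form p-value for a unique maximum", {
  # width-2 PWM, one maximal residue per column, uniform background:
  # p-value of the top score is (1/20)^2
  sites <- c("RY", "RY", "RY")
  pwm <- pwm_from_pfm(build_pfm(sites), pseudocount = 1e-6)
  hits <- pwm_scan("ARYA", pwm, p_threshold = 1)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$p_value, (1 / 20)^2, tolerance = 1e-12)
  expect_equal(best$matched_seq, "RY")
})

test_that("pwm_scan edge contracts hold", {
  pwm <- pwm_from_pfm(build_pfm(c("RY", "RY")), pseudocount = 0.5)
  expect_equal(nrow(pwm_scan("R", pwm)), 0)
  expect_error(pwm_scan("RYRY", pwm, p_threshold = 0), "p_threshold")
  expect_error(pwm_scan("RYRY", pwm, p_threshold = 1.5), "p_threshold")
})

test_that("planted sites outscore random sequences through the PFM->PWM path", {
  set.seed(31)
  sites <- replicate(25, paste0("R", random_protein(2), "H"))
  pwm <- pwm_from_pfm(build_pfm(sites), pseudocount = 0.5)
  score_of <- function(s) {
    max(pwm_scan(s, pwm, p_threshold = 1)$score)
  }
  site_scores <- vapply(sites, score_of, numeric(1))
  rand_scores <- vapply(replicate(25, random_protein(4)), score_of, numeric(1))
  expect_gt(mean(site_scores), mean(rand_scores))
})
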