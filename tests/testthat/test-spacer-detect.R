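REP <- "GTTTTTGTACTCTCAAGATTTAAGTAACTGTACAAC"

test_that("repeat finder locates exact and mismatched copies", {
  spec <- repeat_spec(REP, max_mismatch = 2)
  s1 <- random_dna_str(30)
  seq <- paste0(REP, s1, REP)
  hits <- find_repeats(seq, spec)
  expect_equal(hits$start, c(0, nchar(REP) + 30))
  expect_equal(hits$end, hits$start + nchar(REP))
  # one copy carrying a substitution is still found
  mut <- seq
  substr(mut, 5, 5) <- ifelse(substr(mut, 5, 5) == "A", "C", "A")
  hits2 <- find_repeats(mut, spec)
  expect_equal(nrow(hits2), 2)
  expect_equal(hits2$mismatches, c(1, 0))
  expect_equal(hits2$start, oracle_greedy(
    oracle_hamming_scan(mut, REP, 2))$start)
  expect_equal(nrow(find_repeats("", spec)), 0)
})

test_that("overlapping candidate windows resolve greedily left to right", {
  spec <- repeat_spec("AAAAAAAA", max_mismatch = 2)
  hits <- find_repeats(strrep("A", 12), spec)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 0)
  hits2 <- find_repeats(strrep("A", 16), spec)
  expect_equal(hits2$start, c(0, 8))
})

test_that("repeat scan matches the exhaustive Hamming oracle", {
  set.seed(55)
  for (i in 1:50) {
    L <- sample(40:300, 1)
    seq <- random_dna_str(L)
    pat <- if (runif(1) < 0.5) {
      random_dna_str(10)
    } else {  # a planted copy so matches are guaranteed
      s0 <- sample(L - 10, 1)
      substr(seq, s0, s0 + 9)
    }
    k <- sample(0:2, 1)
    expect_equal(hamming_scan(seq, pat, k),
                 oracle_hamming_scan(seq, pat, k),
                 ignore_attr = TRUE)
  }
})

test_that("array parsing returns ordered spacers and flags atypical ones", {
  spec <- repeat_spec(REP)
  s1 <- random_dna_str(30); s2 <- random_dna_str(30)
  arr <- parse_array(paste0(REP, s1, REP, s2, REP), spec)
  expect_equal(arr$spacers, c(s1, s2))
  expect_false(any(arr$atypical))
  one <- parse_array(paste0(REP, s1, REP), spec)
  expect_equal(one$spacers, s1)
  short <- parse_array(paste0(REP, "ACGTACGT", REP), spec)
  expect_true(short$atypical[1])
  expect_error(parse_array(paste0(REP, s1), spec), "unparseable")
})

test_that("parsing is conservative: repeats + spacers rebuild the segment", {
  set.seed(77)
  spec <- repeat_spec(REP, max_mismatch = 3)
  for (i in 1:20) {
    spacers <- replicate(sample(1:4, 1), random_dna_str(sample(18:45, 1)))
    seq <- paste0(random_dna_str(10), REP,
                  paste(vapply(spacers, function(s) paste0(s, REP),
                               character(1)), collapse = ""),
                  random_dna_str(10))
    arr <- parse_array(seq, spec)
    expect_equal(arr$spacers, unname(spacers))
    reps <- arr$repeat_positions
    segment <- substr(seq, reps$start[1] + 1, reps$end[nrow(reps)])
    expect_identical(serialize_array(arr), segment)
    # round trip: re-parsing the serialised array recovers the spacers
    expect_equal(parse_array(serialize_array(arr), spec)$spacers,
                 arr$spacers)
  }
})

test_that("acquisition calls separate novel spacers from ancestral ones", {
  anc <- c("ACGTACGTACGTACGTACGTACGTACGTAC",
           "TTGCATTGCATTGCATTGCATTGCATTGCA")
  spec <- repeat_spec(REP)
  mk <- function(spacers) {
    parse_array(paste0(REP, paste(vapply(spacers, function(s)
      paste0(s, REP), character(1)), collapse = "")), spec)
  }
  same <- call_acquisition(mk(anc), anc)
  expect_false(same$expanded)
  expect_length(same$new_spacers, 0)
  snew <- "GGGGGCCCCCGGGGGCCCCCGGGGGCCCCC"
  exp <- call_acquisition(mk(c(snew, anc)), anc)
  expect_true(exp$expanded)
  expect_true(exp$expanded_by_count && exp$expanded_by_novelty)
  expect_equal(exp$new_spacers, snew)
  # <= novelty_max_mismatch errors on an ancestral spacer is not novel
  worn <- anc                                  # anc[1] = "ACGTACGT..."
  substr(worn[1], 1, 1) <- "T"
  substr(worn[1], 5, 5) <- "T"                 # 2 substitutions
  call2 <- call_acquisition(mk(worn), anc, novelty_max_mismatch = 2)
  expect_false(call2$expanded_by_novelty)
  substr(worn[1], 9, 9) <- "T"                 # 3rd substitution -> novel
  call3 <- call_acquisition(mk(worn), anc, novelty_max_mismatch = 2)
  expect_true(call3$expanded_by_novelty)
})

test_that("zero-error cohorts are parsed back to the simulated truth", {
  cfg <- sim_config(seed = 41, n_reads = 300, p_acq = 0.33, error_rate = 0)
  co <- simulate_cohort(cfg)
  merged <- merge_pairs(co$pairs)
  expect_equal(nrow(merged$merged), 300)
  spec <- repeat_spec(cfg$repeat_seq)
  for (i in seq_len(300)) {
    arr <- parse_array(merged$merged$sequence[i], spec)
    expect_equal(arr$spacers, co$arrays[[i]])
  }
})

test_that("per-read calls agree with simulated truth under realistic error", {
  cfg <- sim_config(seed = 47, n_reads = 2000, p_acq = 0.33,
                    error_rate = 0.001)
  co <- simulate_cohort(cfg)
  merged <- merge_pairs(co$pairs)
  det <- detect_acquisition(merged$merged, repeat_spec(cfg$repeat_seq),
                            co$refs$ancestral$spacers)
  truth <- co$truth$acquired[match(det$calls$read_id, co$truth$read_id)]
  agreement <- mean(det$calls$expanded == truth)
  expect_gte(agreement, 0.99)
})

test_that("acquisition estimates recover the generative rate across a grid", {
  refs <- build_references(sim_config(seed = 61))
  spec <- repeat_spec(sim_config()$repeat_seq)
  for (p in c(0, 0.005, 0.33, 1.0)) {
    cfg <- sim_config(seed = 61, n_reads = 10000, p_acq = p, error_rate = 0)
    sim <- simulate_arrays(cfg, refs)
    merged <- data.frame(read_id = sim$truth$read_id,
                         sequence = sim$amplicons,
                         stringsAsFactors = FALSE)
    det <- detect_acquisition(merged, spec, refs$ancestral$spacers)
    se <- sqrt(p * (1 - p) / 10000)
    expect_lte(abs(det$fraction$estimate - p), max(3 * se, 1e-12))
  }
})

test_that("acquisition fraction uses the Wilson score interval", {
  est <- acquisition_fraction(c(rep(TRUE, 33), rep(FALSE, 67)))
  expect_equal(est$estimate, 0.33)
  oracle <- prop.test(33, 100, correct = FALSE)$conf.int
  expect_equal(est$lower, oracle[1], tolerance = 1e-10)
  expect_equal(est$upper, oracle[2], tolerance = 1e-10)
  expect_gt(est$lower, 0.24)
  expect_lt(est$upper, 0.43)
  zero <- acquisition_fraction(rep(FALSE, 50))
  expect_equal(zero$estimate, 0)
  expect_equal(zero$lower, 0)
})
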