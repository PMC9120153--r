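make_refs <- function(seed = 17) build_references(sim_config(seed = seed))

test_that("planted substrings map exactly with correct strand and interval", {
  refs <- make_refs()
  plasmid <- refs$sequences[["plasmid"]]
  spacer <- substr(plasmid, 101, 130)
  hits <- map_spacer(spacer, refs)
  expect_equal(attr(hits, "category"), "plasmid")
  top <- hits[1, ]
  expect_equal(c(top$start, top$end), c(100, 130))
  expect_equal(top$strand, "+")
  expect_equal(top$mismatches, 0)
  # reverse-complemented query hits the same interval on the minus strand
  rc_hits <- map_spacer(revcomp(spacer), refs)
  rc_top <- rc_hits[1, ]
  expect_equal(c(rc_top$start, rc_top$end), c(100, 130))
  expect_equal(rc_top$strand, "-")
})

test_that("spacers absent from the references are unmapped", {
  refs <- make_refs()
  set.seed(23)
  repeat {
    q <- random_dna_str(30)
    absent <- !any(vapply(refs$sequences, function(s) {
      grepl(q, s, fixed = TRUE) || grepl(revcomp(q), s, fixed = TRUE)
    }, logical(1)))
    if (absent) break
  }
  hits <- map_spacer(q, refs)
  expect_equal(nrow(hits), 0)
  expect_equal(attr(hits, "category"), "unmapped")
})

test_that("circular plasmid windows may wrap the origin", {
  refs <- make_refs()
  plasmid <- refs$sequences[["plasmid"]]
  L <- nchar(plasmid)
  wrap <- paste0(substr(plasmid, L - 14, L), substr(plasmid, 1, 15))
  hits <- map_spacer(wrap, refs)
  expect_gte(nrow(hits), 1)
  expect_equal(hits$start[1], L - 15)
  expect_equal(hits$end[1], L + 15)
  # the same window on the linear genome reference finds nothing
  genome <- refs$sequences[["genome"]]
  gwrap <- paste0(substr(genome, nchar(genome) - 14, nchar(genome)),
                  substr(genome, 1, 15))
  expect_equal(attr(map_spacer(gwrap, refs), "category"), "unmapped")
})

test_that("small-instance mapping equals a brute-force scan on both strands", {
  set.seed(29)
  toy <- structure(list(
    sequences = c(plasmid = random_dna_str(200)),
    circular = c(plasmid = FALSE)), class = "reference_set")
  for (i in 1:20) {
    q <- if (runif(1) < 0.5) random_dna_str(15) else {
      s0 <- sample(185, 1)
      w <- substr(toy$sequences[["plasmid"]], s0, s0 + 14)
      if (runif(1) < 0.5) w else revcomp(w)
    }
    hits <- map_spacer(q, toy, max_mismatch = 1)
    fwd <- oracle_hamming_scan(toy$sequences[["plasmid"]], q, 1)
    rev <- oracle_hamming_scan(toy$sequences[["plasmid"]], revcomp(q), 1)
    expect_equal(nrow(hits), nrow(fwd) + nrow(rev))
    expect_setequal(hits$start[hits$strand == "+"], fwd$start)
    expect_setequal(hits$start[hits$strand == "-"], rev$start)
  }
})

test_that("category abundances recover planted target proportions", {
  cfg <- sim_config(seed = 31, n_reads = 1000, p_acq = 1, error_rate = 0,
                    target_weights = c(plasmid = 0.7, acr = 0.2,
                                       genome = 0.1))
  refs <- build_references(cfg)
  sim <- simulate_arrays(cfg, refs)
  counts <- table(vapply(sim$arrays, `[`, character(1), 1))
  cls <- classify_spacers(setNames(as.integer(counts), names(counts)), refs)
  ab <- categorize_cohort(cls)
  expect_equal(sum(ab), 1)
  for (cat in c("plasmid", "acr", "genome")) {
    p <- cfg$target_weights[[cat]]
    se <- sqrt(p * (1 - p) / 1000)
    expect_lt(abs(ab[[cat]] - p), 3 * se)
  }
  # all-plasmid cohort and the empty cohort are degenerate but clean
  only <- cls[cls$category == "plasmid", ]
  expect_equal(categorize_cohort(only)[["plasmid"]], 1)
  empty <- categorize_cohort(cls[0, ])
  expect_equal(sum(empty), 0)
})

test_that("positional map bins starts and reports a uniformity statistic", {
  refs <- make_refs()
  L <- nchar(refs$sequences[["plasmid"]])
  set.seed(37)
  ok <- 0
  for (rep in 1:10) {
    starts <- sample(0:(L - 1), 1000, replace = TRUE)
    cls <- data.frame(ref_id = "plasmid", start = starts,
                      strand = sample(c("+", "-"), 1000, TRUE), count = 1L)
    pm <- position_map(cls, "plasmid", L, bin_size = 300)
    expect_equal(sum(pm$bins$plus + pm$bins$minus), 1000)
    if (pm$p_value > 0.001) ok <- ok + 1
  }
  expect_gte(ok, 9)
  # all mass in one bin is maximally non-uniform for that configuration
  one <- data.frame(ref_id = "plasmid", start = rep(10L, 50),
                    strand = "+", count = 1L)
  pm1 <- position_map(one, "plasmid", L, bin_size = 300)
  widths <- pm1$bins$bin_end - pm1$bins$bin_start
  exp_counts <- 50 * widths / sum(widths)
  max_chisq <- sum((c(50, rep(0, length(widths) - 1)) - exp_counts)^2 /
                   exp_counts)
  expect_equal(pm1$chisq, max_chisq, tolerance = 1e-8)
  # zero hits -> empty map, no statistic
  pm0 <- position_map(one[0, ], "plasmid", L, bin_size = 300)
  expect_true(is.na(pm0$chisq))
})

test_that("PAM extraction is 3' of the protospacer and strand-consistent", {
  refs <- make_refs()
  plasmid <- refs$sequences[["plasmid"]]
  pam_sites <- iupac_scan(plasmid, "NNAGAAW")
  s <- pam_sites$start[pam_sites$start > 40][1]
  spacer <- substr(plasmid, s - 29, s)          # 30-mer ending at the PAM
  hit <- map_spacer(spacer, refs)[1, ]
  pam <- extract_pam(hit, refs)
  expect_identical(pam, substr(plasmid, s + 1, s + 7))
  expect_match(pam, sprintf("^%s$", iupac_regex("NNAGAAW")))
  # a protospacer sampled on the minus strand carries its PAM 3' on that
  # strand, i.e. left of the interval in forward coordinates
  minus_sites <- iupac_scan(plasmid, "NNAGAAW", both_strands = TRUE)
  ms <- minus_sites[minus_sites$strand == "-" &
                    minus_sites$end + 30 <= nchar(plasmid), ][1, ]
  minus_spacer <- revcomp(substr(plasmid, ms$end + 1, ms$end + 30))
  mhit <- map_spacer(minus_spacer, refs)[1, ]
  expect_equal(mhit$strand, "-")
  expect_equal(c(mhit$start, mhit$end), c(ms$end, ms$end + 30))
  mpam <- extract_pam(mhit, refs)
  expect_identical(mpam, revcomp(substr(plasmid, ms$start + 1, ms$end)))
  expect_match(mpam, sprintf("^%s$", iupac_regex("NNAGAAW")))
  # reconstruction: reference[start, end+7) = spacer + pam for + hits
  expect_identical(substr(plasmid, hit$start + 1, hit$end + 7),
                   paste0(spacer, pam))
})

test_that("PAM flank wraps on the circular plasmid, not on linear refs", {
  refs <- make_refs()
  L <- nchar(refs$sequences[["plasmid"]])
  hit <- data.frame(ref_id = "plasmid", start = L - 30, end = L,
                    strand = "+", mismatches = 0L)
  pam <- extract_pam(hit, refs)
  expect_equal(nchar(pam), 7)
  expect_identical(pam, substr(refs$sequences[["plasmid"]], 1, 7))
  gl <- nchar(refs$sequences[["genome"]])
  ghit <- data.frame(ref_id = "genome", start = gl - 30, end = gl,
                     strand = "+", mismatches = 0L)
  expect_true(is.na(extract_pam(ghit, refs)))
})

test_that("strand invariance: flipping a reference flips hits, not calls", {
  refs <- make_refs()
  genome <- refs$sequences[["genome"]]
  gl <- nchar(genome)
  spacer <- substr(genome, 501, 530)
  hit <- map_spacer(spacer, refs)[1, ]
  pam <- extract_pam(hit, refs)
  flipped <- refs
  flipped$sequences[["genome"]] <- revcomp(genome)
  fhit_all <- map_spacer(spacer, flipped)
  fhit <- fhit_all[1, ]
  expect_equal(attr(fhit_all, "category"), "genome")
  expect_equal(fhit$strand, "-")
  expect_equal(fhit$start, gl - hit$end)
  expect_identical(extract_pam(fhit, flipped), pam)
})

test_that("extracted PAMs from an error-free cohort all match NNAGAAW", {
  cfg <- sim_config(seed = 43, n_reads = 300, p_acq = 1, error_rate = 0)
  co <- simulate_cohort(cfg)
  merged <- merge_pairs(co$pairs)
  det <- detect_acquisition(merged$merged, repeat_spec(cfg$repeat_seq),
                            co$refs$ancestral$spacers)
  cls <- classify_spacers(det$spacer_counts, co$refs)
  pams <- cls$pam[!is.na(cls$pam)]
  expect_gt(length(pams), 0)
  expect_true(all(grepl(sprintf("^%s$", iupac_regex("NNAGAAW")), pams)))
})

test_that("PAM model computes information content and IUPAC consensus", {
  flat <- build_pam_model(rep("TTAGAAT", 25))
  expect_equal(unname(flat$information), rep(2, 7))
  expect_equal(flat$consensus, "TTAGAAT")
  expect_true(all(colSums(flat$counts) == flat$n_sites))
  half <- build_pam_model(c(rep("ATAGAAA", 10), rep("TTAGAAT", 10)))
  expect_equal(unname(half$information[1]), 1)
  expect_equal(substr(half$consensus, 1, 1), "W")
  expect_equal(substr(half$consensus, 7, 7), "W")
  # 500 draws from the NNAGAAW expansion give back the degenerate motif
  set.seed(53)
  draws <- vapply(1:500, function(i) {
    paste0(random_dna_str(2), "AGAA", sample(c("A", "T"), 1))
  }, character(1))
  expect_equal(build_pam_model(draws)$consensus, "NNAGAAW")
})
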