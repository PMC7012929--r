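test_that("block decomposition covers 1..L with a short trailing block", {
  d656 <- decompose_blocks(656)
  expect_equal(nrow(d656), 66L)
  expect_equal(d656$width[66], 6L)
  expect_equal(d656$start[1], 1L)
  expect_equal(d656$end[66], 656L)
  expect_true(all(d656$width[-66] == 10L))
  expect_true(all(d656$start[-1] == d656$end[-66] + 1L)) # no gaps, no overlap

  expect_equal(nrow(decompose_blocks(10)), 1L)
  d7 <- decompose_blocks(7)
  expect_equal(nrow(d7), 1L)
  expect_equal(d7$width, 7L)
  expect_error(decompose_blocks(0), "length")
  expect_error(decompose_blocks(10, 0), "block_size")
})

test_that("candidate enumeration yields B(B+1)/2 runs in lexicographic order", {
  for (B in c(1L, 2L, 5L, 17L, 66L, 100L)) {
    cand <- enumerate_candidates(decompose_blocks(B * 10L))
    expect_equal(nrow(cand), B * (B + 1L) / 2L)
    expect_true(all(cand$first_block <= cand$last_block))
    ord <- order(cand$first_block, cand$last_block)
    expect_equal(ord, seq_len(nrow(cand)))
  }
  c3 <- enumerate_candidates(decompose_blocks(30))
  expect_equal(c3$start, c(1L, 1L, 1L, 11L, 11L, 21L))
  expect_equal(c3$end, c(10L, 20L, 30L, 20L, 30L, 30L))
})

test_that("candidate scores follow the normalized inside / inside-outside sums", {
  # single inside pair
  m1 <- bpp(data.frame(i = 3, j = 8, p = 0.5), 20)
  s1 <- score_candidates(m1)
  r1 <- s1[s1$start == 1 & s1$end == 10, ]
  expect_equal(r1$p_inside, 0.5 / 100)
  expect_equal(r1$p_io, 0)
  # single cross pair
  m2 <- bpp(data.frame(i = 5, j = 15, p = 0.3), 20)
  s2 <- score_candidates(m2)
  r2 <- s2[s2$start == 1 & s2$end == 10, ]
  expect_equal(r2$p_inside, 0)
  expect_equal(r2$p_io, 0.3 / (10 * 10))
  # the symmetric-double-count convention doubles only the cross sum
  s2d <- score_candidates(m2, double_count_cross = TRUE)
  r2d <- s2d[s2d$start == 1 & s2d$end == 10, ]
  expect_equal(r2d$p_io, 2 * r2$p_io)
  expect_equal(r2d$p_inside, r2$p_inside)
})

test_that("the prefix-sum scanner equals a naive double-loop oracle", {
  set.seed(51)
  for (r in 1:30) {
    L <- sample(20:60, 1)
    m <- random_bpp(L, n_entries = sample(5:40, 1))
    P <- bpp_matrix(m)
    scored <- score_candidates(m)
    pick <- sample(nrow(scored), min(8, nrow(scored)))
    for (k in pick) {
      oracle <- naive_domain_scores(P, scored$start[k], scored$end[k])
      expect_lt(abs(scored$p_inside[k] - oracle["p_inside"]), 1e-12)
      expect_lt(abs(scored$p_io[k] - oracle["p_io"]), 1e-12)
    }
  }
})

test_that("the whole-sequence candidate has an empty cross set and p_io = 0", {
  set.seed(52)
  m <- random_bpp(40, n_entries = 30)
  scored <- score_candidates(m)
  whole <- scored[scored$start == 1 & scored$end == 40, ]
  expect_equal(whole$p_io, 0)
})

test_that("p_inside is invariant to rearranging probability within the domain", {
  # two matrices, same total inside mass, different arrangement
  ma <- bpp(data.frame(i = c(21, 22), j = c(50, 49), p = c(0.4, 0.2)), 60)
  mb <- bpp(data.frame(i = c(25, 30), j = c(44, 40), p = c(0.3, 0.3)), 60)
  sa <- score_candidates(ma)
  sb <- score_candidates(mb)
  ka <- sa[sa$start == 21 & sa$end == 50, ]
  kb <- sb[sb$start == 21 & sb$end == 50, ]
  expect_equal(ka$p_inside, kb$p_inside)
  expect_equal(ka$p_io, 0)
  expect_equal(kb$p_io, 0)
})

test_that("a planted hairpin passes while flank-only candidates fail", {
  m <- bpp(data.frame(i = 21:30, j = 50:41, p = 0.9), 60)
  scan <- scan_domains(m, mode = "all_passing")
  row2150 <- scan[scan$start == 21 & scan$end == 50, ]
  expect_equal(row2150$p_inside, 9 / 900)
  expect_equal(row2150$p_io, 0)
  expect_true(row2150$pass)
  # no candidate confined to the flanks passes
  flanks <- scan[scan$end <= 20 | scan$start >= 51, ]
  expect_false(any(flanks$pass))
  # candidates truncating the stem lose it to the cross term
  cut <- scan[scan$start == 21 & scan$end == 40, ]
  expect_false(cut$pass)
  # containing candidates up to the dilution bound also pass Eq-arithmetic:
  # 9/2500 = 0.0036 for the 50-nt containers
  big <- scan[scan$start == 1 & scan$end == 50, ]
  expect_equal(big$p_inside, 9 / 2500)
  expect_true(big$pass)
})

test_that("zero matrices yield no domains under any policy", {
  z <- bpp(data.frame(i = integer(), j = integer(), p = numeric()), 50)
  for (mode in c("all_passing", "maximal_passing", "best_nonoverlapping")) {
    expect_equal(nrow(extract_domains(z, mode = mode)), 0L)
  }
  scan <- scan_domains(z)
  expect_equal(nrow(scan), 15L) # B = 5 blocks
  expect_false(any(scan$pass))
})

test_that("extraction policies resolve overlapping passing candidates as documented", {
  m <- bpp(data.frame(i = 21:30, j = 50:41, p = 0.9), 60)
  all_p <- extract_domains(m, mode = "all_passing")
  maxi <- extract_domains(m, mode = "maximal_passing")
  best <- extract_domains(m, mode = "best_nonoverlapping")
  # every maximal candidate is passing and not strictly contained in another
  expect_true(all(paste(maxi$start, maxi$end) %in% paste(all_p$start, all_p$end)))
  for (k in seq_len(nrow(maxi))) {
    containers <- all_p$start <= maxi$start[k] & all_p$end >= maxi$end[k] &
      (all_p$start < maxi$start[k] | all_p$end > maxi$end[k])
    expect_false(any(containers))
  }
  # with zero background noise the containers up to the dilution bound pass,
  # so the maximal set is the two widest containers
  expect_equal(maxi$start, c(1L, 11L))
  expect_equal(maxi$end, c(50L, 60L))
  # greedy best takes the highest p_inside (the planted 21-50) and stops
  expect_equal(nrow(best), 1L)
  expect_equal(c(best$start, best$end), c(21L, 50L))
  expect_equal(best$p_inside, max(all_p$p_inside))
})

test_that("tightening either threshold never adds a domain", {
  set.seed(53)
  for (r in 1:10) {
    fx <- generate_fixture(random_domain_spec(r + 400))
    base <- extract_domains(fx$bpp, mode = "all_passing")
    tighter_in <- extract_domains(fx$bpp, threshold_inside = 0.006, mode = "all_passing")
    tighter_io <- extract_domains(fx$bpp, threshold_io = 0.0001, mode = "all_passing")
    expect_true(all(paste(tighter_in$start, tighter_in$end) %in%
                      paste(base$start, base$end)))
    expect_true(all(paste(tighter_io$start, tighter_io$end) %in%
                      paste(base$start, base$end)))
    expect_lte(nrow(tighter_in), nrow(base))
    expect_lte(nrow(tighter_io), nrow(base))
  }
})

test_that("scan reports carry tidy domains and glance summaries", {
  m <- bpp(data.frame(i = 21:30, j = 50:41, p = 0.9), 60)
  scan <- scan_domains(m)
  expect_s3_class(scan, "domain_scan")
  expect_equal(nrow(scan), 21L) # B = 6
  expect_identical(tidy(scan), attr(scan, "domains"))
  g <- glance(scan)
  expect_equal(g$n_candidates, 21L)
  expect_equal(g$n_passing, sum(scan$pass))
  expect_equal(g$threshold_inside, 0.003)
  expect_equal(g$threshold_io, 0.0003)
  # sequence input folds first
  scan_seq <- scan_domains("GGGGAAAACCCC", block_size = 4)
  expect_s3_class(scan_seq, "domain_scan")
  expect_equal(attr(scan_seq, "length"), 12L)
})

test_that("BED export shifts to 0-based half-open and scales scores", {
  doms <- tibble::tibble(start = 21L, end = 50L, p_inside = 0.01, p_io = 0)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(doms, path, chrom = "eleanor2")
  fields <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(fields[1:3], c("eleanor2", "20", "50"))
  expect_equal(as.numeric(fields[5]), 10) # 0.01 * 1000
})
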