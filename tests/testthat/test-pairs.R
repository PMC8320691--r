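toy_table <- function() {
  tibble::tibble(
    feature_id = c("a", "b", "c"),
    mz = c(100.00, 102.02, 104.04),
    s1 = c(100, 50, 10), s2 = c(200, 100, 20), s3 = c(300, 150, 30),
    s4 = c(120, 60, 12)
  )
}

test_that("pair finding matches rounded PMDs and validates inputs", {
  t <- toy_table()[1:2, ]
  p <- find_pairs(t, 2.02)
  expect_equal(nrow(p), 1L)
  expect_equal(p$from, "a")
  expect_equal(p$pmd, 2.02)
  expect_error(find_pairs(t), "non-empty")
  expect_error(find_pairs(t, numeric(0)), "non-empty")
  expect_error(find_pairs(t, 2.02, digits = -1), "digits")
})

test_that("pair finding equals a brute-force all-pairs filter", {
  withr::with_seed(41, {
    n <- 200
    t <- tibble::tibble(feature_id = sprintf("f%03d", 1:n),
                        mz = runif(n, 100, 500),
                        s1 = runif(n, 1, 10))
    set <- c(2.02, 14.02, 18.01)
    got <- find_pairs(t, set, digits = 2)
    want <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (round(abs(t$mz[i] - t$mz[j]), 2) %in% set) want <- want + 1L
    }
    expect_equal(nrow(got), want)
    # order independence
    got2 <- find_pairs(t[sample(n), ], set, digits = 2)
    expect_identical(got, got2)
  })
})

test_that("co-eluting pairs are excluded by the retention-time gap", {
  t <- tibble::tibble(feature_id = c("a", "b"), mz = c(100, 102.02),
                      rt = c(120, 121), s1 = c(1, 1))
  expect_equal(nrow(find_pairs(t, 2.02, rt_min_gap = 5)), 0L)
  expect_equal(nrow(find_pairs(t, 2.02, rt_min_gap = 0.5)), 1L)
})

test_that("pair statistics recover proportionality and anti-correlation", {
  t <- toy_table()[1:2, ]
  p <- pair_statistics(t, find_pairs(t, c(2.02), digits = 2))
  expect_equal(p$ratio_rsd, 0)
  expect_equal(p$pearson_r, 1)
  # anti-correlated pair
  t2 <- tibble::tibble(feature_id = c("a", "b"), mz = c(100, 102.02),
                       s1 = c(10, 100), s2 = c(20, 80), s3 = c(30, 60),
                       s4 = c(40, 40))
  p2 <- pair_statistics(t2, find_pairs(t2, 2.02))
  expect_lt(p2$pearson_r, 0)
})

test_that("pair statistics match textbook Pearson and RSD formulas", {
  withr::with_seed(42, {
    x <- exp(rnorm(10, 5, 0.4)); y <- exp(rnorm(10, 4, 0.4))
    t <- dplyr::bind_cols(
      tibble::tibble(feature_id = c("a", "b"), mz = c(100, 102.02)),
      tibble::as_tibble(setNames(as.data.frame(rbind(x, y)),
                                 paste0("s", 1:10))))
    p <- pair_statistics(t, find_pairs(t, 2.02))
    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    ratio <- x / y
    rsd_hand <- 100 * sqrt(sum((ratio - mean(ratio))^2) / 9) / mean(ratio)
    expect_equal(p$pearson_r, r_hand, tolerance = 1e-12)
    expect_equal(p$ratio_rsd, rsd_hand, tolerance = 1e-12)
    expect_equal(p$n_used, 10L)
  })
})

test_that("pairs with fewer than 3 usable samples keep NA statistics", {
  t <- tibble::tibble(feature_id = c("a", "b"), mz = c(100, 102.02),
                      s1 = c(10, 5), s2 = c(20, 0), s3 = c(0, 7))
  p <- pair_statistics(t, find_pairs(t, 2.02))
  expect_equal(nrow(p), 1L)
  expect_true(is.na(p$pearson_r))
  expect_false(classify_static(p)$static)
})

test_that("static classification respects both thresholds at the boundary", {
  p <- tibble::tibble(from = c("a", "b", "c"), to = c("x", "y", "z"),
                      pmd = 2.02, pearson_r = c(1, 0.9, 0.7),
                      ratio_rsd = c(0, 31, 29))
  cl <- classify_static(p)
  expect_equal(cl$static, c(TRUE, FALSE, TRUE))
  # 30% exactly is not < 30
  p$ratio_rsd <- 30
  expect_false(any(classify_static(p)$static))
})

test_that("static classification is monotone in its thresholds", {
  withr::with_seed(43, {
    p <- tibble::tibble(from = letters[1:20], to = LETTERS[1:20], pmd = 1,
                        pearson_r = runif(20, -1, 1),
                        ratio_rsd = runif(20, 0, 80))
    base <- classify_static(p, 30, 0.6)$static
    looser <- classify_static(p, 45, 0.3)$static
    expect_true(all(base <= looser))
  })
})

test_that("planted static pairs are recovered from the generator", {
  sim <- gen_peak_table(seed = 44)
  want <- sim$manifest$pairs
  p <- find_pairs(sim$peaks, unique(round(want$pmd, 2)), digits = 2) |>
    pair_statistics(t = sim$peaks) |>
    classify_static()
  got_static <- p[p$static, c("from", "to")]
  want_static <- want[want$type == "static", c("from", "to")]
  expect_setequal(paste(got_static$from, got_static$to),
                  paste(want_static$from, want_static$to))
})

test_that("quantification sums the union of contributing features once", {
  t <- tibble::tibble(feature_id = c("a", "b", "c"),
                      mz = c(100, 102.02, 104.04),
                      s1 = c(1, 2, 4), s2 = c(2, 4, 8), s3 = c(3, 6, 12))
  p <- classify_static(pair_statistics(t, find_pairs(t, 2.02)))
  expect_true(all(p$static))  # a-b and b-c, both proportional
  q <- quantify_pmd(t, p, 2.02)
  expect_equal(q$intensity, c(1 + 2 + 4, 2 + 4 + 8, 3 + 6 + 12))
  expect_warning(q0 <- quantify_pmd(t, p, 9.99), "no static pair")
  expect_equal(nrow(q0), 0L)
})

test_that("quantification is equivariant under sample permutation", {
  sim <- gen_peak_table(n_features = 30, n_samples = 12, seed = 45)
  p <- classify_static(pair_statistics(sim$peaks,
                                       find_pairs(sim$peaks, 2.02)))
  q1 <- quantify_pmd(sim$peaks, p, 2.02)
  perm <- sample(seq_len(12))
  peaks2 <- sim$peaks[, c(1, 2, 2 + perm)]
  p2 <- classify_static(pair_statistics(peaks2, find_pairs(peaks2, 2.02)))
  q2 <- quantify_pmd(peaks2, p2, 2.02)
  expect_equal(q2$intensity[match(q1$sample_id, q2$sample_id)], q1$intensity)
})

test_that("differential analysis is null on symmetric groups", {
  t <- tibble::tibble(feature_id = c("a", "b"), mz = c(100, 102.02),
                      s1 = c(10, 5), s2 = c(20, 10), s3 = c(10, 5),
                      s4 = c(20, 10))
  groups <- tibble::tibble(sample_id = paste0("s", 1:4),
                           group = c("g1", "g1", "g2", "g2"))
  p <- classify_static(pair_statistics(t, find_pairs(t, 2.02)))
  d <- differential_pmd(t, p, groups)
  expect_equal(d$p_value, 1)
  expect_true(is.na(d$direction))
})

test_that("the Welch statistic matches a by-hand computation", {
  x <- c(12, 15, 11, 14, 13); y <- c(20, 25, 19, 22, 27)
  t <- tibble::tibble(feature_id = c("a", "b"), mz = c(100, 102.02))
  im <- rbind(0.6 * c(x, y), 0.4 * c(x, y))
  colnames(im) <- paste0("s", 1:10)
  t <- dplyr::bind_cols(t, tibble::as_tibble(im))
  groups <- tibble::tibble(sample_id = paste0("s", 1:10),
                           group = rep(c("g1", "g2"), each = 5))
  p <- classify_static(pair_statistics(t, find_pairs(t, 2.02)))
  d <- differential_pmd(t, p, groups)
  hand <- welch_by_hand(x, y)  # sums are 0.6x+0.4x = x
  expect_equal(d$statistic, hand$t, tolerance = 1e-12)
  expect_equal(d$df, hand$df, tolerance = 1e-12)
  expect_equal(d$p_value, hand$p, tolerance = 1e-12)
  expect_equal(d$direction, "g2")
})

test_that("differential analysis rejects malformed group tables", {
  t <- toy_table()
  p <- classify_static(pair_statistics(t, find_pairs(t, 2.02)))
  g1 <- tibble::tibble(sample_id = paste0("s", 1:4), group = "only")
  expect_error(differential_pmd(t, p, g1), "two groups")
  g2 <- tibble::tibble(sample_id = paste0("s", 1:4),
                       group = c("a", "a", "a", "b"))
  expect_error(differential_pmd(t, p, g2), "at least 2")
})

test_that("the frequency spectrum is the brute-force pairwise histogram", {
  t <- tibble::tibble(feature_id = c("a", "b", "c"),
                      mz = c(100, 102.02, 104.04), s1 = c(1, 1, 1))
  sp <- pmd_frequency_spectrum(t, digits = 2)
  expect_equal(sp$frequency[sp$pmd == 2.02], 2L)
  expect_equal(sp$frequency[sp$pmd == 4.04], 1L)
  expect_equal(sum(sp$frequency), 3L)
  withr::with_seed(46, {
    n <- 60
    t <- tibble::tibble(feature_id = paste0("f", 1:n), mz = runif(n, 50, 500),
                        s1 = 1)
    sp <- pmd_frequency_spectrum(t, digits = 2, max_pmd = 100)
    want <- integer(0)
    cnt <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- round(abs(t$mz[i] - t$mz[j]), 2)
      if (d <= 100) cnt <- cnt + 1L
    }
    expect_equal(sum(sp$frequency), cnt)
  })
})

test_that("halogen screening flags isotopologue doublets in the ratio window", {
  t <- tibble::tibble(feature_id = c("m", "p", "lone"),
                      mz = c(200.0000, 201.9980, 350.1),
                      s1 = c(100, 97, 5), s2 = c(200, 194, 5),
                      s3 = c(150, 145.5, 5))
  sc <- halogen_screen(t)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$feature_id, "m")
  expect_true(sc$flagged)
  expect_equal(sc$median_ratio, 0.97)
  expect_false("lone" %in% sc$feature_id)
})

test_that("planted Br doublets are recovered among noise features", {
  sim <- gen_peak_table(n_features = 200, n_br = 20, seed = 47)
  sc <- halogen_screen(sim$peaks)
  br <- sim$manifest$pairs[sim$manifest$pairs$role == "br", ]
  expect_true(all(br$from %in% sc$feature_id[sc$flagged]))
  fp <- setdiff(sc$feature_id[sc$flagged], br$from)
  expect_lt(length(fp), 10)  # false positives reported, few expected
})

test_that("mass defect screening retains features inside the window", {
  t <- tibble::tibble(feature_id = c("a", "b"), mz = c(100.05, 100.95),
                      s1 = c(1, 1))
  expect_equal(mass_defect(c(100.05, 100.95)), c(0.05, -0.05))
  expect_equal(mass_defect_screen(t, c(0, 0.1))$feature_id, "a")
})
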