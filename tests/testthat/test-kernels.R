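# Kernel construction: BLOSUM62 windows, Jaccard PPI, Gaussian network
# profiles, and their combination.

test_that("window similarity sums positionwise BLOSUM62 scores", {
  w <- "AAAAAAASAAAAAAA"
  expect_equal(blosum_window_similarity(w, w), 60)
  ww <- strrep("W", 15); aa <- strrep("A", 15)
  expect_equal(blosum_window_similarity(ww, aa), 15 * oracle_seq_raw("W", "A"))
  expect_equal(blosum_window_similarity(ww, aa),
               blosum_window_similarity(aa, ww))
  # pad positions contribute nothing
  padded <- "XXXXXXXSAAAAAAA"
  expect_equal(blosum_window_similarity(padded, w),
               oracle_seq_raw(padded, w))
  expect_equal(blosum_window_similarity(strrep("X", 15), w), 0)
  expect_error(blosum_window_similarity("SHORT", w),
               class = "kinsub_dimension_error")
  expect_error(blosum_window_similarity(strrep("1", 15), w),
               class = "kinsub_lookup_error")
})

test_that("sequence kernel min-max normalizes to [0, 1] and clips", {
  # note c's self-score equals a's (14*4+4), so the identical pair sits at
  # the global max while the dissimilar a-c pairs sit at the min
  w <- c(a = "AAAAAAASAAAAAAA", b = "AAAAAAASAAAAAAA", c = "VVVVVVVSVVVVVVV")
  k <- sequence_kernel(w)
  expect_true(any(k == 1) && any(k == 0))
  expect_equal(k["a", "b"], 1)  # identical windows attain the max raw score
  rng <- attr(k, "meta")$range
  # a raw score above the stored max clips to 1
  k2 <- sequence_kernel(w, range = c(rng[1], rng[2] - 10))
  expect_true(all(k2 <= 1 & k2 >= 0))
  expect_equal(max(k2), 1)
  expect_error(sequence_kernel(c(x = "AAAAAAASAAAAAAA",
                                 y = "AAAAAAASAAAAAAA")),
               class = "kinsub_degenerate_error")
})

test_that("Jaccard similarity follows the set definition", {
  expect_equal(jaccard_similarity(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_similarity(c("a"), c("b")), 0)
  expect_equal(jaccard_similarity(character(0), character(0)), 0)
})

test_that("PPI kernel matches enumerated neighbour-set arithmetic", {
  b <- micro_example()
  k <- ppi_kernel(b$sites, b$ppi)
  # neighbour sets: SUBA {SUBB,P1}, SUBB {SUBA,P1}, SUBC {P1,P2}, SUBD {P3}
  expect_equal(k["SUBA_8", "SUBA_23"], 1)    # same substrate, non-empty set
  expect_equal(k["SUBA_8", "SUBB_8"], 1 / 3)
  expect_equal(k["SUBA_8", "SUBC_8"], 1 / 3)
  expect_equal(k["SUBA_8", "SUBD_8"], 0)     # disjoint sets
  expect_equal(unclass(k), t(unclass(k)), ignore_attr = TRUE)
  # substrate absent from the network has an empty neighbour set
  sites2 <- tibble::tibble(site_id = c("Q_1", "SUBA_8"),
                           substrate = c("QQQ", "SUBA"))
  k2 <- ppi_kernel(sites2, b$ppi)
  expect_equal(k2["Q_1", "SUBA_8"], 0)
  expect_equal(k2["Q_1", "Q_1"], 0)  # empty-vs-empty convention
})

test_that("network-profile bandwidth follows the mean squared row norm", {
  y <- matrix(c(1, 1, 0, 1), 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_equal(pskn_bandwidth(y), 2 / 3)           # mean norm^2 = 1.5
  id <- diag(2); dimnames(id) <- dimnames(y)
  expect_equal(pskn_bandwidth(id), 1)
  expect_equal(pskn_bandwidth(id, gamma_prime = 2), 2)
  expect_error(pskn_bandwidth(y * 0), class = "kinsub_degenerate_error")
})

test_that("network-profile kernel is Gaussian in profile distance", {
  y <- diag(2)
  dimnames(y) <- list(c("s1", "s2"), c("a", "b"))
  k <- pskn_kernel(y, mask_policy = "none")       # gamma = 1 here
  expect_equal(diag(unclass(k)), c(s1 = 1, s2 = 1))
  expect_equal(k["s1", "s2"], exp(-2))
  expect_true(all(k > 0 & k <= 1))
  # masking the target column equals restricting Y to the other columns
  y3 <- matrix(c(1, 0, 1, 0, 1, 1, 1, 1, 0), 3,
               dimnames = list(paste0("s", 1:3), c("k1", "k2", "k3")))
  km <- pskn_kernel(y3, mask_policy = "mask_target_column",
                    target_kinase = "k2")
  kr <- pskn_kernel(y3[, c("k1", "k3")], mask_policy = "none")
  expect_equal(unclass(km), unclass(kr), ignore_attr = TRUE)
  # scaling gamma_prime up never increases off-diagonal similarity
  k2 <- pskn_kernel(y3, gamma_prime = 4, mask_policy = "none")
  k1 <- pskn_kernel(y3, gamma_prime = 1, mask_policy = "none")
  expect_true(all(unclass(k2) <= unclass(k1) + 1e-12))
})

test_that("strict_zero_test_rows additionally zeroes held-out profiles", {
  y <- matrix(c(1, 1, 0, 1, 0, 1), 3,
              dimnames = list(paste0("s", 1:3), c("k1", "k2")))
  k <- pskn_kernel(y, mask_policy = "strict_zero_test_rows",
                   target_kinase = "k1", test_sites = "s3")
  yz <- y[, "k2", drop = FALSE]; yz["s3", ] <- 0
  g <- pskn_bandwidth(yz)
  expect_equal(k["s3", "s1"], exp(-g * sum((yz["s3", ] - yz["s1", ])^2)))
})

new_kernel_for_test <- function(m) {
  structure(m, source = "ppi", class = c("ksr_kernel", class(m)))
}

test_that("kernel combination is a normalized nonnegative average", {
  b <- micro_example()
  w <- setNames(b$sites$window, b$sites$site_id)
  ks <- sequence_kernel(w)
  kp <- ppi_kernel(b$sites, b$ppi)
  kn <- pskn_kernel(b$adjacency, mask_policy = "none")
  kc <- combine_kernels(list(ks, kp, kn))
  expect_equal(unclass(kc), (unclass(ks) + unclass(kp) + unclass(kn)) / 3,
               ignore_attr = TRUE)
  expect_equal(unclass(combine_kernels(list(ks, kp, kn), c(1, 0, 0))),
               unclass(ks), ignore_attr = TRUE)
  expect_equal(unclass(combine_kernels(list(kn, kn), c(0.5, 0.5))),
               unclass(kn), ignore_attr = TRUE)
  # linearity: weights (a, b) scaled by c give the same normalized result
  expect_equal(unclass(combine_kernels(list(ks, kn), c(0.2, 0.8))),
               unclass(combine_kernels(list(ks, kn), c(1, 4))),
               ignore_attr = TRUE)
  expect_error(combine_kernels(list(ks, kp), c(0, 0)),
               class = "kinsub_argument_error")
  kp_bad <- unclass(kp)[c(2:6, 1), c(2:6, 1)]
  expect_error(combine_kernels(list(ks, new_kernel_for_test(kp_bad))),
               class = "kinsub_alignment_error")
})

test_that("every micro-fixture kernel entry matches direct formula evaluation", {
  b <- micro_example()
  w <- setNames(b$sites$window, b$sites$site_id)
  ids <- b$sites$site_id
  raw <- outer(seq_along(ids), seq_along(ids),
               Vectorize(function(i, j) oracle_seq_raw(w[i], w[j])))
  ks <- sequence_kernel(w)
  expect_equal(unclass(ks),
               (raw - min(raw)) / (max(raw) - min(raw)),
               ignore_attr = TRUE, tolerance = 1e-12)
  kp <- ppi_kernel(b$sites, b$ppi)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      a <- b$ppi$neighbors[[b$sites$substrate[i]]]
      bb <- b$ppi$neighbors[[b$sites$substrate[j]]]
      expect_equal(kp[i, j], oracle_jaccard(a, bb), tolerance = 1e-12)
    }
  }
  kn <- pskn_kernel(b$adjacency, mask_policy = "none")
  g <- 1 / mean(rowSums(b$adjacency^2))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      expect_equal(kn[i, j],
                   oracle_gaussian(b$adjacency[i, ], b$adjacency[j, ], g),
                   tolerance = 1e-12)
    }
  }
})

test_that("all kernels are symmetric with values in range", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      wins <- random_windows(6, seed = rep)
      names(wins) <- paste0("s", 1:6)
      ks <- sequence_kernel(wins)
      expect_lt(max(abs(unclass(ks) - t(unclass(ks)))), 1e-10)
      expect_true(all(ks >= 0 & ks <= 1))
      y <- matrix(rbinom(18, 1, 0.4), 6,
                  dimnames = list(paste0("s", 1:6), paste0("k", 1:3)))
      if (all(rowSums(y) == 0)) next
      kn <- pskn_kernel(y, mask_policy = "none")
      expect_lt(max(abs(unclass(kn) - t(unclass(kn)))), 1e-10)
      expect_true(all(kn > 0 & kn <= 1))
      expect_equal(unname(diag(unclass(kn))), rep(1, 6))
    }
  })
})

test_that("kernel matrices round-trip through tab-separated text", {
  b <- micro_example()
  k <- ppi_kernel(b$sites, b$ppi)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kernel(k, path)
  k2 <- read_kernel(path, source = "ppi")
  expect_equal(unclass(k2), unclass(k), ignore_attr = TRUE)
  expect_identical(rownames(k2), rownames(k))
})
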