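test_that("K2P spot values: identity, single transition in 530 bp, closed forms", {
  s <- strrep("ACGT", 150)
  expect_equal(k2p(s, s)$d, 0)

  a <- paste0("A", strrep("C", 529))
  b <- paste0("G", strrep("C", 529))       # one A<->G transition
  r <- k2p(a, b)
  expect_equal(r$P, 1 / 530)
  expect_equal(r$Q, 0)
  expect_equal(round(r$d, 4), 0.0019)
  expect_equal(r$d, -0.5 * log(1 - 2 / 530))

  # P = 0.1, Q = 0.05 on 1000 sites: closed-form evaluation
  L <- 1000
  a <- strrep("A", L)
  b <- paste0(strrep("G", 100), strrep("C", 50), strrep("A", L - 150))
  r2 <- k2p(a, b)
  expect_equal(r2$P, 0.1)
  expect_equal(r2$Q, 0.05)
  expect_equal(r2$d, -0.5 * log(0.75) - 0.25 * log(0.90))
  expect_equal(r2$d, 0.1701812, tolerance = 1e-6)
})

test_that("K2P reduces to Jukes-Cantor when Q = 2P (algebraic identity)", {
  # Q = 2P = 0.02 worked example
  L <- 1000
  a <- strrep("A", L)
  b <- paste0(strrep("G", 10), strrep("C", 10), strrep("T", 10),
              strrep("A", L - 30))
  r <- k2p(a, b)
  expect_equal(r$P, 0.01)
  expect_equal(r$Q, 0.02)
  p <- r$P + r$Q
  expect_equal(r$d, -0.75 * log(1 - 4 * p / 3))
  expect_equal(r$d, 0.0306165, tolerance = 1e-6)

  # property over a grid of P
  for (P in c(0.005, 0.02, 0.05, 0.1)) {
    nts <- round(P * L); ntv <- 2 * nts
    b <- paste0(strrep("G", nts), strrep("C", ntv), strrep("A", L - nts - ntv))
    r <- k2p(a, b)
    expect_equal(r$d, -0.75 * log(1 - 4 * (r$P + r$Q) / 3))
  }
})

test_that("K2P is symmetric and increases with P at fixed Q", {
  withr::local_seed(31)
  for (i in 1:10) {
    s1 <- random_dna(200); s2 <- random_dna(200)
    r12 <- k2p(s1, s2); r21 <- k2p(s2, s1)
    expect_identical(r12, r21)
  }
  L <- 1000
  a <- strrep("A", L)
  ds <- vapply(seq(10, 300, by = 10), function(nts) {
    b <- paste0(strrep("G", nts), strrep("C", 50), strrep("A", L - nts - 50))
    k2p(a, b)$d
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("K2P matches a brute-force site-counting oracle and ape's K80", {
  withr::local_seed(32)
  for (i in 1:60) {
    s1 <- random_dna(50)
    s2 <- mutate_dna(s1, sample(0:15, 1))
    mine <- k2p(s1, s2)
    oracle <- k2p_bruteforce(s1, s2)
    if (is.na(oracle)) {
      expect_true(mine$saturated)
    } else {
      expect_equal(mine$d, oracle, tolerance = 1e-12)
      bin <- ape::as.DNAbin(strsplit(tolower(c(a = s1, b = s2)), ""))
      expect_equal(mine$d, as.numeric(ape::dist.dna(bin, model = "K80")),
                   tolerance = 1e-12)
    }
  }
})

test_that("pairwise deletion drops ambiguity and gap sites", {
  a <- "ACGTNACGT-"
  b <- "ACGTAAC-TT"
  r <- k2p(a, b)
  expect_equal(r$n_sites, 7L)  # positions with N or - on either side excluded
  expect_equal(r$d, 0)
  expect_error(k2p("NNNN", "ACGT"), "no comparable sites")
  expect_error(k2p("ACGT", "ACGTA"), "equal length")
})

test_that("saturation is flagged, not thrown, and excluded from summaries", {
  L <- 100
  a <- strrep("A", L)
  b <- paste0(strrep("G", 60), strrep("A", 40))  # P = 0.6 -> 1-2P-Q < 0
  r <- k2p(a, b)
  expect_true(r$saturated)
  expect_true(is.na(r$d))

  seqs <- c(x = a, y = b, z = paste0(strrep("G", 30), strrep("A", L - 30)))
  expect_warning(dm <- k2p_matrix(seqs), "saturated")
  expect_true(dm$saturated["x", "y"])
  expect_false(dm$saturated["x", "z"] || dm$saturated["y", "z"])
  summ <- group_summaries(dm, c(x = "g1", y = "g1", z = "g1"))
  expect_equal(summ$n_pairs, 2L)  # saturated pair left out of the mean
})

test_that("distance matrices are symmetric with zero diagonal", {
  withr::local_seed(33)
  base <- random_dna(300)
  seqs <- setNames(c(base, mutate_dna(base, 3), mutate_dna(base, 40),
                     mutate_dna(base, 80)), c("a", "b", "c", "d"))
  dm <- k2p_matrix(seqs)
  expect_equal(dm$d, t(dm$d))
  expect_equal(unname(diag(dm$d)), rep(0, 4))
  expect_true(all(dm$d[upper.tri(dm$d)] >= 0))
})

test_that("group summaries use unweighted haplotype-pair means", {
  # single haplotype group: 0 by convention; two haplotypes: the pair value
  L <- 530
  a <- strrep("A", L)
  b <- paste0("G", strrep("A", L - 1))
  c2 <- paste0("GT", strrep("A", L - 2))
  dm <- k2p_matrix(c(h1 = a, h2 = b, h3 = c2))
  gm <- c(h1 = "sp1", h2 = "sp1", h3 = "sp2")
  summ <- group_summaries(dm, gm)
  w1 <- summ[summ$group_a == "sp1" & summ$group_b == "sp1", ]
  expect_equal(w1$n_pairs, 1L)
  expect_equal(w1$mean, k2p(a, b)$d)
  expect_equal(w1$min, w1$max)
  w2 <- summ[summ$group_a == "sp2" & summ$group_b == "sp2", ]
  expect_equal(c(w2$mean, w2$min, w2$max, w2$n_pairs), c(0, 0, 0, 0))
  btw <- summ[summ$group_a != summ$group_b, ]
  expect_equal(btw$mean, mean(c(k2p(a, c2)$d, k2p(b, c2)$d)))
  expect_equal(btw$n_pairs, 2L)

  # excluded haplotypes contribute to nothing
  summ2 <- group_summaries(dm, gm, exclude = "h2")
  expect_equal(summ2[summ2$group_a == "sp1" & summ2$group_b == "sp1", "n_pairs"], 0L)
})

test_that("planted divergences separate within from between summaries", {
  sim <- simulate_survey(sim_config(n_species = 4, samples_per_species = 6,
                                    haplotypes_per_species = 3,
                                    within_divergence = 0.002,
                                    between_divergence = 0.2, seed = 5))
  al <- trim_to_region(sim$records, mode = "auto")
  tab <- name_haplotypes(collapse_haplotypes(al))
  dm <- k2p_matrix(tab)
  summ <- group_summaries(dm, setNames(tab$group, tab$haplotype))
  within <- summ[summ$group_a == summ$group_b, ]
  between <- summ[summ$group_a != summ$group_b, ]
  expect_true(all(within$mean < 0.01))
  expect_true(all(between$mean > 0.01))
})

test_that("barcode gap report captures overlap and fold ratio", {
  within <- data.frame(group_a = c("a", "b"), group_b = c("a", "b"),
                       mean = c(0.002, 0.0086), min = c(0, 0.0086),
                       max = c(0.004, 0.0086), n_pairs = c(3L, 1L))
  between <- data.frame(group_a = "a", group_b = "b",
                        mean = 0.15, min = 0.0095, max = 0.2886,
                        n_pairs = 9L)
  gap <- barcode_gap(within, between)
  expect_false(gap$overlap)           # 0.0095 > 0.0086
  expect_equal(gap$within_range, c(0, 0.0086))
  expect_equal(gap$between_range, c(0.0095, 0.2886))
  expect_gt(gap$fold_ratio, 10)

  # identical single ranges overlap
  same <- data.frame(group_a = "a", group_b = "a", mean = 0.1,
                     min = 0.05, max = 0.2, n_pairs = 1L)
  same_b <- transform(same, group_b = "b")
  expect_true(barcode_gap(same, same_b)$overlap)

  # degenerate zero within-mean: infinite fold ratio
  z <- data.frame(group_a = "a", group_b = "a", mean = 0, min = 0, max = 0,
                  n_pairs = 0L)
  expect_equal(barcode_gap(z, same_b)$fold_ratio, Inf)
})

test_that("K2P estimator recovers true simulated distances (3 SE at 200 reps)", {
  withr::local_seed(34)
  L <- 530L
  for (t in c(0.01, 0.05, 0.1)) {
    dhat <- replicate(200, {
      anc <- sample.int(4L, L, replace = TRUE)
      der <- barcodegap:::mutate_codes(anc, t, kappa = 2)
      bases <- c("A", "G", "C", "T")
      k2p(paste(bases[anc], collapse = ""),
          paste(bases[der], collapse = ""))$d
    })
    se <- stats::sd(dhat) / sqrt(length(dhat))
    expect_lt(abs(mean(dhat) - t), 3 * se + 1e-12)
  }
})
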