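make_ref <- function(...) {
  entries <- list(...)
  data.frame(id = sprintf("ref%02d", seq_along(entries)),
             species = vapply(entries, `[[`, character(1), 1),
             source = "test", location = NA_character_,
             sequence = vapply(entries, `[[`, character(1), 2),
             stringsAsFactors = FALSE)
}

test_that("identification: exact match, ambiguity ties, and the 1-mismatch case", {
  withr::local_seed(51)
  sx <- random_dna(530)
  sy <- mutate_dna(sx, 25)
  ref <- make_ref(list("Gambusia holbrooki", sx), list("Coptodon zillii", sy))
  r <- identify_species(sx, ref)
  expect_equal(r$called_species, "Gambusia holbrooki")
  expect_equal(r$hits$identity[1], 100)
  expect_false(r$ambiguous)

  # identical sequence listed under two species -> AMBIGUOUS at 100% each
  ref2 <- make_ref(list("Acanthobrama lissneri", sx),
                   list("Acanthobrama telavivensis", sx))
  r2 <- identify_species(sx, ref2)
  expect_equal(r2$called_species, "AMBIGUOUS")
  expect_true(r2$ambiguous)
  expect_equal(r2$hits$identity, c(100, 100))

  # one mismatch over 530 compared sites: 99.81% at two decimals
  s1 <- mutate_dna(sx, 1)
  r3 <- identify_species(s1, ref)
  expect_equal(round(r3$hits$identity[1], 2), 99.81)
  expect_equal(r3$hits$identity[1], 100 * 529 / 530)
})

test_that("identification screens by minimum identity and overlap", {
  withr::local_seed(52)
  sx <- random_dna(530)
  far <- mutate_dna(sx, 60)                # ~88.7% identity
  ref <- make_ref(list("A far", far))
  r <- identify_species(sx, ref, min_identity = 97)
  expect_true(is.na(r$called_species))
  expect_equal(nrow(r$hits), 0L)
  r2 <- identify_species(sx, ref, min_identity = 80)
  expect_equal(r2$called_species, "A far")

  expect_error(identify_species(sx, ref[0, , drop = FALSE]), "empty")
  expect_error(identify_species(substr(sx, 1, 150), ref), "usable region")
})

test_that("a query matching its own reference entry ranks first at 100%", {
  withr::local_seed(53)
  base <- random_dna(400)
  refs <- lapply(1:6, function(i) list(sprintf("sp%02d", i),
                                       mutate_dna(base, 8 * i)))
  ref <- do.call(make_ref, refs)
  for (i in seq_len(nrow(ref))) {
    r <- identify_species(ref$sequence[i], ref)
    expect_equal(r$called_species, ref$species[i])
    expect_equal(r$hits$identity[1], 100)
  }
})

test_that("discrepancy and hybrid flags follow the morphological comparison rules", {
  withr::local_seed(54)
  sA <- random_dna(530); sB <- mutate_dna(sA, 30)
  rec <- data.frame(
    id = c("f1", "f2", "f3"),
    species = c("Gambusia affinis", "Oreochromis aureus", "Coptodon zillii"),
    location = "lake",
    hybrid_suspect = c(FALSE, TRUE, FALSE),
    sequence = c(sB, sB, sA), stringsAsFactors = FALSE)
  ref <- make_ref(list("Gambusia holbrooki", sB), list("Coptodon zillii", sA))
  tab <- name_haplotypes(collapse_haplotypes(rec))
  asg <- identify_all(tab, ref)
  fl <- flag_discrepancies(asg, tab, rec)
  fl <- fl[order(fl$id), ]
  # morphological G. affinis called G. holbrooki -> discrepancy, not hybrid
  expect_true(fl$discrepancy[fl$id == "f1"])
  expect_false(fl$hybrid_evidence[fl$id == "f1"])
  # hybrid-suspect sample whose call differs -> hybrid evidence
  expect_true(fl$hybrid_evidence[fl$id == "f2"])
  # call equals label -> no flags
  expect_false(fl$discrepancy[fl$id == "f3"])
  expect_false(fl$hybrid_evidence[fl$id == "f3"])
})

test_that("planted reassignments are all flagged and clean samples never are", {
  sim <- simulate_survey(sim_config(n_species = 8, samples_per_species = 6,
                                    haplotypes_per_species = 2,
                                    n_reassignments = 3, n_hybrids = 2,
                                    seed = 77))
  ref <- reference_from_truth(sim)
  al <- trim_to_region(sim$records, mode = "auto")
  tab <- name_haplotypes(collapse_haplotypes(al))
  fl <- flag_discrepancies(identify_all(tab, ref), tab, al$records)
  planted <- c(sim$truth$planted_reassignments, sim$truth$planted_hybrids)
  expect_true(all(fl$discrepancy[fl$id %in% planted]))
  expect_true(all(fl$hybrid_evidence[fl$id %in% sim$truth$planted_hybrids]))
  expect_false(any(fl$discrepancy[!fl$id %in% planted]))
})

test_that("population tables report cross-pair means and ranges", {
  L <- 530
  a <- strrep("A", L)
  b <- paste0(strrep("G", 5), strrep("A", L - 5))
  c2 <- paste0(strrep("C", 11), strrep("A", L - 11))
  dm <- k2p_matrix(c(GnA = a, GnB = b, Gg = c2))
  # singleton vs singleton: mean == min == max == the single pair value
  pt <- population_table(dm, list(GnA = "GnA", GnB = "GnB", Gg = "Gg"))
  ab <- pt[pt$group_a == "GnA" & pt$group_b == "GnB", ]
  expect_equal(ab$mean, k2p(a, b)$d)
  expect_equal(ab$min, ab$max)
  # self-pair of singleton is 0
  self <- pt[pt$group_a == "GnA" & pt$group_b == "GnA", ]
  expect_equal(c(self$mean, self$min, self$max), c(0, 0, 0))

  expect_error(population_table(dm, list(g = "missing_hap")), "missing_hap")
  expect_error(population_table(dm, list(g1 = "GnA", g2 = "GnA")), "disjoint")
})

test_that("population means agree with an independent matrix-mask aggregation", {
  withr::local_seed(55)
  base <- random_dna(530)
  seqs <- setNames(vapply(c(0, 2, 3, 12, 14, 30, 33),
                          function(k) mutate_dna(base, k), character(1)),
                   sprintf("h%d", 1:7))
  dm <- k2p_matrix(seqs)
  groups <- list(north = c("h1", "h2"), asi = c("h3", "h4"),
                 asia = c("h5", "h6", "h7"))
  pt <- population_table(dm, groups)
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j < i) next
      mask_a <- rownames(dm$d) %in% groups[[i]]
      mask_b <- rownames(dm$d) %in% groups[[j]]
      vals <- if (i == j) dm$d[mask_a, mask_b][upper.tri(dm$d[mask_a, mask_b])]
              else as.vector(dm$d[mask_a, mask_b])
      row <- pt[pt$group_a == names(groups)[i] &
                pt$group_b == names(groups)[j], ]
      if (length(vals) == 0) expect_equal(row$mean, 0)
      else expect_equal(row$mean, mean(vals))
    }
  }
})

test_that("a three-population design recovers its planted divergences", {
  # populations diverge from the species founder by 0.003, 0.015 and 0.045
  # substitutions/site; expected cross-population distance is the branch sum
  cfg <- sim_config(n_species = 1, samples_per_species = 18,
                    haplotypes_per_species = 6, seed = 61,
                    populations = list(
                      sp01 = list(locations = c("near", "mid", "far"),
                                  counts = c(6L, 6L, 6L),
                                  divergence = c(0.003, 0.015, 0.045),
                                  haplotypes = c(2L, 2L, 2L))))
  sim <- simulate_survey(cfg)
  al <- trim_to_region(sim$records, mode = "auto")
  tab <- name_haplotypes(collapse_haplotypes(al, group_key = "species+location"))
  dm <- k2p_matrix(tab)
  groups <- split(tab$haplotype, sub(".* @ ", "", tab$group))
  pt <- population_table(dm, groups)
  planted <- c(near.mid = 0.018, near.far = 0.048, mid.far = 0.060)
  L <- 530
  for (nm in names(planted)) {
    ab <- strsplit(nm, ".", fixed = TRUE)[[1]]
    row <- pt[(pt$group_a == ab[1] & pt$group_b == ab[2]) |
              (pt$group_a == ab[2] & pt$group_b == ab[1]), ]
    tol <- 3 * sqrt(planted[[nm]] / L) + 2 * 0.002  # binomial SE + within noise
    expect_lt(abs(row$mean - planted[[nm]]), tol)
  }
  # ordering of recovered means follows the planted geography
  get_mean <- function(a, b) pt[(pt$group_a == a & pt$group_b == b) |
                                (pt$group_a == b & pt$group_b == a), "mean"]
  expect_lt(get_mean("near", "mid"), get_mean("mid", "far"))
})
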