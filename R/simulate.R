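#' Configuration for a synthetic barcode survey
#'
#' Defines the study conditions a simulated multi-species COI barcode survey
#' emulates: sequence length, transition/transversion rate ratio, typical
#' within-species haplotype divergence, depth of between-species divergence,
#' skewed haplotype frequencies, optional geographic population structure,
#' and planted hybrid / mislabeled ("reassignment") samples with known
#' ground truth.
#'
#' @param n_species number of species.
#' @param L sequence length in bp (default 530, a typical COI analysis
#'   window).
#' @param kappa transition/transversion rate ratio (default 2).
#' @param within_divergence expected substitutions/site separating
#'   conspecific haplotypes from their species founder (default 0.002).
#' @param between_divergence mean pairwise species divergence the species
#'   tree is scaled to (default 0.15).
#' @param min_between floor on the smallest between-species divergence
#'   (default 0.02); keeps sister species distinguishable, as real barcode
#'   surveys rely on.
#' @param max_between cap on the deepest between-species divergence
#'   (default 0.29), keeping distances in the range observed for fish COI
#'   and away from saturation.
#' @param samples_per_species scalar or length-\code{n_species} vector.
#' @param haplotypes_per_species optional vector of haplotype counts; when
#'   NULL a small skewed number is drawn per species.  Sample counts per
#'   haplotype are skewed: the first haplotype takes all samples not
#'   allocated to the singletons (a (5,1,1,1)-like distribution).
#' @param n_hybrids number of planted hybrid samples: morphological label of
#'   one species, mitochondrial haplotype of a donor species,
#'   \code{hybrid_suspect = TRUE}.
#' @param n_reassignments number of planted mislabeled samples: label of one
#'   species, sequence from a donor species, \code{hybrid_suspect = FALSE}.
#' @param populations optional named list (species -> list with
#'   \code{locations}, \code{counts}, \code{divergence}) splitting a species
#'   into geographic subpopulations whose founders sit at the given
#'   substitutions/site from the species founder.
#' @param species_names optional character vector of species names.
#' @param seed integer seed; the whole survey is reproducible from it.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_species, L = 530L, kappa = 2, within_divergence = 0.002,
                       between_divergence = 0.15, min_between = 0.02,
                       max_between = 0.29, samples_per_species = 8L,
                       haplotypes_per_species = NULL, n_hybrids = 0L,
                       n_reassignments = 0L, populations = NULL,
                       species_names = NULL, seed = 1L) {
  stopifnot(n_species >= 1L, L >= 100L, kappa > 0,
            within_divergence > 0, between_divergence > within_divergence)
  sizes <- rep_len(as.integer(samples_per_species), n_species)
  if (!is.null(haplotypes_per_species)) {
    h <- rep_len(as.integer(haplotypes_per_species), n_species)
    if (any(h > sizes)) {
      stop("more haplotypes than samples for species ",
           paste(which(h > sizes), collapse = ", "), call. = FALSE)
    }
  } else h <- NULL
  structure(list(n_species = as.integer(n_species), L = as.integer(L),
                 kappa = kappa, within_divergence = within_divergence,
                 between_divergence = between_divergence,
                 min_between = min_between, max_between = max_between,
                 samples_per_species = sizes, haplotypes_per_species = h,
                 n_hybrids = as.integer(n_hybrids),
                 n_reassignments = as.integer(n_reassignments),
                 populations = populations, species_names = species_names,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# K80 transition probability matrix at branch length t (expected
# substitutions/site), base order A, G, C, T.  Rates are normalized so t is
# the expected number of substitutions per site.
k80_pmatrix <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e4 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e4 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e4        # each of the two transversion targets
  p_same <- 1 - p_ts - 2 * p_tv
  matrix(c(p_same, p_ts, p_tv, p_tv,
           p_ts, p_same, p_tv, p_tv,
           p_tv, p_tv, p_same, p_ts,
           p_tv, p_tv, p_ts, p_same), 4L, 4L, byrow = TRUE)
}

#' Expected K2P quantities under the two-parameter substitution process
#'
#' Closed-form expected transition proportion P, transversion proportion Q,
#' and the K2P distance recomputed from them at a given divergence.  The
#' model is self-consistent: the returned \code{d} equals
#' \code{branch_length} exactly, which anchors estimator-recovery tests.
#'
#' @param branch_length expected substitutions/site (>= 0).
#' @param kappa transition/transversion rate ratio.
#' @return list with \code{P}, \code{Q}, \code{d}.
#' @examples
#' expected_k2p(0.1, kappa = 2)$d  # 0.1
#' @export
expected_k2p <- function(branch_length, kappa = 2) {
  stopifnot(branch_length >= 0)
  M <- k80_pmatrix(branch_length, kappa)
  P <- M[1, 2]
  Q <- M[1, 3] + M[1, 4]
  d <- if (P == 0 && Q == 0) 0 else
    -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  list(P = P, Q = Q, d = d)
}

# Evolve an integer-coded sequence along a branch of length t (site-wise,
# exact transition probabilities; multiple hits handled by construction).
mutate_codes <- function(codes, t, kappa) {
  if (t <= 0) return(codes)
  M <- k80_pmatrix(t, kappa)
  out <- codes
  for (b in 1:4) {
    idx <- which(codes == b)
    if (length(idx) > 0L) {
      out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = M[b, ])
    }
  }
  out
}

# A variant of `founder` at expected divergence t that differs from every
# sequence in `taken`; retries guard against zero-mutation draws so the
# configured number of distinct haplotypes is honored.
distinct_variant <- function(founder, t, kappa, taken, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    v <- mutate_codes(founder, t, kappa)
    key <- paste(v, collapse = "")
    if (!key %in% taken) return(v)
  }
  stop("could not generate a distinct haplotype variant", call. = FALSE)
}

# Random species tree scaled to the configured divergence regime; returns
# leaf founder sequences (integer codes) and the expected distance matrix.
simulate_species <- function(config) {
  n <- config$n_species
  L <- config$L
  sp <- config$species_names %||% sprintf("sp%02d", seq_len(n))
  root_seq <- sample.int(4L, L, replace = TRUE)
  if (n == 1L) {
    return(list(species = sp, founders = list(root_seq),
                expected_d = matrix(0, 1, 1, dimnames = list(sp, sp)),
                tree = NULL))
  }
  phy <- ape::rtree(n, rooted = TRUE)
  phy$tip.label <- sp
  D <- stats::cophenetic(phy)
  off <- D[upper.tri(D)]
  phy$edge.length <- phy$edge.length * config$between_divergence / mean(off)
  D <- stats::cophenetic(phy)
  mx <- max(D[upper.tri(D)])
  if (mx > config$max_between) {
    phy$edge.length <- phy$edge.length * config$max_between / mx
    D <- stats::cophenetic(phy)
  }
  mn <- min(D[upper.tri(D)])
  if (mn < config$min_between) {
    stem <- (config$min_between - mn) / 2
    tip_edges <- phy$edge[, 2] <= n
    phy$edge.length[tip_edges] <- phy$edge.length[tip_edges] + stem
    D <- stats::cophenetic(phy)
  }
  # evolve the root sequence down the tree
  phy2 <- ape::reorder.phylo(phy, "cladewise")
  node_seq <- vector("list", n + phy2$Nnode)
  node_seq[[n + 1L]] <- root_seq
  for (e in seq_len(nrow(phy2$edge))) {
    p <- phy2$edge[e, 1]; ch <- phy2$edge[e, 2]
    node_seq[[ch]] <- mutate_codes(node_seq[[p]], phy2$edge.length[e],
                                   config$kappa)
  }
  founders <- node_seq[seq_len(n)]
  # founders must be mutually distinct so species remain identifiable
  keys <- vapply(founders, paste, character(1), collapse = "")
  while (anyDuplicated(keys)) {
    i <- which(duplicated(keys))[1]
    founders[[i]] <- distinct_variant(founders[[i]], config$min_between / 2,
                                      config$kappa, keys)
    keys[i] <- paste(founders[[i]], collapse = "")
  }
  D <- D[sp, sp]
  list(species = sp, founders = stats::setNames(founders, sp),
       expected_d = D, tree = phy)
}

#' Simulate a barcode survey with known ground truth
#'
#' Draws a random species tree, evolves founder sequences along it under a
#' two-parameter (transition/transversion) substitution process, generates
#' distinct within-species haplotypes around each founder, assigns samples
#' to haplotypes with skewed frequencies, optionally splits species into
#' diverged geographic subpopulations, and plants hybrid and mislabeled
#' samples.  Byte-identical output for identical seeds.
#'
#' @param config a [sim_config()].
#' @return object of class \code{barcode_survey_sim}: list with
#'   \code{records} (the sample table [read_barcode_fasta()] +
#'   [join_metadata()] would produce), \code{truth} (species tree, per-sample
#'   generating haplotype, planted hybrid/reassignment ids, expected
#'   between-species distances) and \code{config}.
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    spd <- simulate_species(config)
    n <- config$n_species
    sizes <- config$samples_per_species
    hcounts <- config$haplotypes_per_species %||%
      pmin(sizes, 1L + stats::rbinom(n, 3L, 0.3))

    hap_rows <- list()     # species, location, hap index, codes
    sample_rows <- list()
    smp <- 0L
    for (i in seq_len(n)) {
      sp <- spd$species[i]
      pop <- config$populations[[sp]]
      if (is.null(pop)) {
        segs <- list(list(location = "main", count = sizes[i],
                          founder = spd$founders[[i]], h = hcounts[i]))
      } else {
        stopifnot(sum(pop$counts) == sizes[i],
                  length(pop$locations) == length(pop$counts),
                  length(pop$divergence) == length(pop$counts))
        segs <- lapply(seq_along(pop$locations), function(k) {
          h <- if (!is.null(pop$haplotypes)) pop$haplotypes[k]
               else if (pop$counts[k] >= 8L) 3L
               else if (pop$counts[k] >= 4L) 2L else 1L
          list(location = pop$locations[k], count = pop$counts[k],
               founder = mutate_codes(spd$founders[[i]], pop$divergence[k],
                                      config$kappa),
               h = min(h, pop$counts[k]))
        })
      }
      for (seg in segs) {
        taken <- vapply(hap_rows, function(r) paste(r$codes, collapse = ""),
                        character(1))
        haps <- list(seg$founder)
        taken <- c(taken, paste(seg$founder, collapse = ""))
        if (seg$h > 1L) for (k in 2:seg$h) {
          v <- distinct_variant(seg$founder, config$within_divergence,
                                config$kappa, taken)
          haps[[k]] <- v
          taken <- c(taken, paste(v, collapse = ""))
        }
        counts <- c(seg$count - seg$h + 1L, rep(1L, seg$h - 1L))
        for (k in seq_len(seg$h)) {
          hap_rows[[length(hap_rows) + 1L]] <-
            list(species = sp, location = seg$location, index = k,
                 codes = haps[[k]])
          for (s in seq_len(counts[k])) {
            smp <- smp + 1L
            sample_rows[[length(sample_rows) + 1L]] <-
              data.frame(id = sprintf("smp%03d", smp), species = sp,
                         location = seg$location, hybrid_suspect = FALSE,
                         sequence = paste(c("A", "G", "C", "T")[haps[[k]]],
                                          collapse = ""),
                         true_species = sp, planted = "none",
                         stringsAsFactors = FALSE)
          }
        }
      }
    }

    planted <- plant_cases(config, spd)
    records <- rbind(do.call(rbind, sample_rows), planted)
    truth <- list(
      species = spd$species,
      tree_newick = if (is.null(spd$tree)) NA_character_
                    else ape::write.tree(spd$tree),
      expected_between = spd$expected_d,
      haplotypes = data.frame(
        species = vapply(hap_rows, `[[`, character(1), "species"),
        location = vapply(hap_rows, `[[`, character(1), "location"),
        index = vapply(hap_rows, `[[`, integer(1), "index"),
        sequence = vapply(hap_rows, function(r)
          paste(c("A", "G", "C", "T")[r$codes], collapse = ""), character(1)),
        stringsAsFactors = FALSE),
      sample_map = records[c("id", "species", "true_species", "planted")],
      planted_hybrids = records$id[records$planted == "hybrid"],
      planted_reassignments = records$id[records$planted == "reassignment"])
    records <- records[c("id", "species", "location", "hybrid_suspect",
                         "sequence")]
    rownames(records) <- NULL
    structure(list(records = records, truth = truth, config = config),
              class = "barcode_survey_sim")
  })
}

# Planted hybrid and mislabeled samples: morphological label from the
# recipient species, sequence copied from the donor species' founder.
plant_cases <- function(config, spd) {
  n_cases <- config$n_hybrids + config$n_reassignments
  if (n_cases == 0L || config$n_species < 2L) {
    return(data.frame(id = character(0), species = character(0),
                      location = character(0), hybrid_suspect = logical(0),
                      sequence = character(0), true_species = character(0),
                      planted = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(n_cases), function(k) {
    pair <- sample(spd$species, 2L)
    is_hybrid <- k <= config$n_hybrids
    donor_seq <- paste(c("A", "G", "C", "T")[spd$founders[[pair[2]]]],
                       collapse = "")
    data.frame(
      id = if (is_hybrid) sprintf("hyb%02d", k)
           else sprintf("ras%02d", k - config$n_hybrids),
      species = pair[1], location = "main",
      hybrid_suspect = is_hybrid, sequence = donor_seq,
      true_species = pair[2],
      planted = if (is_hybrid) "hybrid" else "reassignment",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a reference library from simulation ground truth
#'
#' One entry per true haplotype, labeled with its species.  Optionally the
#' last \code{n_omit_minor} minor haplotypes (index > 1, i.e. the
#' lower-frequency variants) are left out, emulating variants a public
#' reference library has not seen yet — those haplotypes are then reported
#' "new" by [new_vs_reference()].
#'
#' @param sim a \code{barcode_survey_sim}.
#' @param n_omit_minor how many minor haplotypes to omit (default 0).
#' @return a reference library data.frame (id, species, source, location,
#'   sequence).
#' @export
reference_from_truth <- function(sim, n_omit_minor = 0L) {
  h <- sim$truth$haplotypes
  ref <- data.frame(
    id = sprintf("ref_%s_%s_h%d", h$species, h$location, h$index),
    species = h$species, source = "synthetic-truth", location = h$location,
    sequence = h$sequence, stringsAsFactors = FALSE)
  if (n_omit_minor > 0L) {
    minor <- which(h$index > 1L)
    if (length(minor) < n_omit_minor) {
      stop("only ", length(minor), " minor haplotypes available to omit",
           call. = FALSE)
    }
    ref <- ref[-utils::tail(minor, n_omit_minor), , drop = FALSE]
  }
  rownames(ref) <- NULL
  ref
}

#' Write a simulated survey to disk
#'
#' Emits the FASTA + metadata TSV dialect the readers consume, and the
#' ground truth as JSON.
#'
#' @param sim a \code{barcode_survey_sim}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_survey <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_barcode_fasta(sim$records, file.path(dir, "sequences.fasta"))
  meta <- sim$records[c("id", "species", "location", "hybrid_suspect")]
  meta$hybrid_suspect <- ifelse(meta$hybrid_suspect, "yes", "no")
  utils::write.table(meta, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$expected_between <- as.data.frame(truth$expected_between)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Study conditions of a Sea-of-Galilee-like fish survey
#'
#' A 22-species synthetic survey emulating a regional freshwater fish
#' barcode study: realistic skewed sample sizes (1-23 samples per species),
#' 1-4 haplotypes per species, one species split across three geographic
#' subpopulations with a slightly diverged isolated population, two planted
#' hybrid samples and one planted mislabeled sample.
#'
#' @param seed integer seed.
#' @return a \code{sim_config}.
#' @export
galilee_survey_config <- function(seed = 42L) {
  sizes <- c(5L, 8L, 7L, 7L, 5L, 5L, 14L, 2L, 11L, 23L, 1L, 3L, 3L, 1L,
             8L, 7L, 9L, 9L, 8L, 6L, 21L, 7L)
  haps <- c(1L, 4L, 2L, 2L, 3L, 1L, 4L, 1L, 2L, 2L, 1L, 2L, 1L, 1L,
            2L, 1L, 2L, 3L, 1L, 2L, 1L, 1L)
  sim_config(
    n_species = 22L, L = 530L, kappa = 2,
    within_divergence = 0.002, between_divergence = 0.15,
    samples_per_species = sizes, haplotypes_per_species = haps,
    n_hybrids = 2L, n_reassignments = 1L,
    populations = list(
      sp07 = list(locations = c("lake", "spring", "stream"),
                  counts = c(8L, 3L, 3L),
                  divergence = c(0, 0, 0.003))),
    seed = seed)
}
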