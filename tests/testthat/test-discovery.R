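test_that("canonical seed counting slides windows and folds strands", {
  cfg <- discovery_config(lmer_size = 8, min_seed_count = 2,
                          min_consensus_len = 100)
  g <- Biostrings::DNAStringSet(c(c1 = strrep("A", 13)))
  cs <- count_seeds(g, cfg)
  expect_equal(cs$lmer, strrep("A", 8))
  expect_equal(cs$count, 6)

  set.seed(2)
  s <- rand_seq(5000)
  both <- Biostrings::DNAStringSet(c(f = s, r = rc(s)))
  one <- Biostrings::DNAStringSet(c(f = s))
  cfg2 <- discovery_config(lmer_size = 12, min_seed_count = 1)
  c_one <- count_seeds(one, cfg2)
  c_both <- count_seeds(both, cfg2)
  m <- match(c_one$lmer, c_both$lmer)
  expect_false(anyNA(m))
  expect_equal(c_both$count[m], 2L * c_one$count)
})

test_that("a planted repeat dominates the seed ranking", {
  set.seed(3)
  el <- rand_seq(500)
  pl <- plant_copies(el, 20, 1e5)
  cs <- count_seeds(Biostrings::DNAStringSet(c(g = pl$genome)),
                    discovery_config())
  top <- cs$lmer[1]
  expect_true(grepl(top, el, fixed = TRUE) || grepl(rc(top), el, fixed = TRUE))
  expect_gte(cs$count[1], 20)
})

test_that("seed extension recovers planted elements", {
  set.seed(4)
  el <- rand_seq(300)
  pl <- plant_copies(el, 10, 5e4)
  seed <- substr(el, 140, 152)
  canon <- min(seed, rc(seed))
  res <- extend_seed(canon, Biostrings::DNAStringSet(c(g = pl$genome)),
                     discovery_config())
  expect_equal(res$support, 10)
  expect_true(grepl(el, res$consensus, fixed = TRUE) ||
                grepl(rc(el), res$consensus, fixed = TRUE))
  expect_lte(nchar(res$consensus), nchar(el) + 10)
})

test_that("majority vote tolerates per-copy mutation", {
  set.seed(6)
  el <- rand_seq(300)
  seed <- substr(el, 140, 152)
  strands <- sample(c("+", "-"), 20, replace = TRUE)
  pl <- plant_copies(el, 20, 1e5, mut = 0, strands = strands)
  # mutate copies but keep the seed word intact so all occurrences are found
  genome <- pl$genome
  for (i in seq_along(pl$start)) {
    cp <- substr(genome, pl$start[i] + 1, pl$end[i])
    ori <- if (strands[i] == "-") rc(cp) else cp
    m <- mutate_seq(ori, 0.05)
    substr(m, 140, 152) <- seed
    if (strands[i] == "-") m <- rc(m)
    substr(genome, pl$start[i] + 1, pl$end[i]) <- m
  }
  canon <- min(seed, rc(seed))
  res <- extend_seed(canon, Biostrings::DNAStringSet(c(g = genome)),
                     discovery_config())
  cons <- res$consensus
  if (!grepl(substr(el, 141, 150), cons, fixed = TRUE)) cons <- rc(cons)
  pa <- Biostrings::pairwiseAlignment(cons, el, type = "local")
  matches <- Biostrings::nmatch(pa)
  expect_gte(matches / nchar(el), 0.98)
})

test_that("extension stops quickly when flanks are random", {
  set.seed(7)
  seed <- rand_seq(13)
  segs <- vapply(1:5, function(i) paste0(rand_seq(300), seed, rand_seq(300)),
                 "")
  g <- Biostrings::DNAStringSet(c(g = paste(segs, collapse = "")))
  cfg <- discovery_config(min_seed_count = 5)
  res <- extend_seed(min(seed, rc(seed)), g, cfg)
  expect_lt(nchar(res$consensus), 13 + 2 * cfg$extension_stop_patience)
  expect_error(extend_seed(rand_seq(13), g, cfg), "min_seed_count")
})

test_that("candidate filters remove simple repeats, shorties and orphans", {
  cands <- data.frame(
    candidate_id = c("a", "b", "c", "d"),
    consensus = c(strrep("AT", 100), rand_seq(1000), rand_seq(90),
                  rand_seq(500)),
    support = c(10, 10, 10, 2), stringsAsFactors = FALSE)
  res <- filter_candidates(cands, discovery_config())
  expect_equal(res$kept$candidate_id, "b")
  lg <- setNames(res$log$reason, res$log$candidate_id)
  expect_true(lg[["a"]] %in% c("tandem", "low_complexity"))
  expect_equal(unname(lg[["c"]]), "length")
  expect_equal(unname(lg[["d"]]), "support")
})

test_that("redundancy merging drops only candidates strictly above 80%", {
  set.seed(8)
  known <- data.frame(family_id = "RU0001", te_class = "LTR",
                      source = "known", consensus = rand_seq(300),
                      stringsAsFactors = FALSE)
  class(known) <- c("te_library", "data.frame")
  shift_base <- function(s, idx) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    code <- match(v[idx], c("A", "C", "G", "T")) - 1L
    v[idx] <- c("A", "C", "G", "T")[((code + 1L) %% 4L) + 1L]
    paste(v, collapse = "")
  }
  exact_dup <- known$consensus
  # keep a shared 20-bp block so the alignment is attempted, then distribute
  # the mismatches evenly over the remainder; full-length alignment identity
  # is exactly 240/300 = 0.80 and 250/300 respectively
  at_80 <- shift_base(known$consensus, 21L + floor((0:59) * 280 / 60))
  above_80 <- shift_base(known$consensus, 21L + floor((0:49) * 280 / 50))
  unrelated <- rand_seq(300)
  de_novo <- data.frame(candidate_id = c("c1", "c2", "c3", "c4"),
                        consensus = c(exact_dup, at_80, above_80, unrelated),
                        stringsAsFactors = FALSE)
  out <- merge_redundant(de_novo, known, discovery_config())
  kept <- out$consensus[out$source == "de_novo"]
  expect_false(exact_dup %in% kept)    # 100% > 80%: dropped
  expect_true(at_80 %in% kept)         # exactly 80%: rule is strictly greater
  expect_false(above_80 %in% kept)
  expect_true(unrelated %in% kept)
  expect_true(all(grepl("^RS[0-9]+$",
                        out$family_id[out$source == "de_novo"])))
  # idempotence
  again <- merge_redundant(out[out$source == "de_novo", ], known,
                           discovery_config())
  expect_equal(sort(again$consensus), sort(out$consensus))
  expect_equal(sort(again$family_id), sort(out$family_id))
})

test_that("structural classification follows the terminal-repeat rules", {
  set.seed(9)
  ltr <- rand_seq(200)
  expect_equal(classify_family(paste0(ltr, rand_seq(800), ltr)), "LTR")
  tir <- rand_seq(30)
  expect_equal(classify_family(paste0(tir, rand_seq(600), rc(tir))), "DNA")
  expect_equal(classify_family(paste0(rand_seq(500), strrep("A", 15))),
               "non-LTR")
  calls <- replicate(100, classify_family(rand_seq(1000)))
  expect_gte(sum(calls == "unknown"), 98)
})

test_that("de novo discovery recovers simulated families", {
  # recent, well-populated families: at most ~10% pairwise divergence
  cfg <- sim_config(seed = 11, genome_length = 4e5, n_families = 8,
                    insertion_rate_per_family = 4,
                    family_length_range = c(400, 1500), split_time = 1.5,
                    ancestral_depth = 1.5, suppression_factor = 1,
                    fragmentation_prob = 0.15)
  fams <- build_family_set(cfg)
  sim <- simulate_two_lineages(fams, cfg)
  disc <- discover_families(list(sim$genomeA, sim$genomeB),
                            discovery_config())
  recovered <- vapply(seq_len(nrow(fams)), function(f) {
    truecons <- fams$consensus[f]
    for (cand in disc$library$consensus) {
      if (!tedyn:::shared_kmer(cand, truecons)) next
      for (s in c(truecons, rc(truecons))) {
        pa <- tedyn:::local_align(cand, s)
        pat <- as.character(Biostrings::pattern(pa))
        sub <- as.character(Biostrings::subject(pa))
        if (nchar(pat) >= 0.9 * nchar(truecons) &&
            tedyn:::alignment_identity(pat, sub) >= 0.9)
          return(TRUE)
      }
    }
    FALSE
  }, TRUE)
  expect_gte(mean(recovered), 0.9)

  # determinism of the full discovery chain
  disc2 <- discover_families(list(sim$genomeA, sim$genomeB),
                             discovery_config())
  expect_identical(disc$library, disc2$library)

  # conservative mode is a stricter filter of the same candidates
  cons <- discover_families(list(sim$genomeA, sim$genomeB),
                            discovery_config(min_consensus_len = 2000))
  expect_lte(nrow(cons$library), nrow(disc$library))
  expect_true(all(nchar(cons$library$consensus) >= 2000))
})
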