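test_that("family set generation handles empty and degenerate configurations", {
  cfg <- sim_config(seed = 1, n_families = 0)
  expect_equal(nrow(build_family_set(cfg)), 0)
  cfg2 <- sim_config(seed = 1, family_length_range = c(260, 300),
                     min_fragment_len = 100)
  expect_s3_class(build_family_set(cfg2), "te_library")
  expect_error(sim_config(seed = 1, family_length_range = c(50, 300),
                          min_fragment_len = 100),
               "min_fragment_len")
  expect_error(sim_config(suppression_window = c(0, 6), split_time = 5),
               "suppression_window")
})

test_that("family set generation is deterministic and classifiable", {
  cfg <- sim_config(seed = 5, n_families = 10,
                    class_mix = c(LTR = 0.4, DNA = 0.3, `non-LTR` = 0.2,
                                  unknown = 0.1))
  f1 <- build_family_set(cfg)
  f2 <- build_family_set(cfg)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 10)
  # the structural signatures must be recoverable by the rule-based classifier
  called <- vapply(f1$consensus, classify_family, "", USE.NAMES = FALSE)
  expect_gte(sum(called == f1$te_class), 9)
})

test_that("simulation is deterministic and respects the null process", {
  cfg <- sim_config(seed = 9, genome_length = 5e4, n_families = 3,
                    insertion_rate_per_family = 1)
  fams <- build_family_set(cfg)
  s1 <- simulate_two_lineages(fams, cfg)
  s2 <- simulate_two_lineages(fams, cfg)
  expect_identical(as.character(s1$genomeA), as.character(s2$genomeA))
  expect_identical(as.character(s1$genomeB), as.character(s2$genomeB))
  expect_identical(s1$truth, s2$truth)

  cfg0 <- sim_config(seed = 9, genome_length = 5e4, n_families = 3,
                     insertion_rate_per_family = 0)
  s0 <- simulate_two_lineages(build_family_set(cfg0), cfg0)
  expect_equal(nrow(s0$truth), 0)
  expect_equal(unname(Biostrings::width(s0$genomeA)), 5e4)
})

test_that("truth intervals stay inside contigs and never overlap", {
  s <- small_sim()
  tr <- s$sim$truth
  for (g in c("A", "B")) {
    sub <- tr[tr$lineage == g, ]
    glen <- Biostrings::width(s$sim[[paste0("genome", g)]])
    expect_true(all(sub$start >= 0 & sub$start < sub$end & sub$end <= glen))
    sub <- sub[order(sub$start), ]
    expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
})

test_that("complete suppression empties the window in lineage A only", {
  cfg <- sim_config(seed = 21, suppression_window = c(0, 0.5),
                    suppression_factor = 0, genome_length = 1e5,
                    n_families = 10, insertion_rate_per_family = 5)
  sim <- simulate_two_lineages(build_family_set(cfg), cfg, sequences = FALSE)
  tA <- sim$truth$true_insertion_time[sim$truth$lineage == "A"]
  tB <- sim$truth$true_insertion_time[sim$truth$lineage == "B"]
  expect_true(all(tA >= 0.5))
  expect_true(any(tB < 0.5))
})

test_that("without suppression the two lineages are statistically symmetric", {
  cfg <- sim_config(seed = 30, suppression_factor = 1, n_families = 10,
                    insertion_rate_per_family = 4, genome_length = 1e5)
  fams <- build_family_set(cfg)
  nA <- nB <- numeric(20)
  for (i in 1:20) {
    c2 <- cfg; c2$seed <- 3000 + i
    s <- simulate_two_lineages(fams, c2, sequences = FALSE)
    nA[i] <- sum(s$truth$lineage == "A")
    nB[i] <- sum(s$truth$lineage == "B")
  }
  # equal-rate Poisson counts: difference of means within 3 standard errors
  se <- sqrt((var(nA) + var(nB)) / 20)
  expect_lt(abs(mean(nA) - mean(nB)), 3 * se)
})

test_that("copy counts respond monotonically to the insertion rate", {
  means <- vapply(c(1, 3, 6), function(rate) {
    m <- numeric(5)
    for (i in 1:5) {
      cfg <- sim_config(seed = 400 + i, n_families = 5,
                        insertion_rate_per_family = rate,
                        genome_length = 1e5)
      s <- simulate_two_lineages(build_family_set(cfg), cfg,
                                 sequences = FALSE)
      m[i] <- nrow(s$truth)
    }
    mean(m)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("with constant rates and no suppression the age spectrum is flat", {
  cfg <- sim_config(seed = 50, suppression_factor = 1, n_families = 10,
                    insertion_rate_per_family = 5, genome_length = 1e5,
                    split_time = 5, ancestral_depth = 5)
  fams <- build_family_set(cfg)
  ages <- unlist(lapply(1:10, function(i) {
    c2 <- cfg; c2$seed <- 5000 + i
    s <- simulate_two_lineages(fams, c2, sequences = FALSE)
    s$truth$true_insertion_time[s$truth$lineage == "B"]
  }))
  # no copy loss is simulated, so insertion times are uniform over the whole
  # history; the younger half should hold about half the copies
  frac_young <- mean(ages < 5)
  se <- sqrt(0.25 / length(ages))
  expect_lt(abs(frac_young - 0.5), 4 * se)
})

test_that("expected pair divergence follows K = 2 r t", {
  expect_equal(expected_pair_divergence(1, 1, 0.015), 0.03)
  expect_equal(expected_pair_divergence(0, 0, 0.015), 0)
  expect_equal(expected_pair_divergence(2, 5, 0.01), 2 * 0.01 * 2)
  expect_error(expected_pair_divergence(-1, 1, 0.015), "non-negative")
  expect_error(expected_pair_divergence(1, 1, -0.1), "non-negative")
})

test_that("simulated pair divergence matches the closed form", {
  # independent oracle: event-based substitution simulation, applied
  # sequentially site by site (not the package's transition-probability path)
  set.seed(77)
  r <- 0.015; t <- 1; L <- 1000
  naive_evolve <- function(v, d) {
    nsub <- rpois(1, d * length(v))
    for (k in seq_len(nsub)) {
      i <- sample.int(length(v), 1)
      v[i] <- sample(setdiff(0:3, v[i]), 1)
    }
    v
  }
  p_obs <- replicate(500, {
    anc <- sample(0:3, L, replace = TRUE)
    a <- naive_evolve(anc, r * t)
    b <- naive_evolve(anc, r * t)
    mean(a != b)
  })
  K <- expected_pair_divergence(t, t, r)
  p_exp <- 0.75 * (1 - exp(-4 * K / 3))
  se <- sd(p_obs) / sqrt(length(p_obs))
  expect_lt(abs(mean(p_obs) - p_exp), 3 * se)
})

test_that("true TMRCA follows the simulated genealogy", {
  truth <- data.frame(
    copy_id = c("x", "y", "z"), lineage = "A", contig = "chrA",
    start = NA_integer_, end = NA_integer_, strand = "+", family_id = "F",
    true_insertion_time = c(5, 2, 3),
    parent_copy_id = c("master", "x", "master"), stringsAsFactors = FALSE)
  m <- true_tmrca_matrix(truth)
  expect_equal(unname(m["x", "y"]), 2)  # parent-child pair coalesces at birth
  expect_equal(unname(m["x", "z"]), 5)  # siblings via the source lineage
  expect_equal(unname(m["y", "z"]), 5)
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_true(isSymmetric(m))
})
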