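stack_hits <- function(ids, aln_cons, aln_copy, cons_start) {
  data.frame(copy_id = ids, aln_cons = aln_cons, aln_copy = aln_copy,
             cons_start = cons_start, stringsAsFactors = FALSE)
}

test_that("stacks project copies onto consensus columns", {
  cons <- "ACGTACGTAC"
  h <- stack_hits(c("a", "b"), c(cons, cons), c(cons, cons), c(1, 1))
  st <- stack_family(h, 10)
  expect_equal(dim(st$mat), c(2, 10))
  expect_true(all(st$mat != "-"))
  expect_identical(st$mat["a", ], st$mat["b", ])
  expect_equal(unname(st$insertions), c(0L, 0L))

  # partial coverage leaves gaps outside the aligned interval
  h2 <- stack_hits("c", substr(cons, 3, 7), substr(cons, 3, 7), 3)
  st2 <- stack_family(h2, 10)
  expect_equal(unname(st2$mat[1, 1:2]), c("-", "-"))
  expect_equal(unname(st2$mat[1, 8:10]), rep("-", 3))
  expect_equal(unname(st2$mat[1, 3:7]),
               strsplit(substr(cons, 3, 7), "")[[1]])

  # copy insertions relative to the consensus are dropped and counted
  h3 <- stack_hits("d", "AC---GTACGTAC", "ACTTTGTACGTAC", 1)
  st3 <- stack_family(h3, 10)
  expect_equal(ncol(st3$mat), 10)
  expect_equal(unname(st3$insertions["d"]), 3L)

  h4 <- stack_hits("e", cons, cons, 5)
  expect_error(stack_family(h4, 10), "beyond consensus length")
})

test_that("pairwise divergence applies the strict overlap rule and JC", {
  set.seed(16)
  row <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  h <- stack_hits(c("a", "b"), c(row, row), c(row, row), 1)
  st <- stack_family(h, 300)
  dv <- pairwise_divergence(st)
  expect_equal(dv$p, 0)
  expect_equal(dv$K, 0)
  expect_equal(dv$overlap, 300)

  # p = 0.1 over 300 columns: JC correction, checked against the closed form
  v <- strsplit(row, "")[[1]]
  idx <- seq(1, 300, by = 10)
  code <- match(v[idx], c("A", "C", "G", "T")) - 1L
  v[idx] <- c("A", "C", "G", "T")[((code + 1L) %% 4L) + 1L]
  row2 <- paste(v, collapse = "")
  h2 <- stack_hits(c("a", "b"), c(row, row), c(row, row2), 1)
  dv2 <- pairwise_divergence(stack_family(h2, 300))
  expect_equal(dv2$p, 0.1)
  expect_equal(dv2$K, -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-12)
  expect_equal(dv2$K, 0.1073256, tolerance = 1e-6)
  # p-distance model returns the raw proportion
  dvp <- pairwise_divergence(stack_family(h2, 300), model = "p")
  expect_equal(dvp$K, 0.1)

  # overlap exactly 200 is omitted (strictly-greater rule), 201 qualifies
  r200 <- substr(row, 1, 200)
  h200 <- stack_hits(c("a", "b"), c(r200, r200), c(r200, r200), 1)
  expect_equal(nrow(pairwise_divergence(stack_family(h200, 300))), 0)
  r201 <- substr(row, 1, 201)
  h201 <- stack_hits(c("a", "b"), c(r201, r201), c(r201, r201), 1)
  expect_equal(nrow(pairwise_divergence(stack_family(h201, 300))), 1)

  # saturation: p >= 0.75 is flagged and carries no JC distance
  v2 <- strsplit(row, "")[[1]]
  code <- match(v2, c("A", "C", "G", "T")) - 1L
  v2 <- c("A", "C", "G", "T")[((code + 1L) %% 4L) + 1L]
  h3 <- stack_hits(c("a", "b"), c(row, row),
                   c(row, paste(v2, collapse = "")), 1)
  dv3 <- pairwise_divergence(stack_family(h3, 300))
  expect_true(dv3$saturated)
  expect_true(is.na(dv3$K))
})

test_that("JC distance agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(17)
  base <- sample(c("A", "C", "G", "T"), 400, TRUE)
  mat <- matrix(rep(base, each = 5), 5, 400, byrow = FALSE,
                dimnames = list(paste0("c", 1:5), NULL))
  mat <- t(vapply(1:5, function(i) {
    row <- base
    if (i > 1) {
      idx <- sample(400, 30 * (i - 1))
      code <- match(row[idx], c("A", "C", "G", "T")) - 1L
      row[idx] <- c("A", "C", "G", "T")[((code + sample(1:3, length(idx),
                                                        TRUE)) %% 4L) + 1L]
    }
    row
  }, character(400)))
  rownames(mat) <- paste0("c", 1:5)
  dv <- pairwise_divergence(list(mat = mat, insertions = NULL))
  expect_true(all(!dv$saturated))
  bin <- ape::as.DNAbin(tolower(mat))
  ref <- as.matrix(ape::dist.dna(bin, model = "JC69"))
  for (k in seq_len(nrow(dv)))
    expect_equal(dv$K[k], ref[dv$copy1[k], dv$copy2[k]], tolerance = 1e-9)
  # convexity of the correction: JC never below the p-distance
  expect_true(all(dv$K >= dv$p))
})

test_that("nearest-neighbour ages follow T = K / (2r) with deterministic ties", {
  dv <- data.frame(copy1 = c("a", "a", "b"), copy2 = c("b", "c", "c"),
                   overlap = c(300L, 300L, 300L), p = c(0.03, 0.06, 0.03),
                   K = c(0.03, 0.06, 0.03), saturated = FALSE,
                   stringsAsFactors = FALSE)
  ea <- element_age(dv, r = 0.015)
  expect_equal(ea$T[ea$copy_id == "a"], 1)
  expect_equal(ea$nearest_neighbor_id[ea$copy_id == "a"], "b")
  # c has equal K to a and b: the smaller partner id wins
  expect_equal(ea$nearest_neighbor_id[ea$copy_id == "c"], "b")
  expect_error(element_age(dv, r = 0), "positive")

  dv0 <- dv; dv0$K[1] <- 0; dv0$p[1] <- 0
  expect_equal(element_age(dv0, 0.015)$T[1], 0)

  # copies without a qualified pair are reported unqualified
  ea2 <- element_age(dv, 0.015, copy_ids = c("a", "b", "c", "lonely"))
  expect_false(ea2$qualified[ea2$copy_id == "lonely"])
  expect_true(is.na(ea2$T[ea2$copy_id == "lonely"]))
  expect_equal(sum(ea2$qualified) + sum(!ea2$qualified), 4)
})

test_that("family-average age is the mean pairwise divergence over 2r", {
  one <- data.frame(copy1 = "a", copy2 = "b", overlap = 300L, p = 0.25,
                    K = 0.30, saturated = FALSE, stringsAsFactors = FALSE)
  fa <- family_average_age(one, 0.015, "F", "both")
  expect_equal(fa$average_insertion_time, 10)

  three <- data.frame(copy1 = c("a", "a", "b"), copy2 = c("b", "c", "c"),
                      overlap = 300L, p = c(0.03, 0.03, 0.06),
                      K = c(0.03, 0.03, 0.06), saturated = FALSE,
                      stringsAsFactors = FALSE)
  fa3 <- family_average_age(three, 0.015)
  expect_equal(fa3$mean_pairwise_K, 0.04)
  expect_equal(fa3$average_insertion_time, 0.04 / 0.03, tolerance = 1e-12)
  expect_equal(fa3$n_pairs, 3L)

  none <- three[0, ]
  fa0 <- family_average_age(none, 0.015, "F")
  expect_true(is.na(fa0$average_insertion_time))
})

test_that("doubling the mismatches doubles the p-distance ages", {
  set.seed(18)
  row <- rand_seq(400)
  shift <- function(s, idx) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    code <- match(v[idx], c("A", "C", "G", "T")) - 1L
    v[idx] <- c("A", "C", "G", "T")[((code + 1L) %% 4L) + 1L]
    paste(v, collapse = "")
  }
  one <- shift(row, seq(1, 400, by = 20))
  two <- shift(row, seq(1, 400, by = 10))
  mk <- function(other) stack_family(
    stack_hits(c("a", "b"), c(row, row), c(row, other), 1), 400)
  t1 <- element_age(pairwise_divergence(mk(one), model = "p"), 0.015)$T[1]
  t2 <- element_age(pairwise_divergence(mk(two), model = "p"), 0.015)$T[1]
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
})

test_that("phylip export mirrors the divergence records", {
  set.seed(19)
  row <- rand_seq(300)
  h <- stack_hits(c("a", "b", "c"), rep(row, 3), rep(row, 3), 1)
  st <- stack_family(h, 300)
  dv <- pairwise_divergence(st)
  f <- withr::local_tempfile(fileext = ".dist")
  m <- export_distance_matrix(st, dv, f)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_true(all(m == 0))
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1])), 3)
  expect_length(lines, 4)

  # entries equal the divergence records to 6 decimals
  v <- strsplit(row, "")[[1]]
  idx <- seq(1, 300, by = 7)
  code <- match(v[idx], c("A", "C", "G", "T")) - 1L
  v[idx] <- c("A", "C", "G", "T")[((code + 1L) %% 4L) + 1L]
  h2 <- stack_hits(c("a", "b", "c"), rep(row, 3),
                   c(row, paste(v, collapse = ""), row), 1)
  st2 <- stack_family(h2, 300)
  dv2 <- pairwise_divergence(st2)
  f2 <- withr::local_tempfile(fileext = ".dist")
  m2 <- export_distance_matrix(st2, dv2, f2)
  for (k in seq_len(nrow(dv2)))
    expect_equal(round(m2[dv2$copy1[k], dv2$copy2[k]], 6),
                 round(dv2$K[k], 6))

  # short members are excluded; fewer than 3 eligible means no file
  h3 <- stack_hits(c("a", "b", "c"),
                   c(row, substr(row, 1, 150), substr(row, 1, 150)),
                   c(row, substr(row, 1, 150), substr(row, 1, 150)), 1)
  st3 <- stack_family(h3, 300)
  f3 <- withr::local_tempfile(fileext = ".dist")
  expect_message(res <- export_distance_matrix(st3,
                                               pairwise_divergence(st3), f3),
                 "fewer than 3")
  expect_null(res)
  expect_false(file.exists(f3))
})

test_that("losing relatives can only push age estimates upward", {
  s <- small_sim()
  set.seed(20)
  ann <- rbind(s$ann$A, s$ann$B)
  full <- date_copies(ann, s$fams, r = s$cfg$subst_rate)
  # delete half of the copies: each survivor's nearest qualified relative can
  # only become more distant, so its estimate can only grow
  keep <- ann[runif(nrow(ann)) > 0.5, , drop = FALSE]
  dropped <- date_copies(keep, s$fams, r = s$cfg$subst_rate)
  f <- full$ages[full$ages$qualified & full$ages$scope != "both", ]
  d <- dropped$ages[dropped$ages$qualified & dropped$ages$scope != "both", ]
  key <- paste(d$copy_id, d$scope)
  m <- match(key, paste(f$copy_id, f$scope))
  delta <- d$T - f$T[m]
  expect_true(all(delta >= -1e-12))
  expect_gt(mean(delta), 0)
  # against the simulated truth, the deletion shifts the mean signed error up
  db_full <- dating_benchmark(full$ages, ann, s$sim$truth)
  db_drop <- dating_benchmark(dropped$ages, keep, s$sim$truth)
  expect_gt(mean(db_drop$pairs$T - db_drop$pairs$true_age),
            mean(db_full$pairs$T - db_full$pairs$true_age))
})
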