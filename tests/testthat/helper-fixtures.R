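# Shared fixtures: all synthetic, generated in code at test time.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rc <- function(s) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(s)))

# substitute exactly round(p * n) positions to a different base
mutate_seq <- function(s, p) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  k <- round(p * length(v))
  idx <- sample(length(v), k)
  shift <- sample(1:3, k, replace = TRUE)
  code <- match(v[idx], c("A", "C", "G", "T")) - 1L
  v[idx] <- c("A", "C", "G", "T")[((code + shift) %% 4L) + 1L]
  paste(v, collapse = "")
}

# plant copies of an element into a random background at evenly spaced,
# non-adjacent positions; returns genome string and 0-based half-open truth
plant_copies <- function(element, n_copies, bg_len, mut = 0,
                         strands = rep("+", n_copies)) {
  gap <- bg_len %/% (n_copies + 1L)
  segs <- character(0)
  starts <- integer(0)
  pos <- 0L
  for (i in seq_len(n_copies)) {
    segs <- c(segs, rand_seq(gap))
    pos <- pos + gap
    cp <- if (mut > 0) mutate_seq(element, mut) else element
    if (strands[i] == "-") cp <- rc(cp)
    starts <- c(starts, pos)
    segs <- c(segs, cp)
    pos <- pos + nchar(cp)
  }
  segs <- c(segs, rand_seq(gap))
  list(genome = paste(segs, collapse = ""),
       start = starts, end = starts + nchar(element))
}

# small cached two-lineage simulation shared across test files
.tedyn_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.tedyn_cache$small)) {
    cfg <- sim_config(seed = 101, genome_length = 3e5, n_families = 6,
                      insertion_rate_per_family = 3,
                      family_length_range = c(400, 1500))
    fams <- build_family_set(cfg)
    sim <- simulate_two_lineages(fams, cfg)
    ann <- lapply(c(A = "A", B = "B"), function(g)
      resolve_overlaps(scan_genome(sim[[paste0("genome", g)]], fams,
                                   annotate_config(), genome_id = g)))
    .tedyn_cache$small <- list(cfg = cfg, fams = fams, sim = sim, ann = ann)
  }
  .tedyn_cache$small
}

# hits table builder for resolve_overlaps / stats tests
make_hits <- function(start, end, score, contig = "c1", family = "F1",
                      strand = "+") {
  n <- length(start)
  data.frame(copy_id = sprintf("h%02d", seq_len(n)), genome_id = "G",
             contig = rep_len(contig, n), start = start, end = end,
             strand = rep_len(strand, n), family_id = rep_len(family, n),
             score = score, identity = 1, cons_start = 1L,
             cons_end = end - start, aln_cons = "", aln_copy = "",
             stringsAsFactors = FALSE)
}
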