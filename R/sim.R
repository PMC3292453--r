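#' Simulation configuration for paired two-lineage TE genomes
#'
#' Defines the scenario for [simulate_two_lineages()]: a set of ancestral TE
#' families shared by two lineages that split `split_time` million years (Myr)
#' ago, per-family transposition through time, neutral Jukes-Cantor
#' substitution at `subst_rate`, copy fragmentation, and a recent window in
#' lineage A during which successful insertions are suppressed (the analog of
#' the onset of predominant selfing).
#'
#' @param seed integer seed; all randomness in the simulator derives from it.
#' @param genome_length background (non-TE) bp per lineage.
#' @param n_families number of ancestral TE families.
#' @param family_length_range bp interval for family consensus lengths.
#' @param split_time Myr before present at which the two lineages split.
#' @param ancestral_depth Myr of shared ancestral history before the split
#'   during which pre-split copies accumulate.
#' @param suppression_window Myr interval (within `[0, split_time]`) in lineage
#'   A during which insertions succeed only with probability
#'   `suppression_factor`.
#' @param suppression_factor multiplier in `[0, 1]` on insertion success inside
#'   the window (1 = no suppression).
#' @param subst_rate substitutions/site/Myr (default 0.015).
#' @param insertion_rate_per_family transposition events per Myr per family per
#'   lineage.
#' @param p_source_master probability that a transposition event replicates the
#'   family's master (source) lineage; with probability `1 - p_source_master`
#'   it replicates a uniformly chosen existing copy instead.
#' @param fragmentation_prob probability that an observed copy is truncated.
#' @param min_fragment_len minimum bp retained by truncation.
#' @param class_mix named proportions over classes LTR, DNA, non-LTR, unknown
#'   used by [build_family_set()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6,
                       n_families = 25L,
                       family_length_range = c(400L, 2500L),
                       split_time = 5,
                       ancestral_depth = 5,
                       suppression_window = c(0, 0.413),
                       suppression_factor = 0.2,
                       subst_rate = 0.015,
                       insertion_rate_per_family = 6,
                       p_source_master = 1,
                       fragmentation_prob = 0.35,
                       min_fragment_len = 100L,
                       class_mix = c(LTR = 0.3, DNA = 0.35,
                                     `non-LTR` = 0.2, unknown = 0.15)) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_families = as.integer(n_families),
              family_length_range = as.integer(family_length_range),
              split_time = split_time, ancestral_depth = ancestral_depth,
              suppression_window = suppression_window,
              suppression_factor = suppression_factor, subst_rate = subst_rate,
              insertion_rate_per_family = insertion_rate_per_family,
              p_source_master = p_source_master,
              fragmentation_prob = fragmentation_prob,
              min_fragment_len = as.integer(min_fragment_len),
              class_mix = class_mix)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$genome_length > 0, cfg$n_families >= 0,
    length(cfg$family_length_range) == 2,
    cfg$family_length_range[1] <= cfg$family_length_range[2],
    cfg$split_time >= 0, cfg$ancestral_depth >= 0,
    cfg$subst_rate >= 0, cfg$insertion_rate_per_family >= 0,
    cfg$suppression_factor >= 0, cfg$suppression_factor <= 1,
    cfg$p_source_master >= 0, cfg$p_source_master <= 1,
    cfg$fragmentation_prob >= 0, cfg$fragmentation_prob <= 1,
    cfg$min_fragment_len > 0
  )
  if (cfg$suppression_window[1] < 0 || cfg$suppression_window[2] > cfg$split_time ||
      cfg$suppression_window[1] > cfg$suppression_window[2])
    stop("suppression_window must be an interval within [0, split_time]")
  if (cfg$family_length_range[1] < cfg$min_fragment_len)
    stop("family_length_range minimum must be >= min_fragment_len")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-lineage TE genome simulation configuration\n")
  cat(sprintf("  %d families of %d-%d bp; background %g bp per lineage\n",
              x$n_families, x$family_length_range[1], x$family_length_range[2],
              x$genome_length))
  cat(sprintf("  split %g Myr ago, ancestral depth %g Myr\n",
              x$split_time, x$ancestral_depth))
  cat(sprintf("  substitution rate %g /site/Myr; %g insertions/Myr/family\n",
              x$subst_rate, x$insertion_rate_per_family))
  cat(sprintf("  lineage-A suppression: factor %g in [%g, %g] Myr\n",
              x$suppression_factor, x$suppression_window[1],
              x$suppression_window[2]))
  invisible(x)
}

#' Generate the shared ancestral TE family set
#'
#' Draws `n_families` random consensus sequences carrying the structural
#' signatures the rule-based classifier detects: direct long terminal repeats
#' (LTR), terminal inverted repeats (DNA transposons), a 3' poly-A tail
#' (non-LTR), or none (unknown). Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a `te_library` data frame with columns `family_id`, `te_class`,
#'   `source`, `consensus`.
#' @export
build_family_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_families == 0L) return(empty_library())
  if (cfg$family_length_range[1] < 250L)
    stop("family_length_range too small to host terminal structures (need >= 250 bp)")
  set.seed(derive_seed(cfg$seed, 0))
  mix <- cfg$class_mix / sum(cfg$class_mix)
  counts <- diff(round(cumsum(c(0, mix)) * cfg$n_families))
  classes <- rep(names(mix), counts)
  fams <- lapply(seq_len(cfg$n_families), function(i) {
    len <- sample(cfg$family_length_range[1]:cfg$family_length_range[2], 1)
    cls <- classes[i]
    cons <- switch(cls,
      LTR = {
        ltr <- random_dna(max(45L, round(0.18 * len)))
        body <- random_dna(max(50L, len - 2L * nchar(ltr)))
        paste0(ltr, body, ltr)
      },
      DNA = {
        tir <- random_dna(60L)
        body <- random_dna(max(50L, len - 120L))
        paste0(tir, body, revcomp_chr(tir))
      },
      `non-LTR` = paste0(random_dna(max(50L, len - 15L)), strrep("A", 15L)),
      unknown = random_dna(len)
    )
    data.frame(family_id = sprintf("TF%04d", i), te_class = cls,
               source = "known", consensus = cons, stringsAsFactors = FALSE)
  })
  lib <- do.call(rbind, fams)
  class(lib) <- c("te_library", "data.frame")
  lib
}

empty_library <- function() {
  lib <- data.frame(family_id = character(), te_class = character(),
                    source = character(), consensus = character(),
                    stringsAsFactors = FALSE)
  class(lib) <- c("te_library", "data.frame")
  lib
}

empty_truth <- function() {
  data.frame(copy_id = character(), lineage = character(), contig = character(),
             start = integer(), end = integer(), strand = character(),
             family_id = character(), true_insertion_time = numeric(),
             parent_copy_id = character(), stringsAsFactors = FALSE)
}

# Jukes-Cantor evolution of an integer-coded sequence over `d` expected
# substitutions per site: each site changes with probability
# 3/4 (1 - exp(-4d/3)) and, given change, moves to a uniformly chosen
# different base (exact JC transition probabilities).
jc_evolve <- function(v, d) {
  if (d <= 0 || length(v) == 0) return(v)
  p_change <- 0.75 * (1 - exp(-4 * d / 3))
  idx <- which(runif(length(v)) < p_change)
  if (length(idx))
    v[idx] <- (v[idx] + sample.int(3L, length(idx), replace = TRUE)) %% 4L
  v
}

#' Expected divergence between a copy and the element it replicated
#'
#' For two copies whose sequence lineages separate at the younger copy's
#' insertion (a parent-child pair in the simulator), the expected
#' substitutions-per-site divergence is `K = 2 r min(t1, t2)`: both lineages
#' accumulate substitutions independently at rate `r` since the replication
#' event. When both copies date from the same event time `t` this collapses to
#' `K = 2 r t`.
#'
#' @param t1,t2 insertion times in Myr before present (non-negative).
#' @param r substitution rate in substitutions/site/Myr.
#' @return expected divergence K (substitutions/site); vectorised.
#' @export
expected_pair_divergence <- function(t1, t2, r) {
  if (any(t1 < 0) || any(t2 < 0)) stop("insertion times must be non-negative")
  if (any(r < 0)) stop("substitution rate must be non-negative")
  2 * r * pmin(t1, t2)
}

# one transposition history for a single family along one lineage segment.
# `copies` is a list of lists(birth, parent, seq, cur_age); events is a
# decreasing vector of event ages within (age_to, age_from].
run_events <- function(copies, events, age_to, cfg, with_seq) {
  for (a in events) {
    src <- if (length(copies) == 1L || runif(1) < cfg$p_source_master) 1L
           else sample.int(length(copies), 1L)
    if (with_seq) {
      copies[[src]]$seq <- jc_evolve(copies[[src]]$seq,
                                     cfg$subst_rate * (copies[[src]]$cur_age - a))
    }
    copies[[src]]$cur_age <- a
    copies[[length(copies) + 1L]] <-
      list(birth = a, parent = src, seq = copies[[src]]$seq, cur_age = a)
  }
  if (with_seq) {
    for (i in seq_along(copies)) {
      copies[[i]]$seq <- jc_evolve(copies[[i]]$seq,
                                   cfg$subst_rate * (copies[[i]]$cur_age - age_to))
      copies[[i]]$cur_age <- age_to
    }
  } else {
    for (i in seq_along(copies)) copies[[i]]$cur_age <- age_to
  }
  copies
}

#' Simulate two diverged genomes with known TE insertion histories
#'
#' Each family descends from a single master (source) lineage that originates
#' `ancestral_depth + split_time` Myr ago and evolves like any other sequence,
#' but is not itself an observed genomic copy: every observed copy is the
#' product of a dated transposition event. Events arrive as a Poisson process
#' per family per lineage; each event replicates the master lineage (or, with
#' probability `1 - p_source_master`, a uniformly chosen existing copy) at the
#' event time, after which all copies accumulate Jukes-Cantor substitutions
#' independently until the present. Copies existing at the split are inherited
#' by both lineages. In lineage A, events inside `suppression_window` succeed only with
#' probability `suppression_factor`. Observed copies are truncated with
#' probability `fragmentation_prob` and placed, non-overlapping and unnested,
#' into an independent random background per lineage.
#'
#' @param families a `te_library` from [build_family_set()].
#' @param cfg a [sim_config()].
#' @param sequences if `FALSE`, only the truth table is produced (no sequence
#'   evolution or placement; coordinates are `NA`) -- the fast path for power
#'   studies over insertion times.
#' @return a list with `genomeA`, `genomeB` (single-contig
#'   [Biostrings::DNAStringSet] objects, or `NULL` when `sequences = FALSE`)
#'   and `truth`, a data frame with one row per surviving copy: `copy_id`,
#'   `lineage`, `contig`, `start`, `end` (0-based half-open), `strand`,
#'   `family_id`, `true_insertion_time` (Myr), `parent_copy_id`.
#' @export
simulate_two_lineages <- function(families, cfg, sequences = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(families) == 0L) stop("families must be non-empty")
  set.seed(derive_seed(cfg$seed, 1))
  anc_start <- cfg$split_time + cfg$ancestral_depth
  per_lineage <- list(A = list(), B = list())  # per family copy lists

  for (f in seq_len(nrow(families))) {
    master <- list(birth = anc_start, parent = 0L,
                   seq = if (sequences) seq_to_int(families$consensus[f]) else integer(),
                   cur_age = anc_start)
    n_anc <- rpois(1, cfg$insertion_rate_per_family * cfg$ancestral_depth)
    ev_anc <- sort(runif(n_anc, cfg$split_time, anc_start), decreasing = TRUE)
    anc <- run_events(list(master), ev_anc, cfg$split_time, cfg, sequences)
    for (lin in c("A", "B")) {
      n_post <- rpois(1, cfg$insertion_rate_per_family * cfg$split_time)
      ev <- runif(n_post, 0, cfg$split_time)
      if (lin == "A" && cfg$suppression_factor < 1) {
        inside <- ev >= cfg$suppression_window[1] & ev < cfg$suppression_window[2]
        keep <- !inside | runif(n_post) < cfg$suppression_factor
        ev <- ev[keep]
      }
      ev <- sort(ev, decreasing = TRUE)
      per_lineage[[lin]][[f]] <- run_events(anc, ev, 0, cfg, sequences)
    }
  }

  out <- list(genomeA = NULL, genomeB = NULL, truth = empty_truth())
  truth_parts <- list()
  for (lin in c("A", "B")) {
    fam_lists <- per_lineage[[lin]]
    # element 1 of each family list is the virtual master (source) lineage;
    # it is not an observed genomic copy
    n_per_fam <- vapply(fam_lists, length, 0L) - 1L
    fam_of <- rep(seq_along(fam_lists), n_per_fam)
    idx_in_fam <- unlist(lapply(n_per_fam, function(m) seq_len(m) + 1L),
                         use.names = FALSE)
    births <- unlist(lapply(fam_lists, function(l)
      vapply(l[-1], `[[`, 0, "birth")))
    parents <- unlist(lapply(fam_lists, function(l)
      vapply(l[-1], `[[`, 0L, "parent")))
    n <- length(births)
    contig <- paste0("chr", lin)
    if (n == 0L) {
      if (sequences)
        out[[paste0("genome", lin)]] <- Biostrings::DNAStringSet(
          setNames(random_dna(cfg$genome_length), contig))
      truth_parts[[lin]] <- empty_truth()
      next
    }
    ord <- sample.int(n)  # genome order
    ids <- sprintf("%s_%05d", lin, seq_len(n))  # in genome order
    # map (family, index-in-family) -> genome-order id
    key <- paste(fam_of, idx_in_fam)
    id_of_key <- setNames(ids, key[ord])
    parent_id <- ifelse(parents[ord] == 1L, "master",
                        unname(id_of_key[paste(fam_of[ord], parents[ord])]))
    strand <- sample(c("+", "-"), n, replace = TRUE)

    if (sequences) {
      seqs <- unlist(lapply(fam_lists,
                            function(l) lapply(l[-1], `[[`, "seq")),
                     recursive = FALSE)
      seqs <- seqs[ord]
      lens <- vapply(seqs, length, 0L)
      # fragmentation: keep a random contiguous window
      frag <- runif(n) < cfg$fragmentation_prob & lens > cfg$min_fragment_len
      for (i in which(frag)) {
        flen <- sample(cfg$min_fragment_len:lens[i], 1L)
        off <- sample.int(lens[i] - flen + 1L, 1L) - 1L
        seqs[[i]] <- seqs[[i]][(off + 1L):(off + flen)]
      }
      lens <- vapply(seqs, length, 0L)
      G <- cfg$genome_length
      if (G < n) stop("genome too short to place ", n, " copies")
      bg <- random_dna(G)
      cuts <- sort(round(runif(n, 0, G)))
      starts0 <- cuts + c(0, cumsum(lens[-n]))  # 0-based
      ends0 <- starts0 + lens
      ins <- vapply(seq_len(n), function(i) {
        s <- int_to_seq(seqs[[i]])
        if (strand[i] == "-") revcomp_chr(s) else s
      }, "")
      segs <- substring(bg, c(0, cuts) + 1L, c(cuts, G))
      genome <- paste0(paste0(segs[seq_len(n)], ins, collapse = ""), segs[n + 1L])
      gset <- Biostrings::DNAStringSet(setNames(genome, contig))
      out[[paste0("genome", lin)]] <- gset
      truth_parts[[lin]] <- data.frame(
        copy_id = ids, lineage = lin, contig = contig,
        start = as.integer(starts0), end = as.integer(ends0), strand = strand,
        family_id = families$family_id[fam_of[ord]],
        true_insertion_time = births[ord], parent_copy_id = parent_id,
        stringsAsFactors = FALSE)
    } else {
      truth_parts[[lin]] <- data.frame(
        copy_id = ids, lineage = lin, contig = contig,
        start = NA_integer_, end = NA_integer_, strand = strand,
        family_id = families$family_id[fam_of[ord]],
        true_insertion_time = births[ord], parent_copy_id = parent_id,
        stringsAsFactors = FALSE)
    }
  }
  out$truth <- if (length(truth_parts)) do.call(rbind, truth_parts)
               else empty_truth()
  rownames(out$truth) <- NULL
  out
}

#' True pairwise times to most recent common ancestry within a family
#'
#' Computes, from the simulator's truth records, the age at which the sequence
#' lineages of every pair of copies separate -- the quantity that pairwise
#' divergence `K / (2r)` estimates. Rows must belong to a single family and a
#' single lineage.
#'
#' @param truth_fam truth rows for one family in one lineage.
#' @return a symmetric matrix of coalescence ages (Myr) with zero diagonal,
#'   dimnames = copy ids.
#' @export
true_tmrca_matrix <- function(truth_fam) {
  stopifnot(length(unique(truth_fam$family_id)) <= 1,
            length(unique(truth_fam$lineage)) <= 1)
  n <- nrow(truth_fam)
  ids <- truth_fam$copy_id
  birth <- setNames(truth_fam$true_insertion_time, ids)
  parent <- setNames(truth_fam$parent_copy_id, ids)
  # ancestry chain of each copy: copies carrying its sequence going back in time
  chains <- lapply(ids, function(i) {
    ch <- i
    while (parent[ch[length(ch)]] != "master") ch <- c(ch, parent[ch[length(ch)]])
    c(ch, "master")  # virtual source lineage as common root
  })
  names(chains) <- ids
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    ci <- chains[[i]]; cj <- chains[[j]]
    common <- intersect(ci, cj)
    # first common ancestor along both chains
    c0 <- common[which.min(match(common, ci))]
    pi_ <- match(c0, ci); pj_ <- match(c0, cj)
    bi <- if (pi_ == 1L) 0 else birth[ci[pi_ - 1L]]
    bj <- if (pj_ == 1L) 0 else birth[cj[pj_ - 1L]]
    # lineages separate where the later-branching side leaves the common copy
    m[i, j] <- m[j, i] <- max(bi, bj)
  }
  m
}
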