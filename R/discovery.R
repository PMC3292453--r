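#' Configuration for de novo repeat-family discovery
#'
#' @param lmer_size seed length in bp (exact-word seeding).
#' @param min_seed_count minimum occurrences (canonical, i.e. a word and its
#'   reverse complement count as one) for a seed to be considered.
#' @param max_extension maximum bp of consensus extension on each side of the
#'   seed.
#' @param extension_stop_patience number of consecutive columns whose majority
#'   support falls below half the occurrences before extension stops; the
#'   failed run is trimmed from the consensus.
#' @param min_consensus_len minimum candidate consensus length in bp
#'   (conservative mode: 2000).
#' @param redundancy_identity identity fraction above which (strictly) a de
#'   novo candidate is considered redundant with a known family.
#' @param low_complexity_entropy Shannon entropy threshold in bits/base below
#'   which a candidate is discarded as low complexity.
#' @param min_copy_support minimum genomic copies supporting a candidate.
#' @param max_families stop after this many candidate families.
#' @param class_tr_identity,class_tr_minlen identity and minimum aligned length
#'   for a terminal-repeat call in [classify_family()].
#' @param class_polya_len minimum 3' poly-A run for a non-LTR call.
#' @return an object of class `discovery_config`.
#' @export
discovery_config <- function(lmer_size = 13L, min_seed_count = 5L,
                             max_extension = 4000L,
                             extension_stop_patience = 15L,
                             min_consensus_len = 100L,
                             redundancy_identity = 0.80,
                             low_complexity_entropy = 1.5,
                             min_copy_support = 3L,
                             max_families = 500L,
                             class_tr_identity = 0.80,
                             class_tr_minlen = 25L,
                             class_polya_len = 10L) {
  cfg <- list(lmer_size = as.integer(lmer_size),
              min_seed_count = as.integer(min_seed_count),
              max_extension = as.integer(max_extension),
              extension_stop_patience = as.integer(extension_stop_patience),
              min_consensus_len = as.integer(min_consensus_len),
              redundancy_identity = redundancy_identity,
              low_complexity_entropy = low_complexity_entropy,
              min_copy_support = as.integer(min_copy_support),
              max_families = as.integer(max_families),
              class_tr_identity = class_tr_identity,
              class_tr_minlen = as.integer(class_tr_minlen),
              class_polya_len = as.integer(class_polya_len))
  stopifnot(cfg$lmer_size >= 8L, cfg$min_consensus_len >= cfg$lmer_size,
            cfg$redundancy_identity > 0, cfg$redundancy_identity < 1)
  structure(cfg, class = "discovery_config")
}

as_dna_set <- function(genomes) {
  if (is(genomes, "DNAStringSet")) return(genomes)
  if (is.list(genomes))
    return(do.call(c, lapply(genomes, as_dna_set)))
  Biostrings::DNAStringSet(genomes)
}

decode_kmer <- function(code, l) {
  out <- character(length(code))
  for (i in seq_along(code)) {
    c0 <- code[i]
    d <- integer(l)
    for (j in l:1) { d[j] <- c0 %% 4; c0 <- c0 %/% 4 }
    out[i] <- paste(BASES[d + 1L], collapse = "")
  }
  out
}

# Canonical l-mer index over a genome set: per-position codes plus counts.
# Codes are 2-bit packed (A=0..T=3); canonical = min(code, revcomp code).
seed_index <- function(genomes, cfg) {
  genomes <- as_dna_set(genomes)
  l <- cfg$lmer_size
  w <- 4^((l - 1):0)
  parts <- list()
  for (ci in seq_along(genomes)) {
    s <- seq_to_int(as.character(genomes[[ci]]))
    n <- length(s)
    if (n < l) next
    fwd <- as.numeric(stats::filter(s, rev(w), method = "convolution", sides = 1))[l:n]
    rc <- as.numeric(stats::filter(3 - s, w, method = "convolution", sides = 1))[l:n]
    canon <- pmin(fwd, rc)
    ok <- !is.na(canon)
    parts[[length(parts) + 1L]] <- data.table::data.table(
      code = canon[ok], contig = names(genomes)[ci],
      pos = which(ok), strand = ifelse(fwd[ok] <= rc[ok], "+", "-"))
  }
  if (!length(parts)) {
    warning("no contig is at least lmer_size long; no seeds counted")
    return(list(counts = data.frame(lmer = character(), count = integer()),
                pos = NULL, contigs = character()))
  }
  dt <- data.table::rbindlist(parts)
  cnt <- dt[, list(count = .N), by = "code"]
  cnt <- cnt[cnt$count >= cfg$min_seed_count, ]
  data.table::setorderv(cnt, c("count", "code"), order = c(-1L, 1L))
  pos <- dt[dt$code %in% cnt$code, ]
  data.table::setkeyv(pos, "code")
  counts <- data.frame(lmer = decode_kmer(cnt$code, l),
                       count = cnt$count, stringsAsFactors = FALSE)
  list(counts = counts, codes = cnt$code, pos = pos,
       contigs = setNames(as.character(genomes), names(genomes)))
}

#' Count repeated seed words (canonical l-mers) in a genome set
#'
#' Exact counts of every l-mer, where a word and its reverse complement are
#' counted as one (canonical form). Only seeds occurring at least
#' `cfg$min_seed_count` times are retained; the result is sorted by descending
#' count with ties broken lexicographically.
#'
#' @param genomes a [Biostrings::DNAStringSet], character vector, or list of
#'   either.
#' @param cfg a [discovery_config()].
#' @return data frame with columns `lmer`, `count`.
#' @export
count_seeds <- function(genomes, cfg = discovery_config()) {
  seed_index(genomes, cfg)$counts
}

# column-major majority vote over a flank character matrix (n occurrences x
# max_extension), returning adopted consensus bases. Per-column quality is
# the majority support fraction minus 0.6 (random flanks sit well below that
# fraction for any occurrence count, genuine family columns well above);
# extension stops when the cumulative quality falls 0.2*patience below its
# running maximum (X-drop), or after `patience` consecutive columns whose
# majority support is below half the occurrences; the consensus is trimmed
# back to the cumulative maximum.
vote_extend <- function(mat, n_occ, patience) {
  if (is.null(dim(mat)) || ncol(mat) == 0L) return(character(0))
  codes <- matrix(match(mat, BASES), nrow = nrow(mat))
  counts <- vapply(1:4, function(b) colSums(codes == b, na.rm = TRUE),
                   numeric(ncol(codes)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  support <- apply(counts, 1L, max)
  maj <- max.col(counts, ties.method = "first")
  cum <- cumsum(support / n_occ - 0.6)
  runmax <- cummax(cum)
  xdrop <- which(runmax - cum >= 0.2 * patience)
  good <- support * 2L >= n_occ
  runs <- rle(good)
  ends <- cumsum(runs$lengths)
  bad_run <- which(!runs$values & runs$lengths >= patience)
  stop_at <- min(if (length(xdrop)) xdrop[1L] else length(cum),
                 if (length(bad_run)) ends[bad_run[1L]] -
                   runs$lengths[bad_run[1L]] + patience else length(cum))
  last <- which.max(cum[seq_len(stop_at)])
  if (cum[last] <= 0) return(character(0))
  BASES[maj[seq_len(last)]]
}

# Occurrence-coherence screen. Seeds inside a terminal inverted repeat (or
# any self-reverse-complementary context) collect occurrences that anchor
# the element in two incompatible orientations; their flanks disagree
# systematically and majority voting would corrupt the consensus. Keep the
# largest subset of rows coherent with the most representative row over the
# near flanks; the discarded anchors re-seed the mirror candidate later,
# which redundancy merging then folds away.
coherent_rows <- function(left, right, min_keep) {
  n <- nrow(left)
  if (n < 3L) return(rep(TRUE, n))
  pair_agree <- function(m) {
    w <- m[, seq_len(min(100L, ncol(m))), drop = FALSE]
    a <- matrix(1, n, n)
    if (ncol(w) < 20L) return(a)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- !is.na(w[i, ]) & !is.na(w[j, ])
      a[i, j] <- a[j, i] <- if (any(ok)) mean(w[i, ok] == w[j, ok]) else 0
    }
    a
  }
  # the two sides are screened separately: a seed near an element edge has
  # one genuinely random (off-element) side that must not dilute the vote
  aL <- pair_agree(left)
  aR <- pair_agree(right)
  ref <- which.max(rowSums(aL) + rowSums(aR))
  keep <- aL[ref, ] >= 0.7 | aR[ref, ] >= 0.7
  if (sum(keep) >= min_keep && any(!keep)) keep else rep(TRUE, n)
}

# shared extension core: occ has columns contig, start (1-based), strand
extend_core <- function(seed, occ, contigs, cfg) {
  l <- nchar(seed)
  n <- nrow(occ)
  maxe <- cfg$max_extension
  flank <- function(side) {
    v <- character(n)
    for (i in seq_len(n)) {
      ctg <- contigs[[occ$contig[i]]]
      st <- occ$start[i]
      if ((side == "right") == (occ$strand[i] == "+")) {
        f <- substr(ctg, st + l, st + l - 1L + maxe)           # genome rightward
        if (occ$strand[i] == "-") f <- revcomp_chr(f)
      } else {
        f <- substr(ctg, max(1L, st - maxe), st - 1L)          # genome leftward
        f <- if (occ$strand[i] == "+") f else revcomp_chr(f)
        if (occ$strand[i] == "+") {
          # left flank read outward from the seed edge
          f <- paste(rev(strsplit(f, "", fixed = TRUE)[[1]]), collapse = "")
        }
      }
      v[i] <- f
    }
    v
  }
  to_mat <- function(strs) {
    chars <- lapply(strs, function(x) strsplit(x, "", fixed = TRUE)[[1]])
    width <- max(lengths(chars), 0L)
    if (width == 0L) return(matrix(character(0), nrow = n, ncol = 0L))
    t(vapply(chars, function(x) c(x, rep(NA_character_, width - length(x))),
             character(width)))
  }
  # right flank in seed orientation, read outward (near base first)
  right_raw <- flank("right")
  # minus-strand right flanks come revcomp'ed with near base first already;
  # plus-strand right flanks are already outward-ordered
  right <- to_mat(right_raw)
  left_raw <- flank("left")
  # plus-strand left flanks were reversed to outward order above; minus-strand
  # left flanks (revcomp of genome rightward) end adjacent to the seed, so
  # reverse them to outward order
  fix <- occ$strand == "-"
  if (any(fix)) left_raw[fix] <- vapply(left_raw[fix], function(x)
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""), "")
  left <- to_mat(left_raw)
  keep <- coherent_rows(left, right, cfg$min_seed_count)
  if (any(!keep)) {
    left <- left[keep, , drop = FALSE]
    right <- right[keep, , drop = FALSE]
    occ <- occ[keep, , drop = FALSE]
    n <- nrow(occ)
  }
  rb <- vote_extend(right, n, cfg$extension_stop_patience)
  lb <- vote_extend(left, n, cfg$extension_stop_patience)
  consensus <- paste0(paste(rev(lb), collapse = ""), seed,
                      paste(rb, collapse = ""))
  left_len <- length(lb); right_len <- length(rb)
  ext_start <- ifelse(occ$strand == "+", occ$start - left_len,
                      occ$start - right_len)
  ext_end <- ifelse(occ$strand == "+", occ$start + l - 1L + right_len,
                    occ$start + l - 1L + left_len)
  list(consensus = consensus, support = n,
       occurrences = data.frame(contig = occ$contig,
                                start = pmax(1L, as.integer(ext_start)),
                                end = as.integer(ext_end),
                                strand = occ$strand, stringsAsFactors = FALSE))
}

#' Extend a seed word into a family consensus by majority vote
#'
#' Collects all occurrences of `seed` (both strands), then extends left and
#' right column by column, taking the majority base across occurrences.
#' Extension stops after `extension_stop_patience` consecutive columns whose
#' majority support falls below half the occurrences, or at `max_extension`.
#'
#' @param seed the seed word (canonical l-mer).
#' @param genomes genome sequences (see [count_seeds()]).
#' @param cfg a [discovery_config()].
#' @param mask optional named list of logical vectors (one per contig) marking
#'   positions already assigned to a family; occurrences touching masked
#'   positions are ignored.
#' @return a list with `consensus`, `support` (number of occurrences used) and
#'   `occurrences` (data frame of the extended genomic extents).
#' @export
extend_seed <- function(seed, genomes, cfg = discovery_config(), mask = NULL) {
  genomes <- as_dna_set(genomes)
  l <- nchar(seed)
  occ <- list()
  rc <- revcomp_chr(seed)
  for (ci in seq_along(genomes)) {
    nm <- names(genomes)[ci]
    hits <- Biostrings::matchPattern(seed, genomes[[ci]])
    if (length(hits))
      occ[[length(occ) + 1L]] <- data.frame(contig = nm,
                                            start = BiocGenerics::start(hits),
                                            strand = "+", stringsAsFactors = FALSE)
    if (rc != seed) {
      mh <- Biostrings::matchPattern(rc, genomes[[ci]])
      if (length(mh))
        occ[[length(occ) + 1L]] <- data.frame(contig = nm,
                                              start = BiocGenerics::start(mh),
                                              strand = "-", stringsAsFactors = FALSE)
    }
  }
  occ <- if (length(occ)) do.call(rbind, occ) else
    data.frame(contig = character(), start = integer(), strand = character())
  if (!is.null(mask) && nrow(occ)) {
    keep <- vapply(seq_len(nrow(occ)), function(i) {
      m <- mask[[occ$contig[i]]]
      !any(m[occ$start[i]:(occ$start[i] + l - 1L)])
    }, TRUE)
    occ <- occ[keep, , drop = FALSE]
  }
  if (nrow(occ) < cfg$min_seed_count)
    stop("seed occurs fewer than min_seed_count times (after masking)")
  contigs <- setNames(as.character(genomes), names(genomes))
  extend_core(seed, occ, contigs, cfg)
}

# periodicity check: best identity between the sequence and itself shifted by
# a small offset, covering > 80% of positions
is_tandem <- function(s, max_offset = 50L) {
  v <- seq_to_int(s)
  L <- length(v)
  for (d in seq_len(min(max_offset, L - 1L))) {
    frac <- mean(v[seq_len(L - d)] == v[(d + 1L):L], na.rm = TRUE)
    if (!is.nan(frac) && frac > 0.8) return(TRUE)
  }
  FALSE
}

#' Filter candidate consensi down to likely TE families
#'
#' Removes candidates that are shorter than `min_consensus_len`, low complexity
#' (Shannon entropy below `low_complexity_entropy` bits/base), tandem-periodic
#' (best self-alignment at offset <= 50 bp matching > 80% of positions), or
#' supported by fewer than `min_copy_support` genomic copies. Each removal is
#' logged with its reason.
#'
#' @param candidates data frame with columns `candidate_id`, `consensus`,
#'   `support`.
#' @param cfg a [discovery_config()].
#' @return list with `kept` (surviving rows) and `log` (data frame
#'   `candidate_id`, `reason`).
#' @export
filter_candidates <- function(candidates, cfg = discovery_config()) {
  if (nrow(candidates) == 0L)
    return(list(kept = candidates,
                log = data.frame(candidate_id = character(),
                                 reason = character())))
  reason <- rep(NA_character_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    s <- candidates$consensus[i]
    if (nchar(s) < cfg$min_consensus_len) reason[i] <- "length"
    else if (shannon_entropy(s) < cfg$low_complexity_entropy)
      reason[i] <- "low_complexity"
    else if (is_tandem(s)) reason[i] <- "tandem"
    else if (candidates$support[i] < cfg$min_copy_support) reason[i] <- "support"
  }
  list(kept = candidates[is.na(reason), , drop = FALSE],
       log = data.frame(candidate_id = candidates$candidate_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE))
}

shared_kmer <- function(a, b, k = 11L) {
  if (nchar(a) < k || nchar(b) < k) return(TRUE)  # too short to prefilter
  ka <- substring(a, 1:(nchar(a) - k + 1L), k:nchar(a))
  kb <- substring(b, 1:(nchar(b) - k + 1L), k:nchar(b))
  if (any(ka %in% kb)) return(TRUE)
  rb <- revcomp_chr(b)
  any(ka %in% substring(rb, 1:(nchar(rb) - k + 1L), k:nchar(rb)))
}

# strictly-greater-than-threshold identity over an alignment covering at
# least half of the shorter sequence, against any member of `others`
is_redundant <- function(cand, others, cfg) {
  for (kn in others) {
    if (!shared_kmer(cand, kn)) next
    best <- NULL
    for (subj in c(kn, revcomp_chr(kn))) {
      pa <- local_align(cand, subj)
      if (is.null(best) || Biostrings::score(pa) > Biostrings::score(best))
        best <- pa
    }
    pat <- as.character(Biostrings::pattern(best))
    sub <- as.character(Biostrings::subject(best))
    if (alignment_identity(pat, sub) > cfg$redundancy_identity &&
        nchar(pat) >= 0.5 * min(nchar(cand), nchar(kn)))
      return(TRUE)
  }
  FALSE
}

#' Merge de novo candidates into a known library, dropping redundant ones
#'
#' Every de novo candidate whose best local alignment to any known family has
#' identity strictly greater than `redundancy_identity` over at least 50% of
#' the shorter sequence is dropped. Survivors receive fresh `RSxxxx`
#' identifiers (known-library entries keep theirs, typically `RUxxxx`); the
#' output is the union of the known library and the survivors. Idempotent:
#' candidates that already carry an RS identifier keep it.
#'
#' @param de_novo data frame of candidates (needs a `consensus` column;
#'   `family_id`/`candidate_id`, `support`, `te_class` are carried through if
#'   present).
#' @param known a `te_library` (or `NULL` for none).
#' @param cfg a [discovery_config()].
#' @return a `te_library` data frame.
#' @export
merge_redundant <- function(de_novo, known = NULL, cfg = discovery_config()) {
  if (is.null(known)) known <- empty_library()
  if (is.null(de_novo) || nrow(de_novo) == 0L) {
    out <- known
    class(out) <- c("te_library", "data.frame")
    return(out)
  }
  drop <- vapply(seq_len(nrow(de_novo)), function(i)
    is_redundant(de_novo$consensus[i], known$consensus, cfg), TRUE)
  surv <- de_novo[!drop, , drop = FALSE]
  ids <- if ("family_id" %in% names(surv)) surv$family_id
         else if ("candidate_id" %in% names(surv)) surv$candidate_id
         else rep(NA_character_, nrow(surv))
  has_rs <- !is.na(ids) & grepl("^RS[0-9]+$", ids)
  existing <- suppressWarnings(as.integer(sub("^RS", "", ids[has_rs])))
  next_id <- if (length(existing)) max(existing) + 1L else 1L
  fresh <- sprintf("RS%04d", seq(next_id, length.out = sum(!has_rs)))
  ids[!has_rs] <- fresh
  add <- data.frame(family_id = ids,
                    te_class = if ("te_class" %in% names(surv)) surv$te_class
                               else NA_character_,
                    source = "de_novo", consensus = surv$consensus,
                    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(known)[, c("family_id", "te_class", "source",
                                        "consensus")], add)
  if (anyDuplicated(out$family_id)) stop("duplicate family_id after merge")
  class(out) <- c("te_library", "data.frame")
  out
}

#' Rule-based TE class assignment from structural signatures
#'
#' LTR if the two terminal windows (first/last 15% of the length, at least
#' 50 bp) align directly at >= 80% identity over >= 40 aligned columns; DNA if
#' they align reverse-complemented (terminal inverted repeat); non-LTR if the
#' 3' end carries a poly-A run of at least 10 bp and no terminal repeat was
#' found; otherwise unknown.
#'
#' @param consensus consensus nucleotide sequence (character).
#' @param cfg a [discovery_config()] holding the thresholds.
#' @return one of `"LTR"`, `"DNA"`, `"non-LTR"`, `"unknown"`.
#' @export
classify_family <- function(consensus, cfg = discovery_config()) {
  L <- nchar(consensus)
  w <- max(50L, round(0.15 * L))
  if (L < 2L * w) w <- floor(L / 2)
  w1 <- substr(consensus, 1L, w)
  w2 <- substr(consensus, L - w + 1L, L)
  tr_call <- function(a, b) {
    # harsh mismatch cost: the optimal local alignment then stays within the
    # high-identity repeat core instead of extending into flanking noise
    pa <- local_align(a, b, match = 1, mismatch = -4, gap_open = -5,
                      gap_extend = -2)
    pat <- as.character(Biostrings::pattern(pa))
    sub <- as.character(Biostrings::subject(pa))
    nchar(pat) >= cfg$class_tr_minlen &&
      alignment_identity(pat, sub) >= cfg$class_tr_identity
  }
  if (w >= cfg$class_tr_minlen) {
    if (tr_call(w1, w2)) return("LTR")
    if (tr_call(w1, revcomp_chr(w2))) return("DNA")
  }
  tail3 <- substr(consensus, max(1L, L - 29L), L)
  runs <- rle(strsplit(tail3, "", fixed = TRUE)[[1]])
  if (any(runs$values == "A" & runs$lengths >= cfg$class_polya_len))
    return("non-LTR")
  "unknown"
}

#' De novo family discovery over a genome set
#'
#' Runs the full discovery chain: canonical l-mer seed counting, rank-ordered
#' seed extension with occurrence masking (so one genomic region seeds at most
#' one family), candidate filtering, redundancy merging against a known
#' library, and rule-based classification of the survivors.
#'
#' @param genomes genome sequences (see [count_seeds()]).
#' @param cfg a [discovery_config()].
#' @param known optional known-family `te_library`.
#' @return list with `library` (a `te_library`), `candidates` (all extended
#'   candidates) and `filter_log`.
#' @export
discover_families <- function(genomes, cfg = discovery_config(), known = NULL) {
  genomes <- as_dna_set(genomes)
  idx <- seed_index(genomes, cfg)
  mask <- lapply(idx$contigs, function(s) rep(FALSE, nchar(s)))
  l <- cfg$lmer_size
  cands <- list()
  if (!is.null(idx$pos)) {
    for (si in seq_along(idx$codes)) {
      if (length(cands) >= cfg$max_families) break
      rows <- idx$pos[list(idx$codes[si]), on = "code"]
      keep <- logical(nrow(rows))
      for (i in seq_len(nrow(rows))) {
        m <- mask[[rows$contig[i]]]
        keep[i] <- !any(m[rows$pos[i]:(rows$pos[i] + l - 1L)])
      }
      if (sum(keep) < cfg$min_seed_count) next
      occ <- data.frame(contig = rows$contig[keep], start = rows$pos[keep],
                        strand = rows$strand[keep], stringsAsFactors = FALSE)
      res <- extend_core(idx$counts$lmer[si], occ, idx$contigs, cfg)
      for (i in seq_len(nrow(res$occurrences))) {
        o <- res$occurrences[i, ]
        hi <- min(o$end, length(mask[[o$contig]]))
        mask[[o$contig]][o$start:hi] <- TRUE
      }
      cands[[length(cands) + 1L]] <-
        data.frame(candidate_id = sprintf("cand%04d", length(cands) + 1L),
                   consensus = res$consensus, support = res$support,
                   stringsAsFactors = FALSE)
    }
  }
  cands <- if (length(cands)) do.call(rbind, cands) else
    data.frame(candidate_id = character(), consensus = character(),
               support = integer(), stringsAsFactors = FALSE)
  flt <- filter_candidates(cands, cfg)
  # self-deduplication: a family can seed several candidates through
  # distinct seed words (including fragments and mirror orientations); keep
  # the longest representative of each redundancy group
  kept <- flt$kept
  if (nrow(kept) > 1L) {
    kept <- kept[order(-nchar(kept$consensus), kept$candidate_id), ,
                 drop = FALSE]
    self_drop <- logical(nrow(kept))
    for (i in 2:nrow(kept))
      self_drop[i] <- is_redundant(kept$consensus[i],
                                   kept$consensus[seq_len(i - 1L)][
                                     !self_drop[seq_len(i - 1L)]], cfg)
    kept <- kept[!self_drop, , drop = FALSE]
    kept <- kept[order(kept$candidate_id), , drop = FALSE]
  }
  lib <- merge_redundant(kept, known, cfg)
  novel <- lib$source == "de_novo" & is.na(lib$te_class)
  for (i in which(novel)) lib$te_class[i] <- classify_family(lib$consensus[i], cfg)
  list(library = lib, candidates = cands, filter_log = flt$log)
}
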