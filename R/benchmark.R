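# Evaluation of pipeline output against simulator truth. Used by the
# validation suite; exported because simulation studies need the same
# machinery.

#' Match annotations to simulated truth copies
#'
#' Same-family best-overlap matching between annotation intervals and truth
#' intervals on the same contig set.
#'
#' @param annotations overlap-resolved annotations of one genome.
#' @param truth truth rows of the same lineage.
#' @return data frame `copy_id`, `truth_id`, `overlap`, `truth_frac`
#'   (overlap / truth length), `hit_frac` (overlap / annotation length).
#' @export
match_truth_copies <- function(annotations, truth) {
  if (!nrow(annotations) || !nrow(truth))
    return(data.frame(copy_id = character(), truth_id = character(),
                      overlap = integer(), truth_frac = numeric(),
                      hit_frac = numeric(), stringsAsFactors = FALSE))
  ir_h <- IRanges::IRanges(annotations$start + 1L, annotations$end)
  ir_t <- IRanges::IRanges(truth$start + 1L, truth$end)
  ov <- IRanges::findOverlaps(ir_h, ir_t)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  same <- annotations$family_id[q] == truth$family_id[s] &
    annotations$contig[q] == truth$contig[s]
  q <- q[same]; s <- s[same]
  if (!length(q))
    return(data.frame(copy_id = character(), truth_id = character(),
                      overlap = integer(), truth_frac = numeric(),
                      hit_frac = numeric(), stringsAsFactors = FALSE))
  w <- IRanges::width(IRanges::pintersect(ir_h[q], ir_t[s]))
  keep <- unlist(tapply(seq_along(q), q, function(ii) ii[which.max(w[ii])]))
  data.frame(copy_id = annotations$copy_id[q[keep]],
             truth_id = truth$copy_id[s[keep]], overlap = w[keep],
             truth_frac = w[keep] / IRanges::width(ir_t)[s[keep]],
             hit_frac = w[keep] / IRanges::width(ir_h)[q[keep]],
             stringsAsFactors = FALSE)
}

# expected p-distance of a copy from the family consensus at age t:
# K = 2 r t along the two branches, p = 3/4 (1 - exp(-4K/3))
expected_p_divergence <- function(t, r) 0.75 * (1 - exp(-8 * r * t / 3))

#' Annotation recall and precision against simulated truth
#'
#' Recall is measured over truth copies at least `min_len` bp long whose
#' expected divergence from the consensus does not exceed `max_divergence`
#' (older copies are outside the method's stated operating range); a truth
#' copy counts as recovered when a same-family annotation covers at least
#' half of it. Precision counts annotations at least half-covered by a
#' same-family truth copy, over all annotations.
#'
#' @param annotations overlap-resolved annotations of one genome.
#' @param truth truth rows of the same lineage.
#' @param min_len minimum truth copy length (bp).
#' @param max_divergence maximum expected p-distance from the consensus.
#' @param r substitution rate used to convert ages to divergences.
#' @return list with `recall`, `precision`, `n_eligible`, `n_annotations`.
#' @export
annotation_benchmark <- function(annotations, truth, min_len = 100L,
                                 max_divergence = 0.20, r = 0.015) {
  p_exp <- expected_p_divergence(truth$true_insertion_time, r)
  eligible <- (truth$end - truth$start) >= min_len & p_exp <= max_divergence
  m <- match_truth_copies(annotations, truth)
  recovered <- m$truth_id[m$truth_frac >= 0.5]
  recall <- if (any(eligible))
    mean(truth$copy_id[eligible] %in% recovered) else NA_real_
  tp <- m$copy_id[m$hit_frac >= 0.5]
  precision <- if (nrow(annotations))
    mean(annotations$copy_id %in% tp) else NA_real_
  list(recall = recall, precision = precision,
       n_eligible = sum(eligible), n_annotations = nrow(annotations))
}

#' Compare per-copy age estimates with simulated truth
#'
#' Joins qualified per-copy estimates (same-genome scope) with their matched
#' truth copies and reports the Spearman rank correlation between true
#' insertion times and estimated times.
#'
#' @param ages the `ages` data frame from [date_copies()].
#' @param annotations concatenated overlap-resolved annotations.
#' @param truth the full truth table.
#' @param scopes genome ids to evaluate (matched against `lineage`).
#' @return list with `pairs` (data frame `copy_id`, `true_age`, `T`) and
#'   `spearman`.
#' @export
dating_benchmark <- function(ages, annotations, truth,
                             scopes = unique(truth$lineage)) {
  out <- list()
  for (g in scopes) {
    tr <- truth[truth$lineage == g, , drop = FALSE]
    ann <- annotations[annotations$genome_id == g, , drop = FALSE]
    m <- match_truth_copies(ann, tr)
    a <- ages[ages$scope == g & ages$qualified, , drop = FALSE]
    m$T <- a$T[match(m$copy_id, a$copy_id)]
    m$true_age <- tr$true_insertion_time[match(m$truth_id, tr$copy_id)]
    out[[g]] <- m[!is.na(m$T), c("copy_id", "true_age", "T")]
  }
  pairs <- do.call(rbind, out)
  list(pairs = pairs,
       spearman = if (nrow(pairs) > 2)
         stats::cor(pairs$true_age, pairs$T, method = "spearman")
       else NA_real_)
}

#' Compare family-average age estimates with true mean pairwise TMRCA
#'
#' The estimator (mean pairwise divergence / 2r) targets the mean pairwise
#' time to most recent common ancestry within the family, which
#' [true_tmrca_matrix()] computes from the simulated genealogy.
#'
#' @param family_ages the `family_ages` data frame from [date_copies()].
#' @param annotations concatenated overlap-resolved annotations.
#' @param truth the full truth table.
#' @param min_copies only families with at least this many annotated copies
#'   in a genome are evaluated.
#' @return data frame `family_id`, `genome`, `n_copies`, `true_age`,
#'   `estimated_age`, `rel_error`.
#' @export
family_age_benchmark <- function(family_ages, annotations, truth,
                                 min_copies = 10L) {
  rows <- list()
  for (g in unique(truth$lineage)) {
    ann <- annotations[annotations$genome_id == g, , drop = FALSE]
    for (f in unique(truth$family_id)) {
      n <- sum(ann$family_id == f)
      if (n < min_copies) next
      trf <- truth[truth$lineage == g & truth$family_id == f, , drop = FALSE]
      if (nrow(trf) < 2) next
      tm <- true_tmrca_matrix(trf)
      true_age <- mean(tm[upper.tri(tm)])
      fa <- family_ages[family_ages$scope == g &
                          family_ages$family_id == f, , drop = FALSE]
      if (!nrow(fa) || is.na(fa$average_insertion_time)) next
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = f, genome = g, n_copies = n, true_age = true_age,
        estimated_age = fa$average_insertion_time,
        rel_error = abs(fa$average_insertion_time - true_age) / true_age,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows) %||%
    data.frame(family_id = character(), genome = character(),
               n_copies = integer(), true_age = numeric(),
               estimated_age = numeric(), rel_error = numeric())
}

#' Brute-force best-score non-overlapping hit selection
#'
#' Exhaustive oracle for [resolve_overlaps()] on small instances: enumerates
#' all subsets of pairwise non-overlapping hits and returns the one with the
#' highest total score (ties broken toward the lexicographically first subset
#' by hit order).
#'
#' @param hits annotation data frame (at most ~15 rows).
#' @return the selected rows, sorted by contig and start.
#' @export
brute_force_selection <- function(hits) {
  n <- nrow(hits)
  stopifnot(n <= 15L)
  if (n == 0L) return(hits)
  overlaps <- function(i, j)
    hits$contig[i] == hits$contig[j] &&
      hits$start[i] < hits$end[j] && hits$start[j] < hits$end[i]
  best <- NULL; best_score <- -Inf
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    ok <- TRUE
    if (length(idx) > 1L)
      for (a in seq_along(idx)[-1]) for (b in seq_len(a - 1L))
        if (overlaps(idx[a], idx[b])) { ok <- FALSE; break }
    if (!ok) next
    sc <- sum(hits$score[idx])
    if (sc > best_score) { best_score <- sc; best <- idx }
  }
  out <- hits[best, , drop = FALSE]
  out[order(out$contig, out$start), , drop = FALSE]
}
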