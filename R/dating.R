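#' Build a consensus-anchored alignment stack for one family
#'
#' Projects every copy's pairwise alignment onto the consensus coordinate
#' system: each row has exactly one column per consensus position; copy bases
#' inserted relative to the consensus are dropped (counted per copy), and
#' positions a copy does not cover are gap characters.
#'
#' @param hits annotations of a single family (rows of the [scan_genome()]
#'   output, typically after [resolve_overlaps()]).
#' @param consensus_len length of the family consensus in bp.
#' @return a list with `mat` (character matrix, rows = copies, columns =
#'   consensus positions) and `insertions` (named integer vector of dropped
#'   inserted bases per copy).
#' @export
stack_family <- function(hits, consensus_len) {
  n <- nrow(hits)
  mat <- matrix("-", n, consensus_len,
                dimnames = list(hits$copy_id, NULL))
  ins <- setNames(integer(n), hits$copy_id)
  for (i in seq_len(n)) {
    cs <- strsplit(hits$aln_cons[i], "", fixed = TRUE)[[1]]
    cc <- strsplit(hits$aln_copy[i], "", fixed = TRUE)[[1]]
    keep <- cs != "-"
    pos <- hits$cons_start[i] - 1L + seq_len(sum(keep))
    if (any(pos > consensus_len))
      stop("alignment for ", hits$copy_id[i],
           " references consensus positions beyond consensus length")
    mat[i, pos] <- cc[keep]
    ins[i] <- sum(!keep)
  }
  list(mat = mat, insertions = ins)
}

#' Pairwise divergences within a family stack
#'
#' For every pair of rows sharing strictly more than `min_overlap` non-gap
#' columns, computes the p-distance (mismatches/overlap) and, under the JC
#' model, the Jukes-Cantor distance `K = -(3/4) ln(1 - (4/3) p)`. Pairs at or
#' below `min_overlap` shared columns are omitted; pairs with `p >= 0.75` are
#' flagged saturated and carry `K = NA`.
#'
#' @param stack result of [stack_family()] (or a bare character matrix).
#' @param model `"JC"` (default) or `"p"` for the uncorrected p-distance.
#' @param min_overlap overlap threshold in bp (strictly-greater rule;
#'   default 200).
#' @return data frame with `copy1`, `copy2`, `overlap`, `p`, `K`, `saturated`.
#' @export
pairwise_divergence <- function(stack, model = c("JC", "p"),
                                min_overlap = 200L) {
  model <- match.arg(model)
  mat <- if (is.list(stack)) stack$mat else stack
  if (nrow(mat) < 2L)
    return(data.frame(copy1 = character(), copy2 = character(),
                      overlap = integer(), p = numeric(), K = numeric(),
                      saturated = logical(), stringsAsFactors = FALSE))
  code <- matrix(match(mat, BASES, nomatch = 0L), nrow = nrow(mat))
  cover <- (code > 0L) * 1
  ov <- tcrossprod(cover)
  matches <- Reduce(`+`, lapply(1:4, function(b) tcrossprod((code == b) * 1)))
  idx <- which(upper.tri(ov) & ov > min_overlap, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(copy1 = character(), copy2 = character(),
                      overlap = integer(), p = numeric(), K = numeric(),
                      saturated = logical(), stringsAsFactors = FALSE))
  overlap <- ov[idx]
  p <- 1 - matches[idx] / overlap
  saturated <- model == "JC" & p >= 0.75
  K <- switch(model,
              p = p,
              JC = ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_))
  ids <- rownames(mat)
  data.frame(copy1 = ids[idx[, 1L]], copy2 = ids[idx[, 2L]],
             overlap = as.integer(overlap), p = p, K = K,
             saturated = saturated, stringsAsFactors = FALSE)
}

#' Per-copy insertion-time estimates by nearest neighbour
#'
#' Each copy is dated by its closest qualified relative: the family member with
#' the lowest divergence `K` among pairs with sufficient overlap, via
#' `T = K / (2 r)`. Ties are broken deterministically by the smaller partner
#' copy id. Copies with no qualified pair get `qualified = FALSE` and an
#' undefined `T`; they are excluded from age distributions.
#'
#' @param divergences output of [pairwise_divergence()] (saturated pairs are
#'   not qualified).
#' @param r substitution rate in substitutions/site/Myr (> 0).
#' @param copy_ids ids of all copies to report (defaults to those occurring in
#'   `divergences`).
#' @return data frame with `copy_id`, `nearest_neighbor_id`, `K`, `overlap`,
#'   `T`, `r_used`, `qualified`.
#' @export
element_age <- function(divergences, r, copy_ids = NULL) {
  if (r <= 0) stop("substitution rate r must be positive")
  if (is.null(copy_ids))
    copy_ids <- sort(unique(c(divergences$copy1, divergences$copy2)))
  qual <- divergences[!divergences$saturated & !is.na(divergences$K), ,
                      drop = FALSE]
  # symmetric long form
  long <- rbind(
    data.frame(copy_id = qual$copy1, partner = qual$copy2, K = qual$K,
               overlap = qual$overlap, stringsAsFactors = FALSE),
    data.frame(copy_id = qual$copy2, partner = qual$copy1, K = qual$K,
               overlap = qual$overlap, stringsAsFactors = FALSE))
  out <- data.frame(copy_id = copy_ids, nearest_neighbor_id = NA_character_,
                    K = NA_real_, overlap = NA_integer_, T = NA_real_,
                    r_used = r, qualified = FALSE, stringsAsFactors = FALSE)
  if (nrow(long)) {
    long <- long[order(long$copy_id, long$K, long$partner), , drop = FALSE]
    best <- long[!duplicated(long$copy_id), , drop = FALSE]
    m <- match(best$copy_id, out$copy_id)
    ok <- !is.na(m)
    out$nearest_neighbor_id[m[ok]] <- best$partner[ok]
    out$K[m[ok]] <- best$K[ok]
    out$overlap[m[ok]] <- best$overlap[ok]
    out$T[m[ok]] <- best$K[ok] / (2 * r)
    out$qualified[m[ok]] <- TRUE
  }
  out
}

#' Family-average insertion time
#'
#' The average insertion time of a family is the mean divergence over all
#' qualified pairs in scope, divided by `2 r`.
#'
#' @param divergences output of [pairwise_divergence()].
#' @param r substitution rate (> 0).
#' @param family_id,scope labels carried into the result (`scope` is typically
#'   `"both"`, `"A"` or `"B"`).
#' @return one-row data frame with `family_id`, `scope`, `mean_pairwise_K`,
#'   `average_insertion_time`, `n_pairs`; the time is `NA` (family flagged)
#'   when no qualified pair exists.
#' @export
family_average_age <- function(divergences, r, family_id = NA_character_,
                               scope = "both") {
  if (r <= 0) stop("substitution rate r must be positive")
  qual <- divergences[!divergences$saturated & !is.na(divergences$K), ,
                      drop = FALSE]
  if (!nrow(qual))
    return(data.frame(family_id = family_id, scope = scope,
                      mean_pairwise_K = NA_real_,
                      average_insertion_time = NA_real_, n_pairs = 0L,
                      stringsAsFactors = FALSE))
  mk <- mean(qual$K)
  data.frame(family_id = family_id, scope = scope, mean_pairwise_K = mk,
             average_insertion_time = mk / (2 * r), n_pairs = nrow(qual),
             stringsAsFactors = FALSE)
}

#' Export a family distance matrix in PHYLIP square format
#'
#' Members whose stack row covers more than 200 non-gap positions are
#' included; pairs without a qualified divergence are encoded as -1 (missing).
#' Families with fewer than three eligible members are skipped with a message.
#'
#' @param stack result of [stack_family()].
#' @param divergences output of [pairwise_divergence()] on the same stack.
#' @param file output path.
#' @param min_member_len minimum non-gap row length (default 200, strict).
#' @return invisibly, the matrix written (or `NULL` if skipped).
#' @export
export_distance_matrix <- function(stack, divergences, file,
                                   min_member_len = 200L) {
  mat <- if (is.list(stack)) stack$mat else stack
  rowlen <- rowSums(matrix(mat %in% BASES, nrow = nrow(mat)))
  eligible <- rownames(mat)[rowlen > min_member_len]
  if (length(eligible) < 3L) {
    message("fewer than 3 members exceed ", min_member_len,
            " bp; distance matrix not written")
    return(invisible(NULL))
  }
  n <- length(eligible)
  d <- matrix(-1, n, n, dimnames = list(eligible, eligible))
  diag(d) <- 0
  qual <- divergences[!divergences$saturated & !is.na(divergences$K), ,
                      drop = FALSE]
  for (i in seq_len(nrow(qual))) {
    a <- qual$copy1[i]; b <- qual$copy2[i]
    if (a %in% eligible && b %in% eligible)
      d[a, b] <- d[b, a] <- qual$K[i]
  }
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i)
               paste0(sprintf("%-10s", substr(eligible[i], 1L, 10L)),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  ")), ""))
  writeLines(lines, file)
  invisible(d)
}

#' Date every copy in two annotated genomes
#'
#' Convenience wrapper: builds per-family stacks over the requested scope,
#' computes pairwise divergences, nearest-neighbour copy ages and family
#' averages. Per-genome scopes restrict nearest neighbours to same-genome
#' members; the `"both"` scope allows cross-genome partners.
#'
#' @param annotations annotation data frame (both genomes concatenated, or
#'   one).
#' @param library the `te_library`.
#' @param r substitution rate in substitutions/site/Myr.
#' @param model divergence model, see [pairwise_divergence()].
#' @param min_overlap qualification threshold in bp (strictly greater).
#' @param scopes which stacks to build, a subset of the genome ids plus
#'   `"both"`.
#' @return list with `ages` (per-copy estimates across scopes, with `scope`
#'   column) and `family_ages`.
#' @export
date_copies <- function(annotations, library, r = 0.015, model = "JC",
                        min_overlap = 200L,
                        scopes = c(unique(annotations$genome_id), "both")) {
  ages <- list(); fam_ages <- list()
  for (scope in scopes) {
    sub <- if (scope == "both") annotations
           else annotations[annotations$genome_id == scope, , drop = FALSE]
    for (f in unique(sub$family_id)) {
      hits <- sub[sub$family_id == f, , drop = FALSE]
      cl <- nchar(library$consensus[match(f, library$family_id)])
      st <- stack_family(hits, cl)
      dv <- pairwise_divergence(st, model = model, min_overlap = min_overlap)
      ea <- element_age(dv, r, copy_ids = hits$copy_id)
      ea$family_id <- f
      ea$scope <- scope
      ages[[length(ages) + 1L]] <- ea
      fa <- family_average_age(dv, r, family_id = f, scope = scope)
      fam_ages[[length(fam_ages) + 1L]] <- fa
    }
  }
  list(ages = do.call(rbind, ages), family_ages = do.call(rbind, fam_ages))
}
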