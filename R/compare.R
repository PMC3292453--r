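#' Per-family summaries across two genomes
#'
#' One row per library family: copy counts and densities in each genome,
#' shared/unique/absent status, and (optionally) average insertion ages.
#'
#' @param annotations_a,annotations_b overlap-resolved annotations of the two
#'   genomes.
#' @param library the `te_library`.
#' @param genome_len_a,genome_len_b assembly lengths in bp.
#' @param family_ages optional `family_ages` data frame from [date_copies()]
#'   (scopes named as the two genome ids and `"both"`).
#' @param genome_ids the two genome ids, in (A, B) order.
#' @return a `family_summary` data frame.
#' @export
family_summaries <- function(annotations_a, annotations_b, library,
                             genome_len_a, genome_len_b, family_ages = NULL,
                             genome_ids = c("A", "B")) {
  cnt_a <- table(factor(annotations_a$family_id, levels = library$family_id))
  cnt_b <- table(factor(annotations_b$family_id, levels = library$family_id))
  status <- ifelse(cnt_a > 0 & cnt_b > 0, "shared",
            ifelse(cnt_a > 0, "unique_A", ifelse(cnt_b > 0, "unique_B",
                                                 "absent")))
  out <- data.frame(family_id = library$family_id,
                    te_class = library$te_class,
                    count_A = as.integer(cnt_a), count_B = as.integer(cnt_b),
                    density_A = density_normalize(as.integer(cnt_a), genome_len_a),
                    density_B = density_normalize(as.integer(cnt_b), genome_len_b),
                    status = status, avg_age_A = NA_real_,
                    avg_age_B = NA_real_, avg_age_both = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(family_ages)) {
    pick <- function(scope) {
      fa <- family_ages[family_ages$scope == scope, , drop = FALSE]
      fa$average_insertion_time[match(out$family_id, fa$family_id)]
    }
    out$avg_age_A <- pick(genome_ids[1])
    out$avg_age_B <- pick(genome_ids[2])
    out$avg_age_both <- pick("both")
  }
  class(out) <- c("family_summary", "data.frame")
  out
}

#' Partition families by presence status
#'
#' @param summaries a `family_summary` data frame (one row per library
#'   family).
#' @return named integer vector with counts of `shared`, `unique_A`,
#'   `unique_B`, `absent` families plus `total`; totals sum to the library
#'   size.
#' @export
partition_families <- function(summaries) {
  if (anyDuplicated(summaries$family_id))
    stop("duplicate family_id in summaries")
  lv <- c("shared", "unique_A", "unique_B", "absent")
  cnt <- table(factor(summaries$status, levels = lv))
  c(setNames(as.integer(cnt), lv), total = nrow(summaries))
}

#' Copy-number table per genome
#'
#' Per scope (one TE class or all families): total copies, mean copies per
#' family over families with at least one copy in that genome, and the maximum
#' family size.
#'
#' @param summaries a `family_summary` data frame.
#' @param scope `"all"` or one of the TE classes.
#' @return data frame with one row per genome: `genome`, `total_copies`,
#'   `mean_copies_per_family`, `max_family_size`, `n_families_present`.
#' @export
copy_number_table <- function(summaries, scope = "all") {
  sub <- if (identical(scope, "all")) summaries
         else summaries[summaries$te_class == scope, , drop = FALSE]
  one <- function(genome, counts) {
    present <- counts[counts > 0]
    data.frame(genome = genome, scope = scope,
               total_copies = sum(counts),
               mean_copies_per_family = if (length(present)) mean(present)
                                        else NA_real_,
               max_family_size = if (length(present)) max(present) else 0L,
               n_families_present = length(present),
               stringsAsFactors = FALSE)
  }
  rbind(one("A", sub$count_A), one("B", sub$count_B))
}

#' Wilcoxon rank-sum comparison of two copy-number samples
#'
#' Rank-sum test with midranks for ties. In `"exact"` mode (the default when
#' the pooled size is at most 20 and there are no ties) the p-value is exact;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. Two-sided.
#'
#' @param x,y numeric samples (e.g. per-family copy counts in each genome).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list with `statistic` (rank-sum W as in [stats::wilcox.test()]),
#'   `p_two_sided`, and `mode_used`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 1, length(y) >= 1)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all pooled values identical; p = 1 by convention")
    return(list(statistic = sum(rank(pooled)[seq_along(x)]) -
                  length(x) * (length(x) + 1) / 2,
                p_two_sided = 1, mode_used = "degenerate"))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- switch(mode,
                  exact = TRUE,
                  normal = FALSE,
                  auto = (length(pooled) <= 20L) && !ties)
  if (exact && ties) exact <- FALSE  # exact enumeration is undefined with ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_two_sided = wt$p.value,
       mode_used = if (exact) "exact" else "normal")
}

#' Copies per million base pairs
#'
#' @param count copy count (vectorised).
#' @param genome_len_bp assembly length in bp (> 0).
#' @return `count * 1e6 / genome_len_bp`.
#' @export
density_normalize <- function(count, genome_len_bp) {
  if (any(genome_len_bp <= 0)) stop("genome length must be positive")
  count * 1e6 / genome_len_bp
}
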