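#' Pipeline configuration: the single source of truth for all thresholds
#'
#' Aggregates the stage configurations plus the global constants every module
#' reads from here: the substitution rate `r`, the 100-bp minimum copy length,
#' the 200-bp overlap rule, and the conservative-library switch (minimum
#' consensus length 2000 bp).
#'
#' @param sim a [sim_config()].
#' @param discovery a [discovery_config()].
#' @param annotate an [annotate_config()].
#' @param r substitution rate in substitutions/site/Myr.
#' @param min_overlap_bp pairwise-overlap qualification threshold (strictly
#'   greater).
#' @param bin_width age histogram bin width (Myr).
#' @param drop_window tested window for the recent-insertion deficit (Myr).
#' @param conservative_mode if `TRUE`, de novo families must be >= 2000 bp.
#' @param library_mode `"de_novo"` (discover families from the simulated
#'   genomes), `"true"` (annotate with the simulator's family set), or
#'   `"combined"` (de novo discovery merged against the true set as the known
#'   library).
#' @param seed overrides `sim$seed` when not `NULL`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            discovery = discovery_config(),
                            annotate = annotate_config(),
                            r = 0.015, min_overlap_bp = 200L,
                            bin_width = 0.25, drop_window = c(0, 0.5),
                            conservative_mode = FALSE,
                            library_mode = c("de_novo", "true", "combined"),
                            seed = NULL) {
  library_mode <- match.arg(library_mode)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  if (conservative_mode) discovery$min_consensus_len <- 2000L
  stopifnot(r > 0, min_overlap_bp >= 0)
  structure(list(sim = sim, discovery = discovery, annotate = annotate,
                 r = r, min_overlap_bp = as.integer(min_overlap_bp),
                 bin_width = bin_width, drop_window = drop_window,
                 conservative_mode = conservative_mode,
                 library_mode = library_mode, seed = sim$seed),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline end to end
#'
#' simulate -> discover -> annotate -> date -> compare -> agedist, writing
#' every intermediate into `output_dir` and a manifest recording the package
#' version, seed, configuration hash and the md5 checksum of every output
#' file. Any stage error aborts with the stage name; outputs of completed
#' stages are retained.
#'
#' @param cfg a [pipeline_config()].
#' @param output_dir directory for outputs (created if needed).
#' @param genomes optionally a list with `genomeA`, `genomeB`
#'   ([Biostrings::DNAStringSet]) and (optionally) `truth`, to run the
#'   analysis on externally supplied genomes instead of simulating.
#' @return invisibly, a result bundle: `library`, `annotations`, `dating`,
#'   `summaries`, `partition`, `age_analysis`, `truth`, `manifest`.
#' @export
run_all <- function(cfg, output_dir, genomes = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(writer, obj, name, ...) {
    path <- file.path(output_dir, name)
    writer(obj, path, ...)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # -- simulate ---------------------------------------------------------------
  truth <- NULL
  families <- NULL
  if (is.null(genomes)) {
    sim <- stage("simulate", {
      families <- build_family_set(cfg$sim)
      simulate_two_lineages(families, cfg$sim)
    })
    truth <- sim$truth
    genomes <- list(genomeA = sim$genomeA, genomeB = sim$genomeB)
    emit(write_fasta, genomes$genomeA, "genomeA.fasta")
    emit(write_fasta, genomes$genomeB, "genomeB.fasta")
    emit(write_truth, truth, "truth.tsv")
    emit(write_bed, data.frame(contig = truth$contig, start = truth$start,
                               end = truth$end, strand = truth$strand,
                               copy_id = truth$copy_id, score = 0),
         "truth.bed")
  } else {
    truth <- genomes$truth
  }

  # -- discover ---------------------------------------------------------------
  disc <- stage("discover", {
    if (cfg$library_mode == "true") {
      if (is.null(families)) stop("library_mode 'true' requires simulation")
      list(library = families,
           filter_log = data.frame(candidate_id = character(),
                                   reason = character()))
    } else {
      known <- if (cfg$library_mode == "combined") families else NULL
      discover_families(c(genomes$genomeA, genomes$genomeB), cfg$discovery,
                        known = known)
    }
  })
  lib <- disc$library
  if (!nrow(lib)) stop("stage 'discover' produced an empty library")
  emit(write_library_fasta, lib, "library.fasta")
  emit(function(x, f) data.table::fwrite(x, f, sep = "\t"), disc$filter_log,
       "filter_log.tsv")

  # -- annotate ---------------------------------------------------------------
  ann <- stage("annotate", {
    lapply(c(A = "A", B = "B"), function(g) {
      resolve_overlaps(scan_genome(genomes[[paste0("genome", g)]], lib,
                                   cfg$annotate, genome_id = g))
    })
  })
  for (g in c("A", "B")) {
    emit(write_rm_out, ann[[g]], paste0("annotations_", g, ".out"),
         library = lib)
    emit(write_gff3, ann[[g]], paste0("annotations_", g, ".gff3"),
         library = lib)
    emit(write_bed, ann[[g]], paste0("annotations_", g, ".bed"))
    emit(write_alignments, ann[[g]], paste0("alignments_", g, ".txt"))
  }
  annotations <- rbind(ann$A, ann$B)

  # -- date -------------------------------------------------------------------
  dating <- stage("date", date_copies(annotations, lib, r = cfg$r,
                                      min_overlap = cfg$min_overlap_bp))
  emit(function(x, f) data.table::fwrite(x, f, sep = "\t"), dating$ages,
       "copy_ages.tsv")
  emit(function(x, f) data.table::fwrite(x, f, sep = "\t"),
       dating$family_ages, "family_ages.tsv")
  stage("date", {
    dist_dir <- file.path(output_dir, "dist")
    dir.create(dist_dir, showWarnings = FALSE)
    for (f in unique(annotations$family_id)) {
      hits <- annotations[annotations$family_id == f, , drop = FALSE]
      if (nrow(hits) < 3L) next
      cl <- nchar(lib$consensus[match(f, lib$family_id)])
      st <- stack_family(hits, cl)
      dv <- pairwise_divergence(st, min_overlap = cfg$min_overlap_bp)
      path <- file.path(dist_dir, paste0(f, ".dist"))
      res <- suppressMessages(export_distance_matrix(st, dv, path))
      if (!is.null(res)) outputs <- c(outputs, path)
    }
  })

  # -- compare ----------------------------------------------------------------
  cmp <- stage("compare", {
    lenA <- sum(Biostrings::width(genomes$genomeA))
    lenB <- sum(Biostrings::width(genomes$genomeB))
    summaries <- family_summaries(ann$A, ann$B, lib, lenA, lenB,
                                  family_ages = dating$family_ages,
                                  genome_ids = c("A", "B"))
    present <- summaries[summaries$count_A > 0 | summaries$count_B > 0, ]
    wx <- wilcoxon_rank_sum(present$count_A, present$count_B)
    list(summaries = summaries, partition = partition_families(summaries),
         table_all = copy_number_table(summaries),
         wilcoxon = wx)
  })
  emit(function(x, f) data.table::fwrite(x, f, sep = "\t"),
       as.data.frame(cmp$summaries), "family_summaries.tsv")
  emit(function(x, f) data.table::fwrite(data.frame(
    status = names(x), n = as.integer(x)), f, sep = "\t"),
    cmp$partition, "family_partition.tsv")

  # -- agedist ----------------------------------------------------------------
  aged <- stage("agedist", {
    per_genome <- lapply(c(A = "A", B = "B"), function(g) {
      a <- dating$ages
      ages <- a$T[a$scope == g & a$qualified]
      dist <- build_age_distribution(ages, bin_width = cfg$bin_width,
                                     scope = "all", genome_id = g)
      fit <- tryCatch(fit_exponential(ages), error = function(e) NULL)
      drop <- tryCatch(detect_drop(ages, window = cfg$drop_window),
                       error = function(e) NULL)
      list(ages = ages, dist = dist, fit = fit, drop = drop)
    })
    per_genome
  })
  for (g in c("A", "B")) {
    emit(function(x, f) data.table::fwrite(x, f, sep = "\t"),
         aged[[g]]$dist$bins, paste0("age_distribution_", g, ".tsv"))
    if (!is.null(aged[[g]]$fit))
      emit(function(x, f) data.table::fwrite(data.frame(
        genome = g, rate_lambda = x$rate_lambda, half_life = x$half_life,
        n_used = x$n_used), f, sep = "\t"), aged[[g]]$fit,
        paste0("exp_fit_", g, ".tsv"))
    if (!is.null(aged[[g]]$drop))
      emit(function(x, f) data.table::fwrite(data.frame(
        genome = g, window_lo = x$window[1], window_hi = x$window[2],
        observed = x$observed, expected = x$expected, ratio = x$ratio,
        ci_lo = x$poisson_interval[1], ci_hi = x$poisson_interval[2],
        drop = x$drop, low_power = x$low_power), f, sep = "\t"),
        aged[[g]]$drop, paste0("drop_report_", g, ".tsv"))
  }

  # -- manifest ---------------------------------------------------------------
  manifest <- list(
    package = "tedyn",
    version = as.character(utils::packageVersion("tedyn")),
    seed = cfg$seed,
    config_md5 = config_hash(cfg),
    n_families_library = nrow(lib),
    n_copies = c(A = nrow(ann$A), B = nrow(ann$B)),
    files = as.list(setNames(unname(tools::md5sum(sort(unique(outputs)))),
                             basename(sort(unique(outputs))))))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(library = lib, annotations = ann, dating = dating,
                 summaries = cmp$summaries, partition = cmp$partition,
                 wilcoxon = cmp$wilcoxon, age_analysis = aged, truth = truth,
                 manifest = manifest))
}
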