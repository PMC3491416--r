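#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis with their default
#' values: 300-bp windows at 150-bp stride and a 10 % edge rule for
#' tiling, a minimum window sum of 5 tags, strict FDR and loose p
#' thresholds of 0.05, gamma-tail peak threshold at P < 0.05, 60-bp kernel
#' bandwidth, 2-kb promoters, a 20-kb association window, 100,000 forward
#' and 1,000 reverse permutations, a 90th-percentile motif-score cutoff,
#' 15-bp footprint half-width, 100-bp aggregate flank, and k = 3 with 100
#' k-means restarts.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param out_dir Output directory for result tables.
#' @param ... Named overrides of any default.
#' @return A named list of parameters.
#' @export
default_config <- function(seed = 1L, out_dir = "results/pipeline", ...) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    W = 300L, step = 150L, edge_frac = 0.10, min_sum = 5L,
    strict_fdr = 0.05, loose_p = 0.05,
    gamma_p = 0.05, bandwidth = 60, min_gap = 50L,
    de_fdr = 0.05,
    promoter = 2000L, assoc_window = 20000L,
    n_perm_forward = 100000L, n_perm_reverse = 1000L,
    percentile = 90, half = 15L, flank = 100L,
    k = 3L, runs = 100L, k_range = 2:5, row_normalize = TRUE,
    scenario = NULL,
    pwm_path = system.file("extdata", "ar_like_synthetic.jaspar",
                           package = "deltadnase")
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  cfg
}

#' Emulated receptor-bound peaks of a scenario
#'
#' The DHS regions of a scenario that contain at least one planted motif
#' site — the synthetic stand-in for an externally supplied ChIP peak BED.
#'
#' @param scenario A `sim_scenario`.
#' @return Interval `data.frame`.
#' @export
scenario_ar_peaks <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  d <- scenario$dhs
  if (nrow(d) == 0L || nrow(scenario$motif_sites) == 0L) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  keep <- IRanges::overlapsAny(
    as_granges(d[, c("chrom", "start", "end")]),
    as_granges(scenario$motif_sites[, c("chrom", "start", "end")])
  )
  out <- d[keep, c("chrom", "start", "end", "name"), drop = FALSE]
  rownames(out) <- NULL
  validate_intervals(out)
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a (simulated) study
#'
#' Executes simulate -> peak calling -> differential accessibility ->
#' differential expression -> region--gene association -> motif scan ->
#' footprint clustering, writing all result tables (TSV/BED) plus a
#' machine-readable `summary.json` into `config$out_dir`. Rerunning with
#' the same configuration reproduces every output byte for byte.
#'
#' @param config Configuration list from [default_config()].
#' @return (Invisibly) a list with all in-memory stage results and the
#'   summary.
#' @export
run_pipeline <- function(config = default_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      dd_stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  ## simulate
  sim <- stage("simulate", {
    scenario <- config$scenario
    if (is.null(scenario)) scenario <- build_scenario(seed = config$seed)
    pwm <- read_jaspar_pwm(config$pwm_path, pseudocount = 1)
    profiles <- simulate_all_cuts(scenario)
    seqs <- simulate_sequence(scenario, pwm)
    expr_cm <- simulate_expression(scenario)
    write_bed(scenario$dhs[, c("chrom", "start", "end", "name")],
              file.path(config$out_dir, "truth_dhs.bed"))
    if (nrow(scenario$delta)) {
      write_bed(scenario$delta[, c("chrom", "start", "end", "name")],
                file.path(config$out_dir, "truth_delta.bed"))
    }
    ar_peaks <- scenario_ar_peaks(scenario)
    if (nrow(ar_peaks)) {
      write_bed(ar_peaks, file.path(config$out_dir, "ar_peaks_synthetic.bed"))
    }
    list(scenario = scenario, pwm = pwm, profiles = profiles, seqs = seqs,
         expr_cm = expr_cm, ar_peaks = ar_peaks)
  })
  conds <- vapply(sim$profiles, function(p) p$condition, "")

  ## peaks (replicates pooled per condition)
  peaks <- stage("callpeaks", {
    out <- list()
    for (cond in c("untreated", "induced")) {
      pooled <- pool_profiles(sim$profiles[conds == cond])
      res <- call_dhs(pooled, bandwidth = config$bandwidth,
                      p = config$gamma_p, min_gap = config$min_gap)
      res$pooled <- pooled
      write_peaks_bed(res$peaks,
                      file.path(config$out_dir,
                                sprintf("peaks_%s.bed", cond)))
      out[[cond]] <- res
    }
    out$overlap <- overlap_fraction(out$untreated$peaks, out$induced$peaks)
    out
  })

  ## differential accessibility
  delta <- stage("delta", {
    union <- union_regions(peaks$untreated$peaks, peaks$induced$peaks)
    write_bed(union, file.path(config$out_dir, "union_dhs.bed"))
    windows <- tile_regions(union, W = config$W, default_step = config$step,
                            edge_frac = config$edge_frac)
    cm <- count_and_filter(windows, sim$profiles, min_sum = config$min_sum)
    res <- nb_exact_test(cm)
    write_tsv(res$table, file.path(config$out_dir, "window_diff.tsv"))
    sets <- classify_and_merge(res, strict_fdr = config$strict_fdr,
                               loose_p = config$loose_p)
    for (nm in c("strict_increase", "loose_increase",
                 "strict_decrease", "loose_decrease")) {
      if (nrow(sets[[nm]])) {
        write_bed(sets[[nm]][, c("chrom", "start", "end", "name")],
                  file.path(config$out_dir, sprintf("delta_%s.bed", nm)))
      }
    }
    union$diff_score <- normalized_differential_score(union, sim$profiles)
    write_tsv(union[, c("chrom", "start", "end", "name", "diff_score")],
              file.path(config$out_dir, "union_diff_score.tsv"))
    list(union = union, windows = windows, cm = cm, result = res,
         sets = sets)
  })

  ## differential expression
  expr <- stage("express", {
    de <- de_genes(sim$expr_cm, fdr = config$de_fdr)
    tab <- de$result$table
    eff_len <- exonic_length(sim$scenario$genes, exclude_utr3 = TRUE)
    rpkm_mat <- sapply(seq_len(ncol(sim$expr_cm$counts)), function(j) {
      rpkm(sim$expr_cm$counts[, j], eff_len[tab$gene_id],
           max(sim$expr_cm$lib_sizes[j], 1))
    })
    colnames(rpkm_mat) <- colnames(sim$expr_cm$counts)
    write_tsv(cbind(tab, round(rpkm_mat, 3)),
              file.path(config$out_dir, "expression_diff.tsv"))
    de
  })

  ## region--gene association
  assoc <- stage("associate", {
    genes <- sim$scenario$genes
    universe <- genes$genes$gene_id
    regions <- delta$sets$loose_increase
    ann_union <- annotate_regions(delta$union, genes,
                                  promoter = config$promoter)
    ann_delta <- annotate_regions(regions, genes, promoter = config$promoter)
    fwd <- rev <- NULL
    if (nrow(regions) && length(expr$up)) {
      ng <- nearest_gene(regions, genes)
      fwd <- permutation_enrichment(unique(ng$gene_id), expr$up, universe,
                                    N = config$n_perm_forward,
                                    seed = config$seed)
      rev <- reverse_association(expr$up, regions, genes,
                                 window = config$assoc_window,
                                 N = config$n_perm_reverse,
                                 seed = config$seed)
    }
    list(ann_union = ann_union, ann_delta = ann_delta,
         forward = fwd, reverse = rev)
  })

  ## motif scan + relative enrichment
  motif <- stage("scan", {
    matches <- scan_sequence(sim$seqs, sim$pwm,
                             percentile = config$percentile,
                             mask = delta$union)
    out_m <- matches
    out_m$score <- round(out_m$score * 100)
    if (nrow(out_m)) {
      write_bed(out_m, file.path(config$out_dir, "motif_matches.bed"))
    }
    enr <- NULL
    if (nrow(delta$sets$loose_increase)) {
      other <- delta$union[!IRanges::overlapsAny(
        as_granges(delta$union[, c("chrom", "start", "end")]),
        as_granges(delta$sets$loose_increase[, c("chrom", "start", "end")])
      ), , drop = FALSE]
      if (nrow(other)) {
        enr <- relative_enrichment(matches, delta$sets$loose_increase, other)
      }
    }
    list(matches = matches, enrichment = enr)
  })

  ## footprints
  foot <- stage("footprint", {
    ar_dhs <- peaks$induced$peaks
    if (nrow(sim$ar_peaks)) {
      keep <- IRanges::overlapsAny(
        as_granges(ar_dhs[, c("chrom", "start", "end")]),
        as_granges(sim$ar_peaks[, c("chrom", "start", "end")])
      )
      ar_dhs <- ar_dhs[keep, , drop = FALSE]
    }
    sites <- best_match_per_region(motif$matches, ar_dhs)
    res <- list(sites = sites)
    if (nrow(sites) > max(config$k_range)) {
      for (cond in c("untreated", "induced")) {
        fm <- suppressWarnings(
          footprint_matrix(peaks[[cond]]$pooled, sites, half = config$half)
        )
        agg <- aggregate_profile(peaks[[cond]]$pooled, sites,
                                 flank = config$flank)
        write_tsv(data.frame(position = seq_along(agg) -
                               (config$flank + (config$half + 1L)),
                             cuts = agg),
                  file.path(config$out_dir,
                            sprintf("aggregate_profile_%s.tsv", cond)))
        res[[cond]] <- list(
          matrix = fm,
          stability = kmeans_stability(fm, k = config$k,
                                       runs = config$runs,
                                       seed = derive_seed(config$seed, cond),
                                       row_normalize = config$row_normalize)
        )
      }
      res$comparison <- compare_stability(res$induced$stability,
                                          res$untreated$stability,
                                          "induced", "untreated")
      res$k_selection <- select_k(res$induced$matrix,
                                  k_range = config$k_range,
                                  runs = config$runs, seed = config$seed,
                                  row_normalize = config$row_normalize)
      centers <- consensus_centers(res$induced$stability)
      write_tsv(as.data.frame(centers),
                file.path(config$out_dir, "footprint_centers_consensus.tsv"))
    }
    res
  })

  ## summary
  summary <- list(
    seed = config$seed,
    parameters = config[setdiff(names(config), c("scenario", "out_dir"))],
    n_peaks = list(untreated = nrow(peaks$untreated$peaks),
                   induced = nrow(peaks$induced$peaks)),
    peak_thresholds = list(untreated = peaks$untreated$threshold,
                           induced = peaks$induced$threshold),
    peak_overlap = peaks$overlap[c("frac_a", "frac_b")],
    n_union = nrow(delta$union),
    n_windows = nrow(delta$windows),
    n_windows_tested = nrow(delta$cm$counts),
    dispersion = delta$result$dispersion,
    n_delta = list(strict_increase = nrow(delta$sets$strict_increase),
                   loose_increase = nrow(delta$sets$loose_increase),
                   strict_decrease = nrow(delta$sets$strict_decrease),
                   loose_decrease = nrow(delta$sets$loose_decrease)),
    n_de = list(up = length(expr$up), down = length(expr$down)),
    association = list(
      forward_p_enrich = if (!is.null(assoc$forward)) assoc$forward$p_enrich,
      reverse_p_enrich = if (!is.null(assoc$reverse)) assoc$reverse$p_enrich
    ),
    n_motif_matches = nrow(motif$matches),
    motif_enrichment = if (!is.null(motif$enrichment))
      motif$enrichment$score,
    n_footprint_sites = nrow(foot$sites),
    footprint = if (!is.null(foot$comparison)) list(
      stability_p = foot$comparison$p_value,
      higher = foot$comparison$higher,
      median_induced = foot$comparison$median_a,
      median_untreated = foot$comparison$median_b,
      recommended_k = foot$k_selection$recommended_k
    )
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(config = config, sim = sim, peaks = peaks, delta = delta,
                 expression = expr, association = assoc, motif = motif,
                 footprint = foot, summary = summary))
}
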