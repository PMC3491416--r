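#' Footprint protection templates
#'
#' Length-31 vectors of per-base protection multipliers in `[0, 1]` applied
#' to the local cut rate at a bound motif, encoding the three footprint
#' shapes left by a palindromic dimer factor on its recognition element:
#' protection of the left half-site only, of the right half-site only
#' (the mirror image of the left), or of the full site with an unprotected
#' central spike over the degenerate 3-bp spacer between the two monomers.
#'
#' When cuts are simulated ([scenario_rates()]), the template is rescaled
#' to mean 1 (`t / mean(t)`) so that cleavage displaced from protected
#' bases accumulates on the exposed bases of the same site and binding
#' leaves the site's total cut rate unchanged; the rescaling is affine, so
#' the protection pattern (and any correlation with it) is preserved.
#'
#' @param protection Multiplier inside protected stretches (default 0.15;
#'   1 = no protection).
#' @return Named list of three numeric length-31 vectors: `left_half`,
#'   `right_half`, `full_dimer`.
#' @export
footprint_templates <- function(protection = 0.15) {
  stopifnot(protection >= 0, protection <= 1)
  left <- rep(1, 31); left[1:14] <- protection
  right <- rev(left)
  full <- rep(1, 31); full[c(1:14, 18:31)] <- protection
  list(left_half = left, right_half = right, full_dimer = full)
}

#' Build a synthetic study scenario
#'
#' Lays out, deterministically given `seed`, a small genome with
#' hypersensitive (DHS) regions on a low background, condition-specific
#' accessibility changes planted in a subset of DHS, motif sites carrying
#' the three footprint templates, and gene models whose differentially
#' expressed (DE) members sit near planted accessibility increases (so the
#' region--gene association holds by construction). Cut rates are per base
#' pair per replicate: a DHS has rate `lambda_bg * dhs_multiplier`.
#'
#' @param L Genome (single chromosome) length in bp.
#' @param chrom Chromosome name.
#' @param lambda_bg Background cut rate (cuts/bp/replicate).
#' @param n_dhs Number of DHS regions (widths drawn in `dhs_width`).
#'   When 0, all planted features are cleared and the scenario is
#'   background-only.
#' @param dhs_width Length-2 range of DHS widths (bp).
#' @param dhs_multiplier Rate multiplier inside a DHS (default 32, i.e.
#'   0.32 cuts/bp/replicate at the default background: roughly 30 pooled
#'   cuts per 31-bp footprint vector over three replicates, and roughly
#'   100 tags per 300-bp window per replicate).
#' @param n_increase,n_decrease Number of DHS planted with an induced-only
#'   fold-change.
#' @param fold,decrease_fold Induced/untreated rate ratio in planted
#'   increase (>1) and decrease (<1) regions.
#' @param sites_per_template Motif sites planted per footprint template.
#' @param sites_per_dhs Maximum motif sites per bound DHS (default 2,
#'   evenly spaced).
#' @param motif_width Width of each motif site (bp).
#' @param n_genes,n_de Total genes and DE genes (DE genes are placed with
#'   their TSS within 2 kb of distinct planted increases).
#' @param de_fold Expression fold-change of DE genes upon induction.
#' @param n_rep Named integer vector `c(untreated=, induced=)`.
#' @param phi Negative-binomial dispersion of per-base cut counts
#'   (0 = Poisson).
#' @param phi_region Biological replicate variability of region
#'   accessibility (default 0.1): each replicate draws an independent
#'   mean-1 gamma factor with this variance for every DHS, shared by all
#'   bases of the region. Region-level variability is what makes window
#'   tag counts overdispersed across biological replicates (per-base
#'   dispersion alone averages out over a window); 0 disables it.
#'   Background bases are unaffected.
#' @param phi_expr Dispersion of gene-level expression counts.
#' @param seed Integer seed; the same seed reproduces the scenario and all
#'   draws simulated from it.
#' @return An object of class `sim_scenario`.
#' @export
build_scenario <- function(L = 2e6, chrom = "chrS", lambda_bg = 0.01,
                           n_dhs = 500, dhs_width = c(300, 700),
                           dhs_multiplier = 32,
                           n_increase = 50, n_decrease = 0,
                           fold = 3, decrease_fold = 1 / 3,
                           sites_per_template = 200, motif_width = 15,
                           sites_per_dhs = 2L,
                           n_genes = 200, n_de = 40, de_fold = 4,
                           n_rep = c(untreated = 3, induced = 3),
                           phi = 0.1, phi_region = 0.1, phi_expr = 0.1,
                           seed = 1) {
  stopifnot(L > 0, lambda_bg > 0, fold > 0, decrease_fold > 0, phi >= 0,
            phi_region >= 0, phi_expr >= 0, all(n_rep >= 1),
            all(c("untreated", "induced") %in% names(n_rep)))
  L <- as.integer(L)
  if (n_dhs == 0L) {
    n_increase <- n_decrease <- sites_per_template <- n_de <- 0L
  }
  n_sites <- 3L * sites_per_template
  if (n_increase + n_decrease > n_dhs) {
    dd_stop("build_scenario: more planted regions than DHS")
  }
  if (n_dhs > 0L && n_sites > sites_per_dhs * n_dhs) {
    dd_stop("build_scenario: more motif sites than available DHS slots")
  }
  if (n_sites > 0L && dhs_width[1] / (sites_per_dhs + 1) < motif_width) {
    dd_stop("build_scenario: DHS too narrow for ", sites_per_dhs,
            " motif sites each")
  }
  if (n_de > max(n_increase, 0L) && n_increase > 0L) {
    dd_stop("build_scenario: more DE genes than planted increases")
  }
  set.seed(derive_seed(seed, "scenario"))

  # DHS: one per regular slot, random width and offset, so regions never
  # overlap and stay clear of the chromosome edges
  dhs <- genomic_intervals(character(), integer(), integer())
  if (n_dhs > 0L) {
    slot <- floor(L / n_dhs)
    if (slot < max(dhs_width) + 400L) {
      dd_stop("build_scenario: genome too small for requested DHS count")
    }
    widths <- as.integer(round(stats::runif(n_dhs, dhs_width[1], dhs_width[2])))
    offs <- vapply(seq_len(n_dhs), function(i) {
      as.integer(floor(stats::runif(1, 200, slot - widths[i] - 200)))
    }, integer(1))
    starts <- (seq_len(n_dhs) - 1L) * slot + offs
    dhs <- genomic_intervals(chrom, starts, starts + widths,
                             name = sprintf("dhs_%d", seq_len(n_dhs)))
    dhs$multiplier <- dhs_multiplier
    dhs$bound <- FALSE
  }

  # planted condition-specific changes occupy whole DHS regions
  planted_idx <- if (n_increase + n_decrease > 0L) {
    sample.int(n_dhs, n_increase + n_decrease)
  } else integer()
  inc_idx <- planted_idx[seq_len(n_increase)]
  dec_idx <- setdiff(planted_idx, inc_idx)
  delta <- NULL
  if (length(planted_idx)) {
    delta <- dhs[planted_idx, c("chrom", "start", "end"), drop = FALSE]
    delta$fold <- c(rep(fold, n_increase), rep(decrease_fold, n_decrease))
    delta$direction <- c(rep("increase", n_increase),
                         rep("decrease", n_decrease))
    delta$name <- sprintf("planted_%s_%d", delta$direction,
                          seq_len(nrow(delta)))
    rownames(delta) <- NULL
  } else {
    delta <- data.frame(chrom = character(), start = integer(),
                        end = integer(), fold = numeric(),
                        direction = character(), name = character())
  }

  # motif sites distributed over "bound" DHS (up to sites_per_dhs per
  # region, evenly spaced)
  sites <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      template = character())
  if (n_sites > 0L) {
    n_bound <- ceiling(n_sites / sites_per_dhs)
    if (n_bound > n_dhs) dd_stop("build_scenario: too many motif sites")
    bound_idx <- sample.int(n_dhs, n_bound)
    d <- rep(bound_idx, each = sites_per_dhs)[seq_len(n_sites)]
    slot <- rep(seq_len(sites_per_dhs), times = n_bound)[seq_len(n_sites)]
    frac <- slot / (sites_per_dhs + 1L)
    center <- as.integer(floor(dhs$start[d] +
                                 frac * (dhs$end[d] - dhs$start[d])))
    start <- center - motif_width %/% 2L
    tmpl <- sample(rep(names(footprint_templates()),
                       length.out = n_sites))
    sites <- data.frame(chrom = chrom, start = start,
                        end = start + motif_width,
                        strand = sample(c("+", "-"), n_sites, replace = TRUE),
                        template = tmpl, stringsAsFactors = FALSE)
    sites <- sites[order(sites$start), , drop = FALSE]
    rownames(sites) <- NULL
    sites$name <- sprintf("site_%d", seq_len(n_sites))
    dhs$bound[unique(d)] <- TRUE
  }

  # genes: DE genes near distinct planted increases, the rest uniform
  genes_df <- NULL
  exons <- NULL
  utr3 <- NULL
  if (n_genes > 0L) {
    span <- 5000L
    tss <- integer(n_genes)
    de <- rep(FALSE, n_genes)
    if (n_de > 0L && n_increase > 0L) {
      near <- sample(inc_idx, n_de)
      mid <- as.integer((dhs$start[near] + dhs$end[near]) %/% 2L)
      tss[seq_len(n_de)] <- mid +
        as.integer(round(stats::runif(n_de, -2000, 2000)))
      de[seq_len(n_de)] <- TRUE
    }
    n_rest <- n_genes - sum(de)
    tss[(sum(de) + 1L):n_genes] <-
      as.integer(floor(stats::runif(n_rest, span + 1000, L - span - 1000)))
    # keep whole gene bodies inside the chromosome
    tss <- pmin(pmax(tss, span + 1000L), L - span - 1000L)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    gstart <- ifelse(strand == "+", tss, tss - span + 1L)
    gend <- gstart + span
    gstart <- pmax(gstart, 0L); gend <- pmin(gend, L)
    ids <- sprintf("gene_%03d", seq_len(n_genes))
    genes_df <- data.frame(gene_id = ids, chrom = chrom, strand = strand,
                           start = as.integer(gstart), end = as.integer(gend),
                           tss = as.integer(pmin(pmax(tss, gstart), gend - 1L)),
                           base_mean = stats::rlnorm(n_genes, log(100), 0.5),
                           de = de,
                           de_fold = ifelse(de, de_fold, 1),
                           stringsAsFactors = FALSE)
    # three 300-bp exons at span start / middle / end; 3'UTR = last 150 bp
    # of the terminal exon (strand-aware)
    exons <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      s <- genes_df$start[i]; e <- genes_df$end[i]
      st <- as.integer(c(s, s + (e - s) %/% 2L - 150L, e - 300L))
      data.frame(gene_id = ids[i], chrom = chrom, start = st, end = st + 300L)
    }))
    utr3 <- data.frame(
      gene_id = ids, chrom = chrom,
      start = ifelse(genes_df$strand == "+", genes_df$end - 150L,
                     genes_df$start),
      end = ifelse(genes_df$strand == "+", genes_df$end,
                   genes_df$start + 150L)
    )
  }
  gm <- if (!is.null(genes_df)) gene_models(genes_df, exons, utr3) else NULL

  sc <- structure(
    list(chrom = chrom, L = L, lambda_bg = lambda_bg, phi = phi,
         phi_region = phi_region, phi_expr = phi_expr,
         n_rep = n_rep, fold = fold,
         de_fold = de_fold, dhs = dhs, delta = delta, motif_sites = sites,
         genes = gm, templates = footprint_templates(), seed = seed),
    class = "sim_scenario"
  )
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "sim_scenario"))
  if (nrow(sc$dhs) && (any(sc$dhs$start < 0) || any(sc$dhs$end > sc$L))) {
    dd_stop("scenario: DHS outside genome")
  }
  if (nrow(sc$delta)) {
    if (any(sc$delta$start < 0) || any(sc$delta$end > sc$L)) {
      dd_stop("scenario: planted region outside genome")
    }
    o <- order(sc$delta$start)
    if (any(sc$delta$start[o][-1L] < sc$delta$end[o][-nrow(sc$delta)])) {
      dd_stop("scenario: overlapping planted regions")
    }
  }
  if (nrow(sc$motif_sites)) {
    inside <- overlap_fraction(
      sc$motif_sites[, c("chrom", "start", "end")],
      sc$dhs[, c("chrom", "start", "end")]
    )$frac_a
    if (inside < 1) dd_stop("scenario: motif site outside any DHS")
  }
  invisible(sc)
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_scenario> %s: %s bp, %d DHS, %d planted increase(s), ",
    "%d decrease(s), %d motif site(s), %d gene(s) (%d DE), seed %d\n"),
    x$chrom, format(x$L, big.mark = ","), nrow(x$dhs),
    sum(x$delta$direction == "increase"),
    sum(x$delta$direction == "decrease"), nrow(x$motif_sites),
    if (is.null(x$genes)) 0L else nrow(x$genes$genes),
    if (is.null(x$genes)) 0L else sum(x$genes$genes$de), x$seed))
  invisible(x)
}

#' Expected per-base cut rate under a scenario
#'
#' The mean of the count distribution at every base for one replicate of
#' `condition`: background rate times DHS multiplier, times the planted
#' fold-change and footprint-template protection when induced.
#'
#' @param scenario A `sim_scenario`.
#' @param condition `"untreated"` or `"induced"`.
#' @return Numeric vector of length `scenario$L`.
#' @export
scenario_rates <- function(scenario, condition) {
  stopifnot(inherits(scenario, "sim_scenario"))
  condition <- match.arg(condition, c("untreated", "induced"))
  rate <- rep(scenario$lambda_bg, scenario$L)
  d <- scenario$dhs
  for (i in seq_len(nrow(d))) {
    rate[(d$start[i] + 1L):d$end[i]] <-
      rate[(d$start[i] + 1L):d$end[i]] * d$multiplier[i]
  }
  if (condition == "induced") {
    dl <- scenario$delta
    for (i in seq_len(nrow(dl))) {
      rate[(dl$start[i] + 1L):dl$end[i]] <-
        rate[(dl$start[i] + 1L):dl$end[i]] * dl$fold[i]
    }
    ms <- scenario$motif_sites
    for (i in seq_len(nrow(ms))) {
      # mass-conserving protection: cleavage displaced from protected
      # bases accumulates on the exposed bases of the same site, so the
      # site's total cut rate is unchanged by binding
      tmpl <- scenario$templates[[ms$template[i]]]
      if (mean(tmpl) > 0) tmpl <- tmpl / mean(tmpl)
      if (ms$strand[i] == "-") tmpl <- rev(tmpl)
      center <- ms$start[i] + (ms$end[i] - ms$start[i]) %/% 2L
      idx <- (center - 15L):(center + 15L) + 1L
      ok <- idx >= 1L & idx <= scenario$L
      rate[idx[ok]] <- rate[idx[ok]] * tmpl[ok]
    }
  }
  rate
}

#' Simulate a replicate cut profile
#'
#' Draws per-base counts from a negative binomial with mean given by
#' [scenario_rates()] and dispersion `scenario$phi` (`phi = 0` degenerates
#' to Poisson). When `phi_region > 0`, each DHS region's rate is first
#' multiplied by a replicate-specific mean-1 gamma factor modelling
#' biological variability of region accessibility. Deterministic given
#' (scenario seed, condition, replicate).
#'
#' @param scenario A `sim_scenario`.
#' @param condition `"untreated"` or `"induced"`.
#' @param replicate Replicate index (1-based) or label.
#' @return A `cut_profile`.
#' @export
simulate_cuts <- function(scenario, condition, replicate = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  condition <- match.arg(condition, c("untreated", "induced"))
  rate <- scenario_rates(scenario, condition)
  set.seed(derive_seed(scenario$seed, "cuts", condition, replicate))
  phi_region <- if (is.null(scenario$phi_region)) 0 else scenario$phi_region
  if (phi_region > 0 && nrow(scenario$dhs)) {
    g <- stats::rgamma(nrow(scenario$dhs), shape = 1 / phi_region,
                       scale = phi_region)
    for (i in seq_len(nrow(scenario$dhs))) {
      span <- (scenario$dhs$start[i] + 1L):scenario$dhs$end[i]
      rate[span] <- rate[span] * g[i]
    }
  }
  counts <- if (scenario$phi > 0) {
    stats::rnbinom(scenario$L, size = 1 / scenario$phi, mu = rate)
  } else {
    stats::rpois(scenario$L, rate)
  }
  cuts <- stats::setNames(list(as.integer(counts)), scenario$chrom)
  cut_profile(cuts, replicate = paste0(condition, "_rep", replicate),
              condition = condition)
}

#' Simulate all replicate cut profiles of a scenario
#'
#' @param scenario A `sim_scenario`.
#' @return Named list of `cut_profile`s
#'   (`untreated_rep1`, ..., `induced_rep1`, ...).
#' @export
simulate_all_cuts <- function(scenario) {
  out <- list()
  for (cond in c("untreated", "induced")) {
    for (r in seq_len(scenario$n_rep[[cond]])) {
      p <- simulate_cuts(scenario, cond, r)
      out[[p$replicate]] <- p
    }
  }
  out
}

#' Simulate genomic sequence with planted motif instances
#'
#' Background bases are i.i.d. draws from the PWM's stationary background
#' distribution; at each motif site a string is sampled per-column from the
#' PWM (reverse-complemented for `-` strand sites).
#'
#' @param scenario A `sim_scenario`; motif site width must equal the PWM
#'   width.
#' @param pwm A `pwm`.
#' @return Named character vector (chromosome -> sequence string).
#' @export
simulate_sequence <- function(scenario, pwm) {
  stopifnot(inherits(scenario, "sim_scenario"), inherits(pwm, "pwm"))
  ms <- scenario$motif_sites
  if (nrow(ms) && any(ms$end - ms$start != pwm$width)) {
    dd_stop("simulate_sequence: motif site width != PWM width")
  }
  set.seed(derive_seed(scenario$seed, "sequence"))
  bases <- c("A", "C", "G", "T")
  chars <- sample(bases, scenario$L, replace = TRUE,
                  prob = pwm$background$stationary)
  for (i in seq_len(nrow(ms))) {
    inst <- vapply(seq_len(pwm$width), function(j) {
      sample(bases, 1L, prob = pwm$mat[, j])
    }, character(1))
    inst <- paste(inst, collapse = "")
    if (ms$strand[i] == "-") inst <- revcomp(inst)
    chars[(ms$start[i] + 1L):ms$end[i]] <- strsplit(inst, "")[[1L]]
  }
  stats::setNames(paste(chars, collapse = ""), scenario$chrom)
}

#' Write a simulated sequence as FASTA
#' @param seqs Named character vector as returned by [simulate_sequence()].
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Simulate gene-level expression counts
#'
#' Negative-binomial counts per gene and replicate with mean
#' `base_mean * de_fold` for DE genes in the induced condition and
#' `base_mean` otherwise; dispersion `scenario$phi_expr`. Deterministic
#' given the scenario seed.
#'
#' @param scenario A `sim_scenario` with gene models.
#' @return A `count_matrix` (see [count_matrix()]) whose features are the
#'   scenario's genes.
#' @export
simulate_expression <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"), !is.null(scenario$genes))
  g <- scenario$genes$genes
  conds <- rep(c("untreated", "induced"),
               times = c(scenario$n_rep[["untreated"]],
                         scenario$n_rep[["induced"]]))
  set.seed(derive_seed(scenario$seed, "expression"))
  counts <- sapply(seq_along(conds), function(j) {
    mu <- g$base_mean * ifelse(g$de & conds[j] == "induced", g$de_fold, 1)
    if (scenario$phi_expr > 0) {
      stats::rnbinom(nrow(g), size = 1 / scenario$phi_expr, mu = mu)
    } else {
      stats::rpois(nrow(g), mu)
    }
  })
  colnames(counts) <- paste0(conds, "_rep",
                             unlist(lapply(scenario$n_rep[c("untreated", "induced")],
                                           seq_len)))
  rownames(counts) <- g$gene_id
  count_matrix(counts, condition = conds, features = g)
}
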