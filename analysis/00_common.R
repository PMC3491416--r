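# Shared setup for the numbered analysis scripts: one seed drives the
# whole study; every script can be rerun independently because all
# intermediate artifacts live under results/.
library(deltadnase)

SEED <- as.integer(Sys.getenv("DELTADNASE_SEED", "1"))
RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

scenario <- build_scenario(seed = SEED)
pwm <- read_jaspar_pwm(system.file("extdata", "ar_like_synthetic.jaspar",
                                   package = "deltadnase"),
                       pseudocount = 1)

path_profile <- function(p) {
  file.path(DATA_DIR, sprintf("cuts_%s.bedgraph", p))
}

load_profiles <- function() {
  out <- list()
  for (cond in c("untreated", "induced")) {
    for (r in seq_len(scenario$n_rep[[cond]])) {
      id <- sprintf("%s_rep%d", cond, r)
      out[[id]] <- read_bedgraph_cuts(
        path_profile(id),
        stats::setNames(scenario$L, scenario$chrom),
        replicate = id, condition = cond
      )
    }
  }
  out
}
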