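# In-code fixtures: small scenarios and toy transition/site tables.

# one-model, one-region scenario; cheap enough for per-test simulation
small_scenario_config <- function(times = c(2, 3, 4, 5), replicates = 3,
                                  burden_cv = 0.25, model = "P301S",
                                  genotype = "0N4R-P301S",
                                  burden = c(plateau = 250, onset = 4,
                                             fold_at_onset = 5.1), ...) {
  models <- list(P301S = NULL, P301L = NULL)
  models[[model]] <- list(genotype = genotype, times = times,
                          regions = "cortex",
                          burden = list(cortex = burden),
                          burden_cv = burden_cv)
  scenario_config(models = models, replicates = replicates, ...)
}

# simulate + emit into a fresh temp directory, return paths
sim_small <- function(seed = 1, cv = 0, cfg = small_scenario_config(), ...) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  sc <- simulate_scenario(cfg, seed = seed)
  emit_transition_report(sc, dir, noise_model(area_cv = cv), seed = seed + 1,
                         ...)
  list(dir = dir, scenario = sc)
}

# toy transition CSV: one sample, two peptides (3 + 2 transitions), both labels
write_toy_transitions <- function(path, area_name = "area") {
  df <- data.frame(
    sample_id = "s1",
    peptide = rep(c("TDHGAEIVYK", "SPVVSGDTSPR"), c(6, 4)),
    label = c(rep(c("light", "heavy"), each = 3),
              rep(c("light", "heavy"), each = 2)),
    transition_id = c("y3", "y4", "y5", "y3", "y4", "y5",
                      "y3", "y4", "y3", "y4"),
    area = c(1000, 2000, 3000, 2000, 4000, 6000, 500, 500, 1000, 1000))
  names(df)[names(df) == "area"] <- area_name
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# parameter-recovery stoichiometry: constitutive (slope 0) true extents
# spanning 0.1-0.9 on every quantified peptide of the P301S transgene panel,
# with one designated unmodified reference per specificity class
recovery_stoichiometry <- function() {
  pan <- default_panel(load_isoform("0N4R-P301S"))
  ivs <- pan$interval[pan$in_transgene & !pan$specificity %in% "flex_tag"]
  refs <- c("275-280", "25-44")
  tgt <- setdiff(ivs, refs)
  extents <- rep(seq(0.1, 0.9, by = 0.1), length.out = length(tgt))
  data.frame(interval = c(tgt, refs),
             max_extent = c(2 * extents, 0, 0),
             half_burden = 100, slope = 0, stringsAsFactors = FALSE)
}

quantify_all <- function(dir, scenario) {
  samples <- scenario$samples
  res <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    rep <- read_transition_report(
      file.path(dir, "transitions", paste0(s$sample_id, ".csv")))
    q <- quantify_sample(rep, scenario$panels[[s$model]],
                         tissue_mass = s$tissue_mass,
                         processed_volume = s$processed_volume)
    list(sample_id = s$sample_id, abundance = q$abundance,
         fractions = q$fractions)
  })
  names(res) <- samples$sample_id
  res
}
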