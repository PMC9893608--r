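# Ground-truth scenario simulation and emission of the pipeline's two input
# table families: transition-level SRM reports and per-engine PTM site
# tables, with controlled multiplicative noise.

# logistic burden trajectory; steepness solved from the fold change between
# the first time point and onset: fold = (1 + exp(k*(onset - t1))) / 2
burden_curve <- function(t, plateau, onset, fold_at_onset, t_first) {
  k <- log(2 * fold_at_onset - 1) / (onset - t_first)
  if (!is.finite(k)) k <- 1  # degenerate single-time-point grids
  plateau / (1 + exp(-k * (t - onset)))
}

# sigmoid coupling of modification extent to log10 burden; slope 0 means an
# uncoupled, constitutive modification at constant extent max/2
extent_curve <- function(burden, max_extent, half_burden, slope) {
  if (max_extent == 0) return(rep(0, length(burden)))
  if (slope == 0) return(rep(max_extent / 2, length(burden)))
  max_extent / (1 + exp(-slope * (log10(burden) - log10(half_burden))))
}

default_stoichiometry <- function(intervals) {
  # drivers: the PRD / C-terminal intervals that become highly modified as
  # aggregates form are burden-coupled; 407-438 couples only at high burden
  # (P301L regime); all other modified peptides are constitutive (slope 0,
  # constant low stoichiometry, as only the PRD/C-terminus tracks pathology);
  # 25-44 (human-specific) and 275-280 (shared) stay unmodified so each
  # normalization class has a true reference
  drivers <- c("195-209" = 0.90, "212-221" = 0.85, "386-395" = 0.88,
               "396-406" = 0.92)
  df <- data.frame(interval = intervals, max_extent = 0.15,
                   half_burden = 100, slope = 0,
                   stringsAsFactors = FALSE)
  hit <- df$interval %in% names(drivers)
  df$max_extent[hit] <- drivers[df$interval[hit]]
  df$slope[hit] <- 2
  df$max_extent[df$interval == "407-438"] <- 0.55
  df$half_burden[df$interval == "407-438"] <- 300
  df$slope[df$interval == "407-438"] <- 2
  df$max_extent[df$interval %in% c("25-44", "275-280")] <- 0
  df$max_extent[df$interval == "299-317"] <- 0.10
  df
}

default_site_model <- function() {
  # detection probability is logistic in the local stoichiometry of the
  # linked quantified peptide: p = 1 / (1 + exp(-slope*(extent - half))).
  # Steep slopes (60) make detection near-deterministic; half-points are set
  # against the default trajectory means with >= ~0.05 margins so categories
  # are crisp: negative halves -> present at all time points (blue); PRD
  # halves stage the pre/concomitant/post sequence; ubiquitin sites couple to
  # the late 407-438 ramp so they appear only in the high-burden (P301L)
  # regime; ubK290 is a planted never-detected negative control; pS301 only
  # exists in the P301S genotype.
  data.frame(
    canonical_position = c(181, 202, 404, 199, 205, 212, 214, 217, 396, 400,
                           155, 163, 44, 254, 267, 290, 301),
    mod_type = c("phospho", "phospho", "phospho", "phospho", "phospho",
                 "phospho", "phospho", "phospho", "phospho", "phospho",
                 "citrullination", "methyl", "methyl", "ubiquitin",
                 "ubiquitin", "ubiquitin", "phospho"),
    interval = c("181-190", "195-209", "396-406", "195-209", "195-209",
                 "212-221", "212-221", "212-221", "396-406", "396-406",
                 "156-163", "156-163", "25-44", "407-438", "407-438",
                 "407-438", "299-317"),
    half_extent = c(-0.05, -0.05, -0.05, 0.28, 0.43, 0.42, 0.52, 0.60, 0.56,
                    0.72, -0.05, 0.03, -0.05, 0.27, 0.38, 0.90, 0.02),
    slope = 60,
    stringsAsFactors = FALSE)
}

#' Noise model for emitted transition areas
#'
#' Multiplicative lognormal noise per transition area (peak areas are
#' positive and CV-stable), 3-5 transitions per precursor, and per-peptide
#' response factors.
#'
#' @param area_cv Coefficient of variation of the lognormal area noise.
#' @param transition_range Integer range of transitions per precursor.
#' @return A `noise_model` list.
#' @export
noise_model <- function(area_cv = 0.1, transition_range = c(3L, 5L)) {
  stopifnot(area_cv >= 0, transition_range[1] >= 1,
            transition_range[2] >= transition_range[1])
  structure(list(area_cv = area_cv,
                 transition_range = as.integer(transition_range)),
            class = "noise_model")
}

#' Scenario configuration for the synthetic study
#'
#' Defaults mirror the study design this package emulates: P301S mice at
#' 2/3/4/5 months (cortex, brainstem, subcortical), P301L at 1.5/2.5/4/6/8
#' months (cortex, hippocampus, subcortical), 6 biological replicates,
#' logistic insoluble-Tau trajectories anchored at the printed cortical
#' plateaus (~250 and ~1000 fmol/mg), onset 4 months and fold-at-onset 5.1x /
#' 11.2x, sigmoid coupling of per-peptide modification extent to log10
#' burden, and stoichiometry-gated PTM site detection.
#'
#' @param ... Named overrides of any default element (uses
#'   [utils::modifyList()] semantics for nested lists).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(...) {
  cfg <- list(
    models = list(
      P301S = list(
        genotype = "0N4R-P301S",
        times = c(2, 3, 4, 5),
        regions = c("cortex", "brainstem", "subcortical"),
        burden = list(cortex = c(plateau = 250, onset = 4,
                                 fold_at_onset = 5.1),
                      brainstem = c(plateau = 400, onset = 3.5,
                                    fold_at_onset = 6),
                      subcortical = c(plateau = 80, onset = 4.5,
                                      fold_at_onset = 3)),
        burden_cv = 0.25),
      P301L = list(
        genotype = "0N4R-P301L",
        times = c(1.5, 2.5, 4, 6, 8),
        regions = c("cortex", "hippocampus", "subcortical"),
        burden = list(cortex = c(plateau = 1000, onset = 4,
                                 fold_at_onset = 11.2),
                      hippocampus = c(plateau = 900, onset = 4,
                                      fold_at_onset = 10),
                      subcortical = c(plateau = 300, onset = 6,
                                      fold_at_onset = 4)),
        burden_cv = 0.5)),
    replicates = 6,
    tissue_mass_mg = 10,
    processed_volume_ul = 50,
    standard_amount_fmol = 500,
    flex_light_spike = 15,
    mutant_spike_conc = 50,
    mouse_endogenous_fmol_per_mg = 0,
    coupling = TRUE,
    stoichiometry = NULL,   # filled per panel in simulate_scenario
    site_model = default_site_model(),
    phospho_intervals = c("195-209", "212-221", "396-406"),
    phospho_share = 0.8,
    fraction = "insoluble")
  over <- list(...)
  if (length(over)) cfg <- modifyList(cfg, over)
  # JSON-sourced overrides arrive as nested lists; normalize to the internal
  # vector forms
  for (m in names(cfg$models)) {
    mc <- cfg$models[[m]]
    mc$times <- as.numeric(unlist(mc$times))
    mc$regions <- as.character(unlist(mc$regions))
    mc$burden <- lapply(mc$burden, function(b) unlist(b))
    cfg$models[[m]] <- mc
  }
  if (is.list(cfg$stoichiometry) && !is.data.frame(cfg$stoichiometry)) {
    cfg$stoichiometry <- as.data.frame(cfg$stoichiometry)
  }
  for (m in names(cfg$models)) {
    mc <- cfg$models[[m]]
    stopifnot(length(mc$times) >= 1, length(mc$regions) >= 1,
              all(mc$regions %in% names(mc$burden)), mc$burden_cv >= 0)
    for (r in mc$regions) {
      b <- mc$burden[[r]]
      stopifnot(all(c("plateau", "onset", "fold_at_onset") %in% names(b)),
                b["plateau"] > 0, b["fold_at_onset"] >= 1)
    }
  }
  stopifnot(cfg$replicates >= 1, cfg$tissue_mass_mg > 0,
            cfg$processed_volume_ul > 0, cfg$standard_amount_fmol > 0)
  structure(cfg, class = "scenario_config")
}

#' Materialize a ground-truth scenario
#'
#' Draws per-animal burdens (logistic trajectory times mean-1 lognormal
#' inter-animal variation), evaluates per-peptide true modification extents
#' (sigmoid coupling to log10 burden; constant when `coupling = FALSE`), and
#' per-site detection probabilities. Fully reproducible under `seed`.
#'
#' @param config A `scenario_config`.
#' @param seed Integer RNG seed.
#' @return Object of class `tau_scenario`: list with `samples` (metadata +
#'   true burden), `extents` (samples x intervals matrix of true modification
#'   extents), `site_prob` (samples x sites matrix), `panel` (per model),
#'   `site_model`, `stoichiometry`, `config`, `seed`.
#' @export
simulate_scenario <- function(config = scenario_config(), seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(seed, {
    rows <- list()
    for (model in names(config$models)) {
      mc <- config$models[[model]]
      for (region in mc$regions) {
        bp <- mc$burden[[region]]
        for (t in mc$times) {
          mu <- burden_curve(t, bp["plateau"], bp["onset"],
                             bp["fold_at_onset"], min(mc$times))
          for (r in seq_len(config$replicates)) {
            rows[[length(rows) + 1]] <- data.frame(
              sample_id = sprintf("%s_%s_%gm_r%d", model, region, t, r),
              model = model, region = region, time = t, replicate = r,
              genotype = mc$genotype, burden_mean = unname(mu),
              burden_cv = mc$burden_cv, stringsAsFactors = FALSE)
          }
        }
      }
    }
    samples <- do.call(rbind, rows)
    # mean-1 lognormal inter-animal effect
    sdl <- sqrt(log(1 + samples$burden_cv^2))
    samples$burden <- samples$burden_mean *
      exp(rnorm(nrow(samples), -sdl^2 / 2, sdl))
    samples$tissue_mass <- config$tissue_mass_mg
    samples$processed_volume <- config$processed_volume_ul
    samples$standard_amount <- config$standard_amount_fmol
    samples$flex_light_spike <- config$flex_light_spike
    samples$fraction <- config$fraction
    # panels per model genotype (mutant peptide differs)
    panels <- lapply(names(config$models), function(model) {
      default_panel(load_isoform(config$models[[model]]$genotype))
    })
    names(panels) <- names(config$models)
    intervals <- unique(unlist(lapply(panels, function(p) {
      p$interval[p$in_transgene & p$specificity != "flex_tag"]
    })))
    stoich <- config$stoichiometry %||% default_stoichiometry(intervals)
    extents <- matrix(0, nrow(samples), length(intervals),
                      dimnames = list(samples$sample_id, intervals))
    for (i in seq_len(nrow(stoich))) {
      iv <- stoich$interval[i]
      if (!iv %in% intervals) next
      extents[, iv] <- if (config$coupling) {
        extent_curve(samples$burden, stoich$max_extent[i],
                     stoich$half_burden[i], stoich$slope[i])
      } else {
        rep(stoich$max_extent[i] / 2, nrow(samples))
      }
    }
    sm <- config$site_model
    canon <- load_isoform("2N4R")
    sm$residue <- substring(canon$sequence, sm$canonical_position,
                            sm$canonical_position)
    # genotype-aware residue at mutated positions is resolved at emission
    site_prob <- matrix(0, nrow(samples), nrow(sm),
                        dimnames = list(samples$sample_id, NULL))
    for (i in seq_len(nrow(sm))) {
      e <- if (sm$interval[i] %in% intervals) {
        extents[, sm$interval[i]]
      } else {
        rep(0, nrow(samples))
      }
      site_prob[, i] <- 1 / (1 + exp(-sm$slope[i] * (e - sm$half_extent[i])))
    }
    structure(list(samples = samples, extents = extents,
                   site_prob = site_prob, panels = panels,
                   site_model = sm, stoichiometry = stoich,
                   config = config, seed = seed),
              class = "tau_scenario")
  })
}

#' @export
print.tau_scenario <- function(x, ...) {
  cat("<tau_scenario> ", nrow(x$samples), " samples (",
      paste(names(x$config$models), collapse = ", "), "), ",
      ncol(x$extents), " panel peptides, ", nrow(x$site_model),
      " PTM sites, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# place a [+80] annotation on the canonical phospho site of a driver peptide
phospho_modified_sequence <- function(peptide, start, site_pos) {
  off <- site_pos - start + 1
  paste0(substring(peptide, 1, off), "[+80]",
         substring(peptide, off + 1, nchar(peptide)))
}

#' Emit transition-level SRM reports for a scenario
#'
#' Writes one CSV per sample under `dir/transitions/`, sample metadata
#' (`samples.csv`), the panel (`panel_<model>.tsv`), and a ground-truth
#' sidecar (`truth.json`). Heavy areas are proportional to the standard
#' concentration times a per-peptide response factor; light areas carry the
#' true unmodified fraction and the endogenous/standard abundance ratio;
#' singly phosphorylated precursors of the configured driver peptides are
#' emitted light-only. All areas receive multiplicative lognormal noise of
#' the given CV (`CV = 0` reproduces the truth exactly through the pipeline).
#'
#' @param scenario A `tau_scenario`.
#' @param dir Output directory (created if needed).
#' @param noise A `noise_model`.
#' @param seed Integer seed for the emission RNG (transition counts, weights,
#'   response factors, noise).
#' @param response_factors Optional named per-peptide response factors
#'   overriding the seeded lognormal draws (for invariance testing).
#' @return Invisibly, a manifest data frame of written files.
#' @export
emit_transition_report <- function(scenario, dir, noise = noise_model(),
                                   seed = 1, response_factors = NULL) {
  stopifnot(inherits(scenario, "tau_scenario"),
            inherits(noise, "noise_model"))
  cfg <- scenario$config
  dir.create(file.path(dir, "transitions"), recursive = TRUE,
             showWarnings = FALSE)
  canon <- load_isoform("2N4R")
  files <- character(0)
  with_seed(seed, {
    # per-peptide response factors and transition layouts, shared across
    # samples (instrument properties, not sample properties)
    all_peps <- unique(unlist(lapply(scenario$panels,
                                     function(p) p$peptide)))
    fct <- setNames(exp(rnorm(length(all_peps), 0, 0.3)), all_peps)
    if (!is.null(response_factors)) {
      fct[names(response_factors)] <- response_factors
    }
    tr <- noise$transition_range
    ntr <- if (tr[1] == tr[2]) {
      rep(tr[1], length(all_peps))
    } else {
      sample(seq(tr[1], tr[2]), length(all_peps), replace = TRUE)
    }
    ntr <- setNames(ntr, all_peps)
    wts <- lapply(setNames(all_peps, all_peps), function(p) {
      w <- runif(ntr[p], 0.5, 1.5); w / sum(w)
    })
    sdl <- if (noise$area_cv > 0) sqrt(log(1 + noise$area_cv^2)) else 0
    noisy <- function(x) {
      if (sdl == 0) x else x * exp(rnorm(length(x), -sdl^2 / 2, sdl))
    }
    scale <- 1e4  # arbitrary instrument response scale
    for (si in seq_len(nrow(scenario$samples))) {
      s <- scenario$samples[si, ]
      panel <- scenario$panels[[s$model]]
      std_conc <- s$standard_amount / s$processed_volume
      endo_conc <- s$burden * s$tissue_mass / s$processed_volume
      mouse_conc <- cfg$mouse_endogenous_fmol_per_mg * s$tissue_mass /
        s$processed_volume
      recs <- list()
      for (pi in seq_len(nrow(panel))) {
        p <- panel[pi, ]
        pep <- p$peptide
        w <- wts[[pep]]; f <- unname(fct[pep])
        heavy_conc <- switch(p$heavy_source,
                             standard = std_conc,
                             spike = cfg$mutant_spike_conc)
        light_conc <- if (isTRUE(p$specificity == "flex_tag")) {
          s$flex_light_spike
        } else if (!p$in_transgene) {
          0
        } else {
          e <- scenario$extents[s$sample_id, p$interval]
          endo_conc * (1 - e) +
            if (isTRUE(p$specificity == "shared")) mouse_conc else 0
        }
        recs[[length(recs) + 1]] <- data.frame(
          sample_id = s$sample_id, peptide = pep,
          label = rep(c("light", "heavy"), each = length(w)),
          transition_id = rep(paste0("y", seq_along(w) + 2), 2),
          area = c(noisy(light_conc * f * w * scale),
                   noisy(heavy_conc * f * w * scale)),
          stringsAsFactors = FALSE)
        # singly phosphorylated light precursor for driver peptides
        if (p$interval %in% cfg$phospho_intervals && p$in_transgene) {
          site <- scenario$site_model[
            scenario$site_model$interval == p$interval &
              scenario$site_model$mod_type == "phospho", , drop = FALSE]
          pos <- if (nrow(site)) site$canonical_position[1] else p$start
          mseq <- phospho_modified_sequence(pep, p$start, pos)
          e <- scenario$extents[s$sample_id, p$interval]
          phos_conc <- endo_conc * e * cfg$phospho_share
          recs[[length(recs) + 1]] <- data.frame(
            sample_id = s$sample_id, peptide = mseq, label = "light",
            transition_id = paste0("y", seq_along(w) + 2),
            area = noisy(phos_conc * f * w * scale),
            stringsAsFactors = FALSE)
        }
      }
      df <- do.call(rbind, recs)
      path <- file.path(dir, "transitions", paste0(s$sample_id, ".csv"))
      write.csv(df, path, row.names = FALSE, quote = FALSE)
      files <- c(files, path)
    }
  })
  write.csv(scenario$samples, file.path(dir, "samples.csv"),
            row.names = FALSE, quote = FALSE)
  for (model in names(scenario$panels)) {
    write_digest_tsv(scenario$panels[[model]],
                     file.path(dir, paste0("panel_", model, ".tsv")))
  }
  truth <- list(seed = scenario$seed,
                noise = list(area_cv = noise$area_cv),
                samples = scenario$samples[, c("sample_id", "model", "region",
                                               "time", "replicate", "burden")],
                extents = as.data.frame(scenario$extents),
                stoichiometry = scenario$stoichiometry)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(data.frame(file = c(files, file.path(dir, "samples.csv"),
                                file.path(dir, "truth.json")),
                       stringsAsFactors = FALSE))
}

#' Emit per-engine PTM site tables for a scenario
#'
#' For every engine, replicate and PTM site: a Bernoulli detection draw with
#' probability `site_prob * engine sensitivity`. Positions are written in the
#' engine's search-database coordinates (the transgene 0N4R local numbering),
#' deliberately exercising the canonical mapping path of the consensus
#' module; residues reflect the genotype (e.g. S at canonical 301 for P301S).
#' Sites whose residue is incompatible with the transgene sequence are
#' skipped for that model.
#'
#' @param scenario A `tau_scenario`.
#' @param dir Output directory.
#' @param engines Engine dialect names (see [engine_dialects()]).
#' @param sensitivity Named multiplier per engine (default 1 each).
#' @param seed Integer seed.
#' @return Invisibly, a manifest data frame of written files.
#' @export
emit_engine_site_tables <- function(scenario, dir,
                                    engines = c("mascot", "maxquant",
                                                "proteinpilot"),
                                    sensitivity = NULL, seed = 1) {
  stopifnot(inherits(scenario, "tau_scenario"))
  dir.create(file.path(dir, "sites"), recursive = TRUE, showWarnings = FALSE)
  sens <- setNames(rep(1, length(engines)), engines)
  if (!is.null(sensitivity)) sens[names(sensitivity)] <- sensitivity
  dialects <- engine_dialects()
  stopifnot(all(engines %in% names(dialects)))
  cfg <- scenario$config
  isoforms <- lapply(cfg$models, function(mc) load_isoform(mc$genotype))
  digests <- lapply(isoforms, function(iso) digest(iso, trypsin_rule()))
  sm <- scenario$site_model
  files <- character(0)
  with_seed(seed, {
    for (eng in engines) {
      rows <- list()
      for (si in seq_len(nrow(scenario$samples))) {
        s <- scenario$samples[si, ]
        iso <- isoforms[[s$model]]
        dg <- digests[[s$model]]
        for (k in seq_len(nrow(sm))) {
          canon_pos <- sm$canonical_position[k]
          local <- match(canon_pos, iso$canonical_map)
          if (is.na(local)) next
          residue <- substring(iso$sequence, local, local)
          if (!residue %in% MOD_RESIDUES[[sm$mod_type[k]]]) next
          p <- scenario$site_prob[s$sample_id, k] * sens[eng]
          if (rbinom(1, 1, min(p, 1)) == 0) next
          host <- dg[dg$local_start <= local & dg$local_end >= local, ]
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = s$sample_id, peptide = host$peptide[1],
            local_position = local, residue = residue,
            mod_type = sm$mod_type[k], stringsAsFactors = FALSE)
        }
      }
      df <- if (length(rows)) {
        do.call(rbind, rows)
      } else {
        data.frame(sample_id = character(0), peptide = character(0),
                   local_position = integer(0), residue = character(0),
                   mod_type = character(0))
      }
      # render in the engine's dialect
      d <- dialects[[eng]]
      out <- df
      out$mod_type <- dialect_mod_vocab(eng, df$mod_type)
      names(out) <- d$columns[match(names(df), names(d$columns))]
      path <- file.path(dir, "sites", paste0(eng, ".csv"))
      write.csv(out, path, row.names = FALSE, quote = FALSE)
      files <- c(files, path)
    }
  })
  invisible(data.frame(file = files, stringsAsFactors = FALSE))
}

# inverse of the dialect normalizers: canonical mod type -> engine vocabulary
dialect_mod_vocab <- function(engine, mod_type) {
  vocab <- switch(engine,
    mascot = c(phospho = "Phospho", ubiquitin = "GlyGly", acetyl = "Acetyl",
               methyl = "Methyl", citrullination = "Citrullination",
               oxidation = "Oxidation"),
    maxquant = c(phospho = "Phospho (STY)", ubiquitin = "GlyGly (K)",
                 acetyl = "Acetyl (K)", methyl = "Methyl (KR)",
                 citrullination = "Citrullination (R)",
                 oxidation = "Oxidation (M)"),
    proteinpilot = setNames(MOD_TYPES, MOD_TYPES),
    fragpipe = c(phospho = "79.9663", ubiquitin = "114.0429",
                 acetyl = "42.0106", methyl = "14.0157",
                 citrullination = "0.9840", oxidation = "15.9949"))
  unname(vocab[mod_type])
}
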