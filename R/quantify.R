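# The FLEXITau calculus: standard concentration from the FLEX reporter,
# absolute Tau abundance, and per-peptide modification extent.

#' Heavy-standard concentration from the FLEX reporter ratio
#'
#' The light FLEX peptide is spiked at a known concentration; the heavy FLEX
#' peptide is released from the heavy full-length standard, so
#' `standard = spike / (L/H)`.
#'
#' @param flex_lh L/H ratio of the FLEX reporter precursor.
#' @param flex_light_spike Known light spike concentration (fmol/ul,
#'   default 15).
#' @return Heavy standard concentration in fmol/ul.
#' @examples
#' standard_concentration_from_flex(3, 15)  # 5 fmol/ul
#' @export
standard_concentration_from_flex <- function(flex_lh, flex_light_spike = 15) {
  if (is.na(flex_lh) || flex_lh <= 0) {
    stop("FLEX L/H ratio must be > 0 (got ", flex_lh, ")")
  }
  stopifnot(flex_light_spike > 0)
  flex_light_spike / flex_lh
}

# rescale spike-calibrated L/H ratios (mutant-specific synthetic heavy
# peptides) onto the standard scale; lh * spike_conc / standard_conc
adjust_lh_scale <- function(lh, heavy_source, standard_conc,
                            spike_conc = 50) {
  ifelse(heavy_source == "spike", lh * spike_conc / standard_conc, lh)
}

#' Absolute Tau abundance of a sample
#'
#' `abundance = max(L/H over the reference class) * standard_conc *
#' processed_volume / tissue_mass`, in fmol Tau per mg tissue. The reference
#' class is `shared` for mouse-model samples (the highest-ratio peptide shared
#' between mouse and transgene human Tau) and `human_specific` for human
#' samples.
#'
#' @param lh Numeric vector of per-peptide L/H ratios (standard scale).
#' @param specificity Character vector parallel to `lh`.
#' @param standard_conc Heavy standard concentration (fmol/ul), from
#'   [standard_concentration_from_flex()].
#' @param processed_volume Processed homogenate volume (ul).
#' @param tissue_mass Tissue wet mass (mg).
#' @param reference_class `"shared"` or `"human_specific"`.
#' @return List: `abundance_fmol_per_mg`, `reference_peptide` (index into
#'   `lh`), `reference_lh`.
#' @export
absolute_tau_abundance <- function(lh, specificity, standard_conc,
                                   processed_volume, tissue_mass,
                                   reference_class = "shared") {
  stopifnot(length(lh) == length(specificity), tissue_mass > 0,
            processed_volume > 0, standard_conc > 0)
  idx <- which(specificity == reference_class & !is.na(lh))
  if (!length(idx)) {
    stop("no quantifiable peptide of reference class '", reference_class, "'")
  }
  ref <- idx[which.max(lh[idx])]
  list(abundance_fmol_per_mg =
         lh[ref] * standard_conc * processed_volume / tissue_mass,
       reference_peptide = ref, reference_lh = lh[ref])
}

#' Unmodified fraction of each peptide within its specificity class
#'
#' For peptide i of class c: `fraction_i = lh_i / max(lh over class c)`,
#' clipped into [0, 1]; `extent_i = 1 - fraction_i`. Mutant-specific peptides
#' normalize within the `human_specific` class (they are transgene-derived);
#' FLEX rows are excluded. A class whose maximum is 0 or undefined yields NA
#' fractions with a flag.
#'
#' @param lh Per-peptide L/H ratios (standard scale), one sample.
#' @param specificity Parallel character vector.
#' @return List: `fraction`, `extent` (both parallel to `lh`), `clipped`
#'   (logical), `reference` (per-class reference index), `flag`.
#' @export
unmodified_fraction <- function(lh, specificity) {
  stopifnot(length(lh) == length(specificity))
  norm_class <- specificity
  norm_class[norm_class %in% "mutant_specific"] <- "human_specific"
  fraction <- rep(NA_real_, length(lh))
  clipped <- rep(FALSE, length(lh))
  flag <- rep("ok", length(lh))
  reference <- integer(0)
  for (cl in setdiff(unique(norm_class), c("flex_tag", NA))) {
    idx <- which(norm_class == cl)
    ok <- idx[!is.na(lh[idx])]
    if (!length(ok) || max(lh[ok]) <= 0) {
      flag[idx] <- "undefined_class_max"
      next
    }
    ref <- ok[which.max(lh[ok])]
    reference <- c(reference, setNames(ref, cl))
    fraction[idx] <- lh[idx] / lh[ref]
    over <- idx[!is.na(fraction[idx]) & fraction[idx] > 1]
    clipped[over] <- TRUE
    fraction[over] <- 1
    flag[idx[is.na(lh[idx])]] <- "undefined_ratio"
  }
  flag[specificity %in% "flex_tag"] <- "excluded_flex"
  list(fraction = fraction, extent = 1 - fraction, clipped = clipped,
       reference = reference, flag = flag)
}

#' Modification-extent matrix across samples
#'
#' Applies [unmodified_fraction()] per sample over a panel, producing
#' peptides-by-samples matrices of unmodified fraction and modification
#' extent. Reference selection is per sample (each sample's own class
#' maximum). When the panel contains spike-calibrated peptides the per-sample
#' heavy standard concentration (from the FLEX reporter) rescales their L/H
#' onto the standard scale.
#'
#' @param lh_table Output of [compute_lh_ratios()] covering >= 1 sample.
#' @param panel Panel data frame from [default_panel()].
#' @param flex_light_spike Light FLEX spike concentration (fmol/ul).
#' @param mutant_spike_conc Heavy mutant-peptide spike concentration
#'   (fmol/ul).
#' @return Object of class `mod_extent_matrix`: list with `unmodified` and
#'   `extent` matrices (rows = panel intervals, columns = samples),
#'   `reference` (data frame sample/class/interval), `clipped` count,
#'   `standard_conc` (named per-sample vector), and the `panel`.
#' @export
mod_extent_matrix <- function(lh_table, panel, flex_light_spike = 15,
                              mutant_spike_conc = 50) {
  samples <- sort(unique(lh_table$sample_id))
  rows <- panel$interval[!panel$specificity %in% "flex_tag"]
  unmod <- matrix(NA_real_, nrow = length(rows), ncol = length(samples),
                  dimnames = list(rows, samples))
  extent <- unmod
  clipped <- 0L
  refs <- list()
  std <- setNames(rep(NA_real_, length(samples)), samples)
  for (s in samples) {
    tab <- lh_table[lh_table$sample_id == s, ]
    lh <- tab$lh_ratio[match(panel$peptide, tab$stripped_sequence)]
    flex_lh <- lh[panel$specificity %in% "flex_tag"][1]
    sc <- if (!is.na(flex_lh) && flex_lh > 0) {
      standard_concentration_from_flex(flex_lh, flex_light_spike)
    } else {
      NA_real_
    }
    std[s] <- sc
    if (any(panel$heavy_source == "spike") && !is.na(sc)) {
      lh <- adjust_lh_scale(lh, panel$heavy_source, sc, mutant_spike_conc)
    }
    uf <- unmodified_fraction(lh, panel$specificity)
    keep <- !panel$specificity %in% "flex_tag"
    unmod[, s] <- uf$fraction[keep]
    extent[, s] <- uf$extent[keep]
    clipped <- clipped + sum(uf$clipped)
    if (length(uf$reference)) {
      refs[[s]] <- data.frame(sample_id = s, class = names(uf$reference),
                              interval = panel$interval[uf$reference],
                              stringsAsFactors = FALSE)
    }
  }
  reference <- if (length(refs)) {
    do.call(rbind, c(refs, list(make.row.names = FALSE)))
  } else {
    NULL
  }
  structure(list(unmodified = unmod, extent = extent,
                 reference = reference,
                 clipped = clipped, standard_conc = std, panel = panel),
            class = "mod_extent_matrix")
}

#' @export
print.mod_extent_matrix <- function(x, ...) {
  cat("<mod_extent_matrix> ", nrow(x$unmodified), " peptides x ",
      ncol(x$unmodified), " samples; ", x$clipped,
      " clipped cell(s)\n", sep = "")
  invisible(x)
}

#' Relative abundance of singly phosphorylated peptides
#'
#' The heavy standard is dephosphorylated, so no heavy phospho form exists;
#' the light phosphopeptide is referenced to the heavy signal of its
#' unmodified sequence counterpart:
#' `relative = sum(light phospho areas) / sum(heavy unmodified areas)`.
#'
#' @param report A `transition_report` for one or more samples.
#' @return Data frame: `sample_id`, `peptide` (modified sequence),
#'   `stripped_sequence`, `n_phospho`, `relative_amount`.
#' @export
phosphopeptide_relative_abundance <- function(report) {
  df <- as.data.frame(report)
  mods <- df[df$n_phospho > 0 & df$label == "light", , drop = FALSE]
  if (!nrow(mods)) {
    return(data.frame(sample_id = character(0), peptide = character(0),
                      stripped_sequence = character(0),
                      n_phospho = integer(0), relative_amount = numeric(0)))
  }
  key <- interaction(mods$sample_id, mods$peptide, drop = TRUE)
  out <- lapply(split(mods, key), function(g) {
    heavy <- df$area[df$sample_id == g$sample_id[1] &
                       df$stripped_sequence == g$stripped_sequence[1] &
                       df$n_phospho == 0 & df$label == "heavy"]
    if (!length(heavy) || sum(heavy) <= 0) {
      stop("no heavy unmodified counterpart for '", g$stripped_sequence[1],
           "' in sample ", g$sample_id[1])
    }
    data.frame(sample_id = g$sample_id[1], peptide = g$peptide[1],
               stripped_sequence = g$stripped_sequence[1],
               n_phospho = g$n_phospho[1],
               relative_amount = sum(g$area) / sum(heavy),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sample_id, res$stripped_sequence), ]
}

#' Quantify one sample end to end
#'
#' Convenience wrapper: L/H ratios, FLEX-calibrated standard concentration,
#' absolute abundance and unmodified fractions for a single sample's
#' transition report.
#'
#' @param report `transition_report` restricted to one sample.
#' @param panel Panel from [default_panel()].
#' @param tissue_mass,processed_volume Sample bookkeeping (mg, ul).
#' @param reference_class Reference class for absolute abundance.
#' @param flex_light_spike,mutant_spike_conc Spike concentrations (fmol/ul).
#' @return List: `lh` (table), `standard_conc`, `abundance` (fmol/mg),
#'   `reference_interval`, `fractions` (named by panel interval), `extent`.
#' @export
quantify_sample <- function(report, panel, tissue_mass, processed_volume,
                            reference_class = "shared",
                            flex_light_spike = 15, mutant_spike_conc = 50) {
  stopifnot(length(unique(report$sample_id)) == 1)
  lh_tab <- compute_lh_ratios(report)
  lh <- lh_tab$lh_ratio[match(panel$peptide, lh_tab$stripped_sequence)]
  flex_lh <- lh[panel$specificity %in% "flex_tag"][1]
  sc <- standard_concentration_from_flex(flex_lh, flex_light_spike)
  lh <- adjust_lh_scale(lh, panel$heavy_source, sc, mutant_spike_conc)
  ab <- absolute_tau_abundance(lh, panel$specificity, sc, processed_volume,
                               tissue_mass, reference_class)
  uf <- unmodified_fraction(lh, panel$specificity)
  keep <- !panel$specificity %in% "flex_tag"
  list(lh = lh_tab, standard_conc = sc,
       abundance = ab$abundance_fmol_per_mg,
       reference_interval = panel$interval[ab$reference_peptide],
       fractions = setNames(uf$fraction[keep], panel$interval[keep]),
       extent = setNames(uf$extent[keep], panel$interval[keep]))
}
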