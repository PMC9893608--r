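# Transition-level SRM report IO and light/heavy ratio aggregation.

#' Strip bracketed mass-shift annotations from modified peptide sequences
#'
#' Skyline-style modified sequences annotate residues as e.g. `S[+80]`; this
#' removes all `[...]` blocks, returning the plain sequence.
#'
#' @param x Character vector of (possibly modified) peptide sequences.
#' @return Character vector of stripped sequences.
#' @export
strip_modifications <- function(x) gsub("\\[[^]]*\\]", "", x)

count_phospho <- function(x) {
  lengths(regmatches(x, gregexpr("\\[\\+(79\\.9663|80)\\]", x)))
}

#' Read a transition-level SRM peak-area report
#'
#' Expects (after column mapping) the logical columns `sample_id`, `peptide`
#' (modified sequence allowed), `label` (light/heavy), `transition_id`,
#' `area`, and optionally `retention_time`. Malformed rows (negative or
#' non-numeric area, unknown label) are rejected and counted, not fatal;
#' missing required columns are a hard error.
#'
#' @param path CSV (`.csv`) or TSV file.
#' @param col_map Named character vector mapping logical names to file column
#'   names, e.g. `c(area = "Area")`. Unmapped names are used as-is.
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @return Data frame of class `transition_report` with the logical columns
#'   plus `stripped_sequence` and `n_phospho`; attribute `rejected` counts
#'   dropped rows.
#' @export
read_transition_report <- function(path, col_map = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  required <- c("sample_id", "peptide", "label", "transition_id", "area")
  cols <- setNames(required, required)
  if (!is.null(col_map)) cols[names(col_map)] <- col_map
  missing <- required[!cols[required] %in% names(raw)]
  if (length(missing)) {
    stop("transition report '", path, "' lacks required column(s): ",
         paste(cols[missing], collapse = ", "))
  }
  df <- data.frame(sample_id = as.character(raw[[cols["sample_id"]]]),
                   peptide = as.character(raw[[cols["peptide"]]]),
                   label = tolower(as.character(raw[[cols["label"]]])),
                   transition_id = as.character(raw[[cols["transition_id"]]]),
                   area = suppressWarnings(as.numeric(raw[[cols["area"]]])),
                   stringsAsFactors = FALSE)
  rt_col <- if (!is.null(col_map) && "retention_time" %in% names(col_map)) {
    col_map[["retention_time"]]
  } else {
    "retention_time"
  }
  df$retention_time <- if (rt_col %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[rt_col]]))
  } else {
    NA_real_
  }
  bad <- is.na(df$area) | df$area < 0 | !df$label %in% c("light", "heavy")
  if (any(bad)) {
    message("read_transition_report: rejected ", sum(bad), " malformed row(s) in ",
            basename(path))
  }
  df <- df[!bad, , drop = FALSE]
  dup <- duplicated(df[, c("sample_id", "peptide", "label", "transition_id")])
  if (any(dup)) {
    message("read_transition_report: dropped ", sum(dup),
            " duplicate transition row(s)")
    df <- df[!dup, , drop = FALSE]
  }
  df$stripped_sequence <- strip_modifications(df$peptide)
  df$n_phospho <- count_phospho(df$peptide)
  rownames(df) <- NULL
  structure(df, rejected = sum(bad) + sum(dup),
            class = c("transition_report", "data.frame"))
}

#' Light/heavy ratio of one precursor from its transition areas
#'
#' Ratio-of-sums aggregation: `sum(light areas) / sum(heavy areas)`. A zero
#' heavy sum gives an undefined (NA) ratio with `flag = "undefined_heavy"`;
#' absence of light transitions gives ratio 0 with `flag = "no_light"`.
#'
#' @param light_areas,heavy_areas Numeric vectors of transition peak areas.
#' @return List with `lh_ratio`, `n_transitions_light`, `n_transitions_heavy`,
#'   `flag` (`"ok"` or a problem code).
#' @examples
#' peptide_lh_ratio(c(1000, 2000, 3000), c(2000, 4000, 6000))$lh_ratio  # 0.5
#' @export
peptide_lh_ratio <- function(light_areas, heavy_areas) {
  light_areas <- light_areas[!is.na(light_areas)]
  heavy_areas <- heavy_areas[!is.na(heavy_areas)]
  stopifnot(all(light_areas >= 0), all(heavy_areas >= 0))
  hs <- sum(heavy_areas)
  ls <- sum(light_areas)
  if (hs <= 0) {
    list(lh_ratio = NA_real_, n_transitions_light = length(light_areas),
         n_transitions_heavy = length(heavy_areas), flag = "undefined_heavy")
  } else if (length(light_areas) == 0) {
    list(lh_ratio = 0, n_transitions_light = 0L,
         n_transitions_heavy = length(heavy_areas), flag = "no_light")
  } else {
    list(lh_ratio = ls / hs, n_transitions_light = length(light_areas),
         n_transitions_heavy = length(heavy_areas), flag = "ok")
  }
}

#' Per-sample, per-peptide L/H ratios from a transition report
#'
#' @param report A `transition_report` (or equivalent data frame).
#' @param include_modified Keep precursors carrying phospho annotations
#'   (default `FALSE`: modified precursors are quantified separately via
#'   [phosphopeptide_relative_abundance()]).
#' @param transition_bounds Expected transitions per precursor per label;
#'   counts outside the range trigger a warning, not an error.
#' @return Data frame: `sample_id`, `peptide` (modified sequence),
#'   `stripped_sequence`, `lh_ratio`, `n_transitions_light`,
#'   `n_transitions_heavy`, `flag`.
#' @export
compute_lh_ratios <- function(report, include_modified = FALSE,
                              transition_bounds = c(3L, 5L)) {
  df <- as.data.frame(report)
  if (!include_modified) df <- df[df$n_phospho == 0, , drop = FALSE]
  key <- interaction(df$sample_id, df$peptide, drop = TRUE)
  groups <- split(df, key)
  out <- lapply(groups, function(g) {
    q <- peptide_lh_ratio(g$area[g$label == "light"],
                          g$area[g$label == "heavy"])
    data.frame(sample_id = g$sample_id[1], peptide = g$peptide[1],
               stripped_sequence = g$stripped_sequence[1],
               lh_ratio = q$lh_ratio,
               n_transitions_light = q$n_transitions_light,
               n_transitions_heavy = q$n_transitions_heavy,
               flag = q$flag, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  n <- pmax(res$n_transitions_light, res$n_transitions_heavy)
  outside <- n > 0 & (n < transition_bounds[1] | n > transition_bounds[2])
  if (any(outside)) {
    warning(sum(outside), " precursor(s) with transition count outside ",
            transition_bounds[1], "-", transition_bounds[2], call. = FALSE)
  }
  res[order(res$sample_id, res$stripped_sequence), ]
}
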