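# Multi-engine PTM site consensus: engine dialect readers, canonical 2N4R
# coordinate mapping, replicate-frequency matrices and the >= 50% rule.

MOD_TYPES <- c("phospho", "ubiquitin", "acetyl", "methyl", "citrullination",
               "oxidation")

# residue compatibility per modification type
MOD_RESIDUES <- list(phospho = c("S", "T", "Y"), ubiquitin = "K",
                     acetyl = "K", methyl = c("K", "R"),
                     citrullination = "R", oxidation = "M")

MOD_PREFIX <- c(phospho = "p", ubiquitin = "ub", acetyl = "ac",
                methyl = "me", citrullination = "c", oxidation = "ox")

#' Registered search-engine table dialects
#'
#' Each dialect maps the logical columns (`sample_id`, `peptide`,
#' `local_position`, `residue`, `mod_type`) to that engine's header names and
#' supplies a normalizer from the engine's modification vocabulary to the
#' canonical types (`r paste(MOD_TYPES, collapse = ", ")`).
#'
#' @return Named list of dialect definitions.
#' @export
engine_dialects <- function() {
  list(
    mascot = list(
      columns = c(sample_id = "sample", peptide = "pep_seq",
                  local_position = "site_pos", residue = "site_res",
                  mod_type = "mod"),
      normalize = function(x) {
        map <- c("Phospho" = "phospho", "GlyGly" = "ubiquitin",
                 "Acetyl" = "acetyl", "Methyl" = "methyl",
                 "Citrullination" = "citrullination",
                 "Oxidation" = "oxidation")
        unname(map[x])
      }),
    maxquant = list(
      columns = c(sample_id = "Raw file", peptide = "Sequence",
                  local_position = "Position", residue = "Amino acid",
                  mod_type = "Modification"),
      normalize = function(x) {
        map <- c("Phospho (STY)" = "phospho", "GlyGly (K)" = "ubiquitin",
                 "Acetyl (K)" = "acetyl", "Methyl (KR)" = "methyl",
                 "Citrullination (R)" = "citrullination",
                 "Oxidation (M)" = "oxidation")
        unname(map[x])
      }),
    proteinpilot = list(
      columns = c(sample_id = "sample_id", peptide = "peptide",
                  local_position = "position", residue = "residue",
                  mod_type = "mod_type"),
      normalize = function(x) ifelse(x %in% MOD_TYPES, x, NA_character_)),
    fragpipe = list(
      columns = c(sample_id = "sample", peptide = "peptide",
                  local_position = "position", residue = "residue",
                  mod_type = "mass_shift"),
      normalize = function(x) {
        shift <- suppressWarnings(as.numeric(x))
        ref <- c(phospho = 79.9663, ubiquitin = 114.0429, acetyl = 42.0106,
                 methyl = 14.0157, citrullination = 0.9840,
                 oxidation = 15.9949)
        idx <- vapply(shift, function(s) {
          if (is.na(s)) return(NA_integer_)
          d <- abs(ref - s)
          if (min(d) < 0.01) which.min(d) else NA_integer_
        }, integer(1))
        names(ref)[idx]
      })
  )
}

#' Read a per-engine PTM site table
#'
#' Positions are residue indices within the engine's search-database protein
#' (e.g. 0N4R local coordinates). Rows with an incompatible residue/mod pair
#' (phospho on S/T/Y, GlyGly/acetyl on K, methyl on K/R, citrullination on R,
#' oxidation on M), an unknown modification, or an ambiguous/non-integer
#' position are rejected and counted. Engine confidence filtering is assumed
#' already applied upstream.
#'
#' @param path CSV (`.csv`) or TSV file in the engine's dialect.
#' @param engine Dialect name registered in [engine_dialects()].
#' @return Data frame of class `site_observations`: `engine`, `sample_id`,
#'   `peptide`, `local_position`, `residue`, `mod_type`; attribute `rejected`.
#' @export
read_engine_sites <- function(path, engine) {
  dialects <- engine_dialects()
  if (!engine %in% names(dialects)) {
    stop("unknown engine dialect: '", engine, "'")
  }
  d <- dialects[[engine]]
  sep <- if (grepl("\\.csv$", path, TRUE)) "," else "\t"
  # colClasses: an all-"T" residue column must not become logical
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  missing <- setdiff(unname(d$columns), names(raw))
  if (length(missing)) {
    stop("engine table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  pos_raw <- as.character(raw[[d$columns["local_position"]]])
  pos <- suppressWarnings(as.integer(pos_raw))
  ambiguous <- is.na(pos) | pos != suppressWarnings(as.numeric(pos_raw))
  df <- data.frame(engine = engine,
                   sample_id = as.character(raw[[d$columns["sample_id"]]]),
                   peptide = as.character(raw[[d$columns["peptide"]]]),
                   local_position = pos,
                   residue = toupper(as.character(raw[[d$columns["residue"]]])),
                   mod_type = d$normalize(as.character(raw[[d$columns["mod_type"]]])),
                   stringsAsFactors = FALSE)
  compatible <- mapply(function(m, r) {
    !is.na(m) && r %in% MOD_RESIDUES[[m]]
  }, df$mod_type, df$residue)
  bad <- ambiguous | !compatible
  if (any(bad)) {
    message("read_engine_sites[", engine, "]: rejected ", sum(bad),
            " row(s) (ambiguous position or residue/mod incompatibility)")
  }
  df <- df[!bad, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, rejected = sum(bad),
            class = c("site_observations", "data.frame"))
}

#' Display name of a PTM site in canonical numbering
#'
#' Field convention: modification prefix (p, ub, ac, me, c, ox) + residue +
#' canonical 2N4R position, e.g. `pT212`, `cR155`.
#'
#' @param mod_type,residue,canonical_position Vectors of equal length.
#' @return Character vector of display names.
#' @export
site_display_name <- function(mod_type, residue, canonical_position) {
  paste0(MOD_PREFIX[mod_type], residue, canonical_position)
}

#' Map engine site observations to canonical 2N4R sites
#'
#' Local positions are validated against the search-database isoform (residue
#' at the position must match the reported residue) and mapped to canonical
#' 2N4R numbering via the isoform's coordinate map. Unmappable or mismatching
#' rows are rejected with a log.
#'
#' @param obs `site_observations` from [read_engine_sites()].
#' @param database_isoform `tau_isoform` the engine searched against (e.g.
#'   `load_isoform("0N4R-P301S")`).
#' @return Data frame: `site`, `canonical_position`, `residue`, `mod_type`,
#'   `sample_id`, `engine`; attribute `rejected`.
#' @export
to_canonical_sites <- function(obs, database_isoform) {
  stopifnot(inherits(database_isoform, "tau_isoform"))
  df <- as.data.frame(obs)
  n <- nchar(database_isoform$sequence)
  ok_pos <- !is.na(df$local_position) & df$local_position >= 1 &
    df$local_position <= n
  seq_res <- rep(NA_character_, nrow(df))
  seq_res[ok_pos] <- substring(database_isoform$sequence,
                               df$local_position[ok_pos],
                               df$local_position[ok_pos])
  ok <- ok_pos & seq_res == df$residue
  if (any(!ok)) {
    message("to_canonical_sites: rejected ", sum(!ok),
            " observation(s) (position out of range or residue mismatch)")
  }
  df <- df[which(ok), , drop = FALSE]
  canon <- database_isoform$canonical_map[df$local_position]
  out <- data.frame(site = site_display_name(df$mod_type, df$residue, canon),
                    canonical_position = canon, residue = df$residue,
                    mod_type = df$mod_type, sample_id = df$sample_id,
                    engine = df$engine, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, rejected = sum(!ok))
}

#' Site-by-condition replicate frequency matrix
#'
#' A site counts in a biological replicate if any engine reports it there
#' (union across engines); the frequency of a site in a condition is the
#' fraction of that condition's replicates (taken from the metadata, not from
#' the observations) with at least one observation.
#'
#' @param sites Canonical site table from [to_canonical_sites()] (rows may
#'   come from several engines; they are pooled).
#' @param meta Sample metadata with `sample_id`, the grouping columns and
#'   `replicate`.
#' @param grouping Metadata columns defining a condition (default
#'   model/region/time).
#' @return Object of class `ptm_site_matrix`: list with `frequency` matrix
#'   (sites x conditions), `sites` (site info), `conditions` (data frame,
#'   ordered by the grouping columns), `n_replicates` per condition.
#' @export
site_frequency <- function(sites, meta,
                           grouping = c("model", "region", "time")) {
  stopifnot(all(grouping %in% names(meta)), "sample_id" %in% names(meta))
  unknown <- setdiff(unique(sites$sample_id), meta$sample_id)
  if (length(unknown)) {
    stop("site observations reference sample(s) without metadata: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  meta <- meta[do.call(order, meta[grouping]), , drop = FALSE]
  cond_of <- function(df) {
    do.call(paste, c(df[grouping], sep = "|"))
  }
  meta$condition <- cond_of(meta)
  conditions <- unique(meta[, c(grouping, "condition")])
  n_rep <- vapply(split(meta$sample_id, meta$condition)[conditions$condition],
                  function(x) length(unique(x)), integer(1))
  if (any(n_rep == 0)) {
    warning("excluding condition(s) with 0 replicates")
    keep <- n_rep > 0
    conditions <- conditions[keep, , drop = FALSE]
    n_rep <- n_rep[keep]
  }
  site_info <- unique(sites[, c("site", "canonical_position", "residue",
                                "mod_type")])
  site_info <- site_info[order(site_info$canonical_position,
                               site_info$mod_type), , drop = FALSE]
  rownames(site_info) <- NULL
  obs <- unique(data.frame(site = sites$site,
                           sample_id = sites$sample_id,
                           stringsAsFactors = FALSE))
  obs$condition <- meta$condition[match(obs$sample_id, meta$sample_id)]
  freq <- matrix(0, nrow = nrow(site_info), ncol = nrow(conditions),
                 dimnames = list(site_info$site, conditions$condition))
  if (nrow(obs)) {
    tab <- table(obs$site, obs$condition)
    freq[rownames(tab), colnames(tab)[colnames(tab) %in% colnames(freq)]] <-
      tab[, colnames(tab) %in% colnames(freq), drop = FALSE]
  }
  freq <- sweep(freq, 2, n_rep[colnames(freq)], "/")
  structure(list(frequency = freq, sites = site_info,
                 conditions = conditions, n_replicates = n_rep,
                 grouping = grouping),
            class = "ptm_site_matrix")
}

#' Binary presence/absence PTM matrix at a replicate-frequency threshold
#'
#' A site is present in a condition when its replicate frequency is `>=`
#' threshold (inclusive boundary; the published filter is ">= 50% of the
#' biological replicates").
#'
#' @param freq A `ptm_site_matrix` from [site_frequency()].
#' @param threshold Frequency threshold in (0, 1]; default 0.5.
#' @param drop_empty Drop sites absent in every condition (default `TRUE`).
#' @return A `ptm_site_matrix` with an additional `binary` 0/1 matrix and the
#'   `threshold` recorded; `sites`/`frequency` are subset in step when
#'   `drop_empty`.
#' @export
binary_ptm_matrix <- function(freq, threshold = 0.5, drop_empty = TRUE) {
  stopifnot(inherits(freq, "ptm_site_matrix"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  bin <- (freq$frequency >= threshold) * 1L
  if (drop_empty) {
    keep <- rowSums(bin) > 0
    bin <- bin[keep, , drop = FALSE]
    freq$frequency <- freq$frequency[keep, , drop = FALSE]
    freq$sites <- freq$sites[keep, , drop = FALSE]
  }
  freq$binary <- bin
  freq$threshold <- threshold
  freq
}

#' @export
print.ptm_site_matrix <- function(x, ...) {
  cat("<ptm_site_matrix> ", nrow(x$frequency), " sites x ",
      ncol(x$frequency), " conditions",
      if (!is.null(x$binary)) paste0(" (binary, threshold ", x$threshold, ")"),
      "\n", sep = "")
  invisible(x)
}
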