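# In-silico tryptic digestion in canonical coordinates, peptide specificity
# classification, and the default quantification panel.

#' FLEX reporter peptide sequence
#'
#' The light synthetic spike of this reporter calibrates the amount of heavy
#' full-length Tau standard in each sample.
#' @export
FLEX_TAG <- "SENLYFQGDISR"

#' Trypsin cleavage rule
#'
#' Cleaves C-terminal of K/R; cleavage is suppressed when the next residue is
#' proline (so e.g. HVPGGGSVQIVYKPVDLSK is a fully tryptic peptide).
#'
#' @param max_missed Maximum number of missed cleavages to enumerate.
#' @param cleave_after,blocked_by_next Residue sets of the rule.
#' @return An `enzyme_rule` list.
#' @export
trypsin_rule <- function(max_missed = 0, cleave_after = c("K", "R"),
                         blocked_by_next = "P") {
  stopifnot(max_missed >= 0)
  structure(list(cleave_after = cleave_after,
                 blocked_by_next = blocked_by_next,
                 max_missed = as.integer(max_missed)),
            class = "enzyme_rule")
}

# cleavage points after position i of a plain sequence (character vector ok)
cleavage_sites <- function(res, rule) {
  n <- length(res)
  if (n == 0) return(integer(0))
  cand <- which(res %in% rule$cleave_after)
  cand <- cand[cand < n]
  blocked <- res[cand + 1] %in% rule$blocked_by_next
  cand[!blocked]
}

digest_sequence <- function(sequence, rule) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n == 0) {
    return(data.frame(peptide = character(0), local_start = integer(0),
                      local_end = integer(0), missed_cleavages = integer(0)))
  }
  cuts <- c(0L, cleavage_sites(res, rule), n)
  starts0 <- cuts[-length(cuts)] + 1L
  ends0 <- cuts[-1]
  out <- list()
  k <- length(starts0)
  for (mc in 0:rule$max_missed) {
    if (mc + 1 > k) break
    i <- seq_len(k - mc)
    out[[mc + 1]] <- data.frame(
      local_start = starts0[i], local_end = ends0[i + mc],
      missed_cleavages = mc)
  }
  df <- do.call(rbind, out)
  df$peptide <- substring(sequence, df$local_start, df$local_end)
  df[order(df$local_start, df$local_end),
     c("peptide", "local_start", "local_end", "missed_cleavages")]
}

#' Tryptic digest of a Tau isoform in canonical coordinates
#'
#' At 0 missed cleavages the peptides tile the sequence without gaps; with
#' `max_missed > 0` all contiguous concatenations up to the limit are added.
#' `start`/`end` are 1-based inclusive canonical 2N4R positions of the first
#' and last residue present in the canonical sequence.
#'
#' @param iso A `tau_isoform`.
#' @param rule An `enzyme_rule`, default [trypsin_rule()].
#' @return Data frame with columns `peptide`, `start`, `end`, `local_start`,
#'   `local_end`, `missed_cleavages`.
#' @examples
#' d <- digest(load_isoform("2N4R"))
#' d[d$start == 396, ]  # SPVVSGDTSPR, 396-406
#' @export
digest <- function(iso, rule = trypsin_rule()) {
  stopifnot(inherits(iso, "tau_isoform"), inherits(rule, "enzyme_rule"))
  df <- digest_sequence(iso$sequence, rule)
  df$start <- iso$canonical_map[df$local_start]
  df$end <- iso$canonical_map[df$local_end]
  rownames(df) <- NULL
  df[, c("peptide", "start", "end", "local_start", "local_end",
         "missed_cleavages")]
}

#' Classify a peptide's species/isoform specificity
#'
#' Membership is decided against tryptic digests (same rule, missed cleavages
#' up to `rule$max_missed`) of the configured sequence set. A peptide is
#' `shared` when present in both the human transgene and mouse digests,
#' `mutant_specific` when present only in the mutated human transgene (absent
#' from the un-mutated human sequence and from mouse), `flex_tag` when equal
#' to the FLEX reporter.
#'
#' @param peptide Character vector of peptide sequences.
#' @param species_set Named list with elements `human` (the transgene
#'   `tau_isoform`, possibly mutated) and `mouse`.
#' @param rule Digestion rule used for membership (default trypsin, up to 2
#'   missed cleavages).
#' @param flex The FLEX reporter sequence.
#' @return Character vector over `shared`, `human_specific`, `mouse_specific`,
#'   `mutant_specific`, `flex_tag`; `NA` if in no digest.
#' @export
classify_peptide <- function(peptide, species_set,
                             rule = trypsin_rule(max_missed = 2),
                             flex = FLEX_TAG) {
  stopifnot(all(c("human", "mouse") %in% names(species_set)))
  human <- species_set$human
  mouse <- species_set$mouse
  human_pep <- digest(human, rule)$peptide
  mouse_pep <- digest(mouse, rule)$peptide
  if (nrow(human$mutations)) {
    wt <- human
    for (i in seq_len(nrow(human$mutations))) {
      wt <- apply_mutation(wt, paste0(human$mutations$alt[i],
                                      human$mutations$canonical_position[i],
                                      human$mutations$ref[i]))
    }
    wt_pep <- digest(wt, rule)$peptide
  } else {
    wt_pep <- human_pep
  }
  vapply(peptide, function(p) {
    if (p == flex) return("flex_tag")
    in_h <- p %in% human_pep
    in_m <- p %in% mouse_pep
    in_wt <- p %in% wt_pep
    if (in_h && in_m) "shared"
    else if (in_h && !in_wt) "mutant_specific"
    else if (in_h || in_wt) "human_specific"
    else if (in_m) "mouse_specific"
    else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Default quantification panel
#'
#' Fully tryptic canonical 2N4R peptides of length `min_len`-`max_len`, plus
#' the FLEX reporter and, when the transgene carries a mutation, the
#' mutant-specific spiked peptide covering it. The published assay quantified
#' 18 Tau peptides without listing them; this default is broader and
#' user-overridable rather than a guess at the exact panel.
#'
#' @param transgene `tau_isoform` of the expressed human transgene (e.g.
#'   `load_isoform("0N4R-P301S")`). Panel rows absent from its digest (e.g.
#'   2N-insert peptides for a 0N transgene) are kept but flagged
#'   `in_transgene = FALSE`; mutated intervals carry the transgene form.
#' @param species_set Passed to [classify_peptide()]; defaults to the
#'   transgene plus the vendored mouse surrogate.
#' @param min_len,max_len Peptide length bounds.
#' @return Data frame: `interval` (e.g. "195-209"), `peptide`, `start`, `end`,
#'   `specificity`, `heavy_source` ("standard" for peptides of the heavy 2N4R
#'   standard, "spike" for synthetic heavy spikes), `in_transgene`.
#' @export
default_panel <- function(transgene = load_isoform("2N4R"),
                          species_set = list(human = transgene,
                                             mouse = load_isoform("mouse")),
                          min_len = 6, max_len = 32) {
  canon <- load_isoform("2N4R")
  d <- digest(canon, trypsin_rule())
  len <- nchar(d$peptide)
  d <- d[len >= min_len & len <= max_len, ]
  tg <- digest(transgene, trypsin_rule())
  # replace peptides whose sequence differs in the transgene (mutation) by the
  # transgene form; the canonical interval is unchanged
  for (i in seq_len(nrow(d))) {
    hit <- tg$start == d$start[i] & tg$end == d$end[i]
    if (any(hit)) d$peptide[i] <- tg$peptide[which(hit)[1]]
  }
  d$in_transgene <- d$peptide %in% tg$peptide
  d$specificity <- classify_peptide(d$peptide, species_set)
  d$heavy_source <- ifelse(d$specificity %in% "mutant_specific",
                           "spike", "standard")
  flex <- data.frame(peptide = FLEX_TAG, start = NA_integer_,
                     end = NA_integer_, local_start = NA_integer_,
                     local_end = NA_integer_, missed_cleavages = 0L,
                     in_transgene = FALSE, specificity = "flex_tag",
                     heavy_source = "standard")
  out <- rbind(d, flex)
  out$interval <- ifelse(is.na(out$start), "FLEX",
                         paste0(out$start, "-", out$end))
  rownames(out) <- NULL
  out[, c("interval", "peptide", "start", "end", "missed_cleavages",
          "specificity", "heavy_source", "in_transgene")]
}

#' Write a digest or panel table as TSV
#' @param x Data frame from [digest()] or [default_panel()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_digest_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
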