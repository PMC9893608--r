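# Tau isoform sequence model: named isoforms, canonical 2N4R numbering,
# cross-isoform coordinate maps, and point mutations.

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Path to the vendored Tau isoform FASTA
#'
#' Contains human 2N4R (P10636-8, 441 aa, defines canonical numbering), human
#' 0N4R (P10636-6, 383 aa, lacks canonical 45-102), and a clearly labelled
#' synthetic mouse-like surrogate (430 aa; the true mouse sequence is not
#' vendored, see the package vignette).
#'
#' @return File path of the FASTA shipped in `inst/extdata`.
#' @export
tau_isoform_fasta <- function() {
  system.file("extdata", "tau_isoforms.fasta", package = "flexitau",
              mustWork = TRUE)
}

# parse "45-102,200-210" into an integer vector of canonical positions
parse_ranges <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  unlist(lapply(parts, function(p) {
    ab <- as.integer(strsplit(trimws(p), "-", fixed = TRUE)[[1]])
    if (length(ab) == 1) ab else seq(ab[1], ab[2])
  }))
}

isoform_structure <- function() {
  path <- system.file("extdata", "isoform_structure.tsv", package = "flexitau",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
}

new_tau_isoform <- function(name, sequence, canonical_map,
                            mutations = data.frame(canonical_position = integer(0),
                                                   ref = character(0),
                                                   alt = character(0))) {
  stopifnot(nchar(sequence) == length(canonical_map))
  if (any(diff(canonical_map) <= 0)) {
    stop("canonical_map must be strictly increasing")
  }
  res <- strsplit(sequence, "")[[1]]
  if (!all(res %in% AA_STANDARD)) {
    stop("sequence of '", name, "' contains non-standard residues: ",
         paste(unique(res[!res %in% AA_STANDARD]), collapse = ","))
  }
  structure(list(name = name, sequence = sequence,
                 canonical_map = as.integer(canonical_map),
                 mutations = mutations),
            class = "tau_isoform")
}

#' Load a Tau isoform with its canonical 2N4R coordinate map
#'
#' Isoform names are `"2N4R"`, `"0N4R"`, `"mouse"`, or `"0N4R-P301S"` /
#' `"0N4R-P301L"` (and analogous `<iso>-<mut>` forms), in which case the point
#' mutation is applied via [apply_mutation()]. The canonical map assigns every
#' residue its position in 2N4R (441-residue) numbering; for 2N4R it is the
#' identity.
#'
#' @param name Isoform identifier.
#' @param fasta Path to a FASTA with the isoform sequences
#'   (default: the vendored [tau_isoform_fasta()]).
#' @return A `tau_isoform` object: list with `name`, `sequence`,
#'   `canonical_map` (integer vector, one canonical position per residue) and
#'   `mutations` (data frame).
#' @examples
#' iso <- load_isoform("2N4R")
#' nchar(iso$sequence)  # 441
#' @export
load_isoform <- function(name, fasta = tau_isoform_fasta()) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  base <- parts[1]
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- vapply(strsplit(names(seqs), " "), `[`, "", 1)
  if (!base %in% ids) {
    stop("unknown isoform name: '", base, "' (have: ",
         paste(ids, collapse = ", "), ")")
  }
  sequence <- as.character(seqs[[match(base, ids)]])
  struct <- isoform_structure()
  row <- struct[struct$isoform == base, , drop = FALSE]
  absent <- if (nrow(row)) parse_ranges(row$absent_canonical[1]) else integer(0)
  canonical_map <- setdiff(seq_len(441), absent)
  if (length(canonical_map) != nchar(sequence)) {
    stop("structure table and sequence length disagree for '", base, "'")
  }
  iso <- new_tau_isoform(base, sequence, canonical_map)
  for (mut in parts[-1]) iso <- apply_mutation(iso, mut)
  iso
}

#' Apply a point mutation given in canonical 2N4R coordinates
#'
#' @param iso A `tau_isoform`.
#' @param spec Mutation string such as `"P301L"`: reference residue, canonical
#'   position, alternate residue.
#' @return A new `tau_isoform` with exactly one residue changed; the mutation
#'   is recorded in `$mutations` and appended to the name.
#' @examples
#' apply_mutation(load_isoform("0N4R"), "P301S")
#' @export
apply_mutation <- function(iso, spec) {
  stopifnot(inherits(iso, "tau_isoform"))
  m <- regmatches(spec, regexec("^([A-Z])([0-9]+)([A-Z])$", spec))[[1]]
  if (length(m) != 4) stop("malformed mutation spec: '", spec, "'")
  ref <- m[2]; pos <- as.integer(m[3]); alt <- m[4]
  if (ref == alt) stop("degenerate mutation '", spec, "': alt equals ref")
  local <- match(pos, iso$canonical_map)
  if (is.na(local)) {
    stop("canonical position ", pos, " is absent from isoform '", iso$name, "'")
  }
  have <- substr(iso$sequence, local, local)
  if (have != ref) {
    stop("reference mismatch at canonical ", pos, ": isoform has '", have,
         "', spec says '", ref, "'")
  }
  sequence <- iso$sequence
  substr(sequence, local, local) <- alt
  new_tau_isoform(paste0(iso$name, "-", spec), sequence, iso$canonical_map,
                  rbind(iso$mutations,
                        data.frame(canonical_position = pos, ref = ref,
                                   alt = alt)))
}

#' Map residue positions between isoforms via canonical numbering
#'
#' @param pos Integer vector of 1-based residue positions in `from_iso`.
#' @param from_iso,to_iso `tau_isoform` objects.
#' @return Integer vector of positions in `to_iso`; `NA` where the canonical
#'   position is absent from `to_iso` (never an error).
#' @examples
#' map_position(243, load_isoform("0N4R"), load_isoform("2N4R"))  # 301
#' @export
map_position <- function(pos, from_iso, to_iso) {
  stopifnot(inherits(from_iso, "tau_isoform"), inherits(to_iso, "tau_isoform"))
  pos <- as.integer(pos)
  if (any(pos < 1 | pos > length(from_iso$canonical_map), na.rm = TRUE)) {
    stop("position out of range for isoform '", from_iso$name, "'")
  }
  canon <- from_iso$canonical_map[pos]
  match(canon, to_iso$canonical_map)
}

#' @export
print.tau_isoform <- function(x, ...) {
  cat("<tau_isoform> ", x$name, ": ", nchar(x$sequence), " aa, canonical ",
      min(x$canonical_map), "-", max(x$canonical_map), sep = "")
  if (nrow(x$mutations)) {
    cat(" [", paste0(x$mutations$ref, x$mutations$canonical_position,
                     x$mutations$alt, collapse = ","), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}
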