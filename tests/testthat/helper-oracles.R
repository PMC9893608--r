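# Independent oracles: implementations deliberately different in style from
# the package code paths they check.

# brute-force trypsin digestion via regex marker insertion: cut after K/R not
# followed by P
oracle_digest <- function(sequence) {
  if (!nchar(sequence)) return(character(0))
  marked <- gsub("(?<=[KR])(?!P)", "\n", sequence, perl = TRUE)
  strsplit(marked, "\n", fixed = TRUE)[[1]]
}

# naive complete-linkage agglomeration over explicit membership lists,
# recomputing every cluster-to-cluster distance from scratch each step
oracle_complete_linkage_heights <- function(m) {
  D <- as.matrix(dist(m))
  members <- lapply(seq_len(nrow(m)), identity)
  heights <- numeric(0)
  while (length(members) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(members)) {
      for (j in seq_along(members)) {
        if (j <= i) next
        d <- max(D[members[[i]], members[[j]]])
        if (d < best) {
          best <- d; bi <- i; bj <- j
        }
      }
    }
    heights <- c(heights, best)
    members[[bi]] <- c(members[[bi]], members[[bj]])
    members[[bj]] <- NULL
  }
  heights
}

random_aa_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# expected temporal category per site from a planted presence matrix
oracle_temporal <- function(present_mat, times, onset) {
  out <- character(0)
  for (i in seq_len(nrow(present_mat))) {
    z <- present_mat[i, ]
    if (!any(z)) next
    out[rownames(present_mat)[i]] <- if (all(z)) {
      "all_timepoints"
    } else {
      t1 <- times[which(z)[1]]
      if (t1 < onset) "pre_onset"
      else if (t1 == onset) "concomitant_with_onset"
      else "post_onset"
    }
  }
  out
}

# partition signature at k groups: order-independent canonical form
partition_signature <- function(hc, k) {
  ct <- stats::cutree(hc, k = k)
  groups <- split(names(ct), ct)
  groups <- lapply(groups, sort)
  paste(sort(vapply(groups, paste, "", collapse = ",")), collapse = ";")
}
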