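write_pp_sites <- function(path, rows) {
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

pp_row <- function(sample_id = "s1", peptide = "TPSLPTPPTR", position = 154,
                   residue = "T", mod_type = "phospho") {
  data.frame(sample_id = sample_id, peptide = peptide, position = position,
             residue = residue, mod_type = mod_type,
             stringsAsFactors = FALSE)
}

test_that("read_engine_sites validates residues, positions and dialects", {
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- rbind(pp_row(residue = "S", position = 141),
                pp_row(residue = "T", position = 154),
                pp_row(residue = "K", position = 160))  # phospho on K: invalid
  write_pp_sites(f, rows)
  expect_message(obs <- read_engine_sites(f, "proteinpilot"), "rejected 1")
  expect_equal(nrow(obs), 2)
  expect_identical(attr(obs, "rejected"), 1L)
  # determinism
  obs2 <- suppressMessages(read_engine_sites(f, "proteinpilot"))
  expect_identical(as.data.frame(obs), as.data.frame(obs2))
  # ambiguous localization (position range) is rejected, counted
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_pp_sites(f2, rbind(pp_row(position = "154"),
                           pp_row(position = "154;157")))
  expect_message(obs3 <- read_engine_sites(f2, "proteinpilot"), "rejected 1")
  expect_equal(obs3$local_position, 154L)
  expect_error(read_engine_sites(f, "sequest"), "unknown engine")
})

test_that("engine dialects normalize to identical observations", {
  # the same pT212 site (0N4R local 154) in three dialects
  f_mq <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Raw file,Sequence,Modification,Amino acid,Position",
               "s1,TPSLPTPPTR,Phospho (STY),T,154"), f_mq)
  f_ma <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,pep_seq,mod,site_res,site_pos",
               "s1,TPSLPTPPTR,Phospho,T,154"), f_ma)
  f_fp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,peptide,mass_shift,residue,position",
               "s1,TPSLPTPPTR,79.9663,T,154"), f_fp)
  cols <- c("sample_id", "peptide", "local_position", "residue", "mod_type")
  mq <- as.data.frame(read_engine_sites(f_mq, "maxquant"))[, cols]
  ma <- as.data.frame(read_engine_sites(f_ma, "mascot"))[, cols]
  fp <- as.data.frame(read_engine_sites(f_fp, "fragpipe"))[, cols]
  expect_identical(mq, ma)
  expect_identical(mq, fp)
})

test_that("to_canonical_sites maps 0N4R local coordinates to 2N4R names", {
  iso <- load_isoform("0N4R-P301S")
  obs <- structure(data.frame(
    engine = "proteinpilot", sample_id = "s1",
    peptide = c("TPSLPTPPTR", "HVSGGGSVQIVYKPVDLSK", "TPPAPK"),
    local_position = c(154L, 243L, 117L),
    residue = c("T", "S", "T"),
    mod_type = c("phospho", "phospho", "phospho"),
    stringsAsFactors = FALSE), class = c("site_observations", "data.frame"))
  out <- to_canonical_sites(obs, iso)
  # local + 58 for local >= 45
  expect_identical(out$canonical_position, c(212L, 301L, 175L))
  expect_identical(out$site, c("pT212", "pS301", "pT175"))
  # identity map for a 2N4R database (local 212 is T in 2N4R numbering)
  obs212 <- obs[1, ]
  obs212$local_position <- 212L
  out2 <- to_canonical_sites(
    structure(obs212, class = c("site_observations", "data.frame")),
    load_isoform("2N4R"))
  expect_identical(out2$canonical_position, 212L)
  # residue mismatch against the database isoform is rejected
  bad <- obs
  bad$residue <- c("S", "S", "S")
  expect_message(out3 <- to_canonical_sites(bad, iso), "rejected 2")
  expect_equal(nrow(out3), 1)
})

toy_sites <- function(samples, site = "pT212", engine = "mascot") {
  data.frame(site = site, canonical_position = 212L, residue = "T",
             mod_type = "phospho", sample_id = samples, engine = engine,
             stringsAsFactors = FALSE)
}

toy_meta <- function(n = 6) {
  data.frame(sample_id = paste0("s", 1:n), model = "P301S",
             region = "cortex", time = 4, replicate = 1:n,
             stringsAsFactors = FALSE)
}

test_that("site_frequency implements replicate-level engine union", {
  meta <- toy_meta(6)
  # seen by one engine in replicates 1-3 of 6 -> frequency 0.5
  freq <- site_frequency(toy_sites(c("s1", "s2", "s3")), meta)
  expect_equal(unname(freq$frequency["pT212", ]), 0.5)
  # a second engine in the same replicate counts once
  both <- rbind(toy_sites(c("s1", "s2", "s3"), engine = "mascot"),
                toy_sites("s1", engine = "maxquant"))
  freq2 <- site_frequency(both, meta)
  expect_equal(unname(freq2$frequency["pT212", ]), 0.5)
  # engine-union monotonicity: adding observations never lowers a frequency
  more <- rbind(both, toy_sites("s4", engine = "maxquant"))
  freq3 <- site_frequency(more, meta)
  expect_true(all(freq3$frequency >= freq2$frequency))
  # unknown sample errors; site absent in another condition has frequency 0
  expect_error(site_frequency(toy_sites("nope"), meta), "without metadata")
  meta2 <- rbind(meta, within(toy_meta(6), {
    sample_id <- paste0("t", 1:6); time <- 5
  }))
  freq4 <- site_frequency(toy_sites(c("s1", "s2", "s3")), meta2)
  expect_equal(unname(freq4$frequency["pT212", "P301S|cortex|5"]), 0)
})

test_that("binary matrix uses an inclusive threshold and drops empty rows", {
  meta <- toy_meta(6)
  sites <- rbind(toy_sites(c("s1", "s2", "s3")),
                 toy_sites(c("s1", "s2"), site = "pS199"))
  freq <- site_frequency(sites, meta)
  bin <- binary_ptm_matrix(freq, threshold = 0.5)
  expect_equal(unname(bin$binary["pT212", ]), 1)       # 0.5 >= 0.5 inclusive
  expect_false("pS199" %in% rownames(bin$binary))      # 2/6 dropped
  bin2 <- binary_ptm_matrix(freq, threshold = 0.5, drop_empty = FALSE)
  expect_equal(unname(bin2$binary["pS199", ]), 0)
  # 2/5 replicates -> 0.4 -> absent
  freq5 <- site_frequency(toy_sites(c("s1", "s2")), toy_meta(5))
  expect_equal(unname(freq5$frequency["pT212", ]), 0.4)
  expect_false("pT212" %in%
                 rownames(binary_ptm_matrix(freq5)$binary))
  expect_error(binary_ptm_matrix(freq, threshold = 0), "threshold")
  expect_error(binary_ptm_matrix(freq, threshold = 1.2), "threshold")
  # threshold monotonicity: raising the threshold never adds a 1
  for (th in c(0.3, 0.6, 0.9)) {
    b_lo <- binary_ptm_matrix(freq, threshold = th, drop_empty = FALSE)
    b_hi <- binary_ptm_matrix(freq, threshold = min(th + 0.2, 1),
                              drop_empty = FALSE)
    expect_true(all(b_hi$binary <= b_lo$binary))
  }
})

test_that("emitted engine tables round-trip through the consensus module", {
  cfg <- small_scenario_config(replicates = 4, burden_cv = 0)
  sc <- simulate_scenario(cfg, seed = 21)
  dir <- withr::local_tempdir()
  emit_engine_site_tables(sc, dir, seed = 22)
  canon <- list()
  for (eng in c("mascot", "maxquant", "proteinpilot")) {
    obs <- read_engine_sites(file.path(dir, "sites", paste0(eng, ".csv")),
                             eng)
    canon[[eng]] <- to_canonical_sites(obs, load_isoform("0N4R-P301S"))
  }
  sites <- do.call(rbind, canon)
  expect_gt(nrow(sites), 0)
  freq <- site_frequency(sites, sc$samples)
  # idempotence: re-reading and re-combining yields the identical matrix
  sites2 <- do.call(rbind, lapply(names(canon), function(eng) {
    to_canonical_sites(
      suppressMessages(read_engine_sites(
        file.path(dir, "sites", paste0(eng, ".csv")), eng)),
      load_isoform("0N4R-P301S"))
  }))
  expect_identical(site_frequency(sites2, sc$samples)$frequency,
                   freq$frequency)
  # always-on sites have frequency 1 in every condition; the planted
  # never-detected control is absent everywhere
  expect_true(all(freq$frequency["pT181", ] == 1))
  expect_false("ubK290" %in% rownames(freq$frequency))
})
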