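test_that("peptide specs parse to the expected residue/repeat/phospho layout", {
  cases <- list(
    # spec string            residues repeats  phospho positions
    list(ctd_peptide_specs()[["NMR-1R"]], 11L, 1L, 7L),
    list("(YSPTSPS)",                      7L, 1L, integer(0)),
    list(ctd_peptide_specs()[["NMR-5R"]], 39L, 5L, c(7L, 35L)),
    list(ctd_peptide_specs()[["NMR-2R"]], 14L, 2L, c(5L, 12L)),
    list(ctd_peptide_specs()[["BLI-1R"]], 15L, 1L, 11L)
  )
  for (cs in cases) {
    p <- parse_peptide_spec(cs[[1]])
    expect_length(p$sequence, cs[[2]])
    expect_identical(p$n_repeats, cs[[3]])
    expect_identical(p$phospho_positions, cs[[4]])
  }
})

test_that("labels and caps are metadata, not residues", {
  p <- parse_peptide_spec(ctd_peptide_specs()[["FITC-1R"]])
  expect_identical(p$n_term_cap, "FITC-linker")
  expect_length(p$sequence, 11L)  # same residues as the unlabeled peptide
  b <- parse_peptide_spec(ctd_peptide_specs()[["BLI-1R"]])
  expect_identical(b$n_term_cap, "biotin-linker")
  # the spelled-out GGSGGS linker counts as ordinary residues
  expect_identical(paste(b$sequence[1:6], collapse = ""), "GGSGGS")
})

test_that("malformed specs raise named parse errors", {
  expect_error(parse_peptide_spec("AS(YSPTpSP)YS"), "6 residues")
  expect_error(parse_peptide_spec("AS(YSPTpSPSY)"), "8 residues")
  expect_error(parse_peptide_spec("AS(YSPTXSPS)YS"), "unknown residue 'X'|unknown residue letter 'X'")
  expect_error(parse_peptide_spec("AS(YSPTpTPS)YS"), "'p'")
  expect_error(parse_peptide_spec("ASYSPTSPS"), "no parenthesized")
  expect_error(parse_peptide_spec("AS(YSPT(pSPS)YS"), "nested")
})

test_that("parse -> serialize -> parse is the identity on the peptide panel", {
  for (nm in names(ctd_peptide_specs())) {
    spec <- ctd_peptide_specs()[[nm]]
    p <- parse_peptide_spec(spec, name = nm)
    expect_identical(format_peptide_spec(p), spec, label = nm)
    p2 <- parse_peptide_spec(format_peptide_spec(p), name = nm)
    expect_identical(p2$sequence, p$sequence)
    expect_identical(p2$phospho_positions, p$phospho_positions)
    expect_identical(p2$repeat_starts, p$repeat_starts)
  }
})

test_that("pSer-Pro motifs are located N-to-C and non-motif pSer warns", {
  m1 <- locate_psp_motifs(parse_peptide_spec(ctd_peptide_specs()[["NMR-1R"]]))
  expect_identical(m1$pser, 7L)
  expect_identical(m1$pro, 8L)

  m0 <- locate_psp_motifs(parse_peptide_spec("(YSPTSPS)(YSPTSPS)"))
  expect_identical(nrow(m0), 0L)

  m5 <- locate_psp_motifs(parse_peptide_spec(ctd_peptide_specs()[["NMR-5R"]]))
  expect_identical(m5$pser, c(7L, 35L))
  expect_identical(m5$pro, c(8L, 36L))

  # phospho-Ser7 has no trailing Pro: omitted with a warning record
  expect_warning(m <- locate_psp_motifs(parse_peptide_spec("(YSPTSPpS)")),
                 "not followed by Pro")
  expect_identical(nrow(m), 0L)
  expect_identical(attr(m, "omitted"), 7L)
})

test_that("motif spacing is the pSer index difference; 7(n-1) for terminal-phospho peptides", {
  expect_identical(motif_spacing(parse_peptide_spec(ctd_peptide_specs()[["NMR-5R"]])), 28L)
  expect_identical(motif_spacing(parse_peptide_spec(ctd_peptide_specs()[["NMR-2R"]])), 7L)
  expect_identical(motif_spacing(parse_peptide_spec(ctd_peptide_specs()[["NMR-1R"]])), NA_integer_)

  # build nR peptides with phospho on the Ser5 of the terminal repeats
  for (n in 2:5) {
    spec <- paste0("AS(YSPTpSPS)",
                   strrep("(YSPTSPS)", n - 2),
                   "(YSPTpSPS)YS")
    expect_identical(motif_spacing(parse_peptide_spec(spec)), 7L * (n - 1L),
                     label = paste0(n, "R"))
  }
})

test_that("extinction coefficient is 1280 per Tyr and linear in Tyr count", {
  expect_identical(extinction_coefficient(parse_peptide_spec("(SSPTSPS)")), 0)
  expect_identical(
    extinction_coefficient(parse_peptide_spec(ctd_peptide_specs()[["NMR-1R"]])),
    2560)
  expect_identical(
    extinction_coefficient(parse_peptide_spec(ctd_peptide_specs()[["NMR-5R"]])),
    7680)
  # linearity across the whole panel
  for (nm in names(ctd_peptide_specs())) {
    p <- parse_peptide_spec(ctd_peptide_specs()[[nm]])
    expect_identical(extinction_coefficient(p), 1280 * sum(p$sequence == "Y"),
                     label = nm)
  }
})
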