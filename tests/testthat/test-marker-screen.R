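test_that("canonical keys honour I/L equivalence", {
  expect_identical(peptide_key("LAILENANVLAR"), peptide_key("IAILENANVIAR"))
  expect_identical(peptide_key("PEPTIDE", equate_il = FALSE), "PEPTIDE")
  expect_identical(peptide_key("IL"), peptide_key("LI"))
  expect_false(peptide_key("IL", equate_il = FALSE) ==
                 peptide_key("LI", equate_il = FALSE))
})

# small hand-built two-species proteome: one planted unique peptide per
# species, one peptide shared by both
toy_proteins <- function() {
  data.frame(
    id = c("a1", "a2", "b1"),
    species = c("A", "A", "B"),
    sequence = c(
      paste0("GGGK", "VAEISDGDIFQYK", "AAAR"),          # unique to A
      paste0("TTTR", "SHEDPEPTIDEGGK", "GGK"),          # shared
      paste0("CCCK", "SHEDPEPTIDEGGK", "WNTDGSTDYGIFQINSR")  # unique to B
    ), stringsAsFactors = FALSE)
}

test_that("index maps planted peptides to the right species sets", {
  peps <- digest_collection(toy_proteins(), max_missed = 0)
  idx <- build_index(peps)
  rep_u <- specificity_report(idx, "VAEISDGDIFQYK")
  expect_equal(rep_u$n_proteins[rep_u$species == "A"], 1L)
  expect_equal(rep_u$n_proteins[rep_u$species == "B"], 0L)
  rep_s <- specificity_report(idx, "SHEDPEPTIDEGGK")
  expect_true(all(rep_s$n_proteins >= 1L))
  rep_a <- specificity_report(idx, "NOTPRESENTK")
  expect_true(all(rep_a$n_proteins == 0L))
  # a single species is refused: uniqueness is undefined
  one <- peps[peps$species == "A", ]
  expect_error(build_index(one), ">= 2 species")
})

test_that("species-specific screening returns exactly the planted markers", {
  peps <- digest_collection(toy_proteins(), max_missed = 0)
  idx <- build_index(peps)
  mA <- find_species_specific(idx, peps, "A")
  expect_equal(mA$sequence, "VAEISDGDIFQYK")
  mB <- find_species_specific(idx, peps, "B")
  expect_equal(mB$sequence, "WNTDGSTDYGIFQINSR")
  expect_error(find_species_specific(idx, peps, "C"), "not present")
  # shared peptide is never a marker for either species
  expect_false("SHEDPEPTIDEGGK" %in% c(mA$sequence, mB$sequence))
})

test_that("marker filter gates length, methionine and missed cleavages", {
  prots <- data.frame(
    id = c("a1", "b1"), species = c("A", "B"),
    sequence = c(paste0("GGGK", "SHORTK", "VAEMSDGDIFQYK", "DDDGSIENSEVK"),
                 "GGGKAAAR"),
    stringsAsFactors = FALSE)
  peps <- digest_collection(prots, max_missed = 2)
  idx <- build_index(peps)
  m <- find_species_specific(idx, peps, "A")
  # SHORTK: 6 < 9 residues; VAEMSDGDIFQYK: contains M; concatenations:
  # missed cleavages > 0; only the clean 12-mer survives
  expect_equal(m$sequence, "DDDGSIENSEVK")
  # allowing Met back in admits the M-bearing peptide
  m2 <- find_species_specific(idx, peps, "A",
                              marker_filter(exclude_residues = character(0)))
  expect_setequal(m2$sequence, c("DDDGSIENSEVK", "VAEMSDGDIFQYK"))
})

test_that("I/L twins across species disqualify a marker when equated", {
  prots <- data.frame(
    id = c("a1", "b1"), species = c("A", "B"),
    sequence = c(paste0("GGGK", "AVILENANVAGTK"),
                 paste0("TTTR", "AVLIENANVAGTK")),   # I/L-swapped twin
    stringsAsFactors = FALSE)
  peps <- digest_collection(prots, max_missed = 0)
  idx_on <- build_index(peps, equate_il = TRUE)
  m_on <- find_species_specific(idx_on, peps, "A",
                                marker_filter(equate_il = TRUE))
  expect_false("AVILENANVAGTK" %in% m_on$sequence)
  idx_off <- build_index(peps, equate_il = FALSE)
  m_off <- find_species_specific(idx_off, peps, "A",
                                 marker_filter(equate_il = FALSE))
  expect_true("AVILENANVAGTK" %in% m_off$sequence)
})

test_that("uniqueness agrees with the brute-force dictionary oracle", {
  sim <- make_toy_proteomes(proteome_spec(n_species = 4, n_proteins = 10,
                                          seed = 77))
  peps <- digest_collection(sim$proteins, max_missed = 2)
  for (il in c(TRUE, FALSE)) {
    idx <- build_index(peps, equate_il = il)
    uniq_keys <- oracle_unique_keys(peps, equate_il = il)
    for (sp in unique(sim$proteins$species)) {
      got <- find_species_specific(idx, peps, sp,
                                   marker_filter(equate_il = il))
      # oracle: unique keys of this species whose source rows pass the
      # hand-applied filter
      sp_rows <- peps[peps$species == sp, ]
      pass <- vapply(seq_len(nrow(sp_rows)), function(i)
        oracle_passes_filter(sp_rows[i, ]), logical(1))
      want <- unique(sp_rows$sequence[pass &
        peptide_key(sp_rows$sequence, il) %in% uniq_keys])
      expect_setequal(got$sequence, want)
    }
  }
})

test_that("tightening the filter never enlarges the marker set", {
  sim <- make_toy_proteomes(proteome_spec(n_species = 3, n_proteins = 8,
                                          seed = 5))
  peps <- digest_collection(sim$proteins, max_missed = 2)
  idx <- build_index(peps)
  base <- find_species_specific(idx, peps, "sp1", marker_filter())
  tighter <- list(
    marker_filter(min_len = 11),
    marker_filter(max_len = 14),
    marker_filter(exclude_residues = c("M", "C", "W"))
  )
  for (f in tighter) {
    m <- find_species_specific(idx, peps, "sp1", f)
    expect_true(all(m$sequence %in% base$sequence))
  }
  # I/L equivalence only ever removes markers
  idx_off <- build_index(peps, equate_il = FALSE)
  m_off <- find_species_specific(idx_off, peps, "sp1",
                                 marker_filter(equate_il = FALSE))
  expect_true(all(base$sequence %in% m_off$sequence))
})

test_that("strict substring mode rejects homologous context", {
  prots <- data.frame(
    id = c("a1", "b1"), species = c("A", "B"),
    # B carries the A marker embedded without tryptic flanks
    sequence = c(paste0("GGGK", "VAEISDGDIFQYK"),
                 paste0("TTT", "VAEISDGDIFQYKW", "AAAR")),
    stringsAsFactors = FALSE)
  peps <- digest_collection(prots, max_missed = 0)
  idx <- build_index(peps)
  loose <- find_species_specific(idx, peps, "A")
  expect_true("VAEISDGDIFQYK" %in% loose$sequence)
  strict <- find_species_specific(idx, peps, "A", strict_substring = TRUE,
                                  proteins = prots)
  expect_false("VAEISDGDIFQYK" %in% strict$sequence)
  expect_error(find_species_specific(idx, peps, "A",
                                     strict_substring = TRUE),
               "protein data.frame")
})

test_that("empirical intensities order markers, unknowns last", {
  markers <- data.frame(species = "A",
                        sequence = c("AAAK", "CCCK", "DDDK"),
                        stringsAsFactors = FALSE)
  ints <- data.frame(sequence = c("AAAK", "DDDK"),
                     intensity = c(10, 500), stringsAsFactors = FALSE)
  r <- rank_markers(markers, ints)
  expect_equal(r$sequence, c("DDDK", "AAAK", "CCCK"))
  expect_true(is.na(r$intensity[3]))
})
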