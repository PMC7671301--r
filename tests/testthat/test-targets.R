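# Antisense-element target prediction: planted-guide recovery, rule gates,
# oracle equivalence, function classification.

test_that("planted C/D guides recover exactly their planted residue", {
  set.seed(201)
  targets <- test_targets()
  for (k in 1:6) {
    kind <- c("rRNA", "snRNA", "dual")[1L + (k %% 3)]
    p <- planted_cd(targets, kind)
    ann <- scan_cd(p$seq, flank = 15L)
    hits <- find_cd_targets(ann, p$seq, targets, locus_id = "x")
    expect_true(any(hits$guide_box == "D" &
                      hits$target_molecule_id == p$loc$target_molecule_id &
                      hits$predicted_residue == p$loc$target_position))
    if (kind == "dual") {
      expect_true(any(hits$guide_box == "Dprime" &
                        hits$target_molecule_id == p$loc$target2_molecule_id &
                        hits$predicted_residue == p$loc$target2_position))
    }
    expect_true(all(hits$modification == "Nm"))
    expect_true(all(hits$duplex_length >= 10L))
    expect_true(all(hits$wobble_count <= 2L))
  }
})

test_that("planted orphans yield no target matches", {
  set.seed(202)
  targets <- test_targets()
  p <- planted_cd(targets, "orphan")
  ann <- scan_cd(p$seq, flank = 15L)
  expect_identical(nrow(find_cd_targets(ann, p$seq, targets)), 0L)
  ph <- planted_haca(targets, "orphan")
  annh <- scan_haca(ph$mature)
  expect_identical(nrow(find_haca_targets(annh, ph$mature, targets)), 0L)
})

test_that("planted H/ACA pockets recover the planted pseudouridine", {
  set.seed(203)
  targets <- test_targets()
  for (k in 1:6) {
    kind <- c("rRNA", "snRNA", "dual")[1L + (k %% 3)]
    p <- planted_haca(targets, kind)
    ann <- scan_haca(p$mature)
    hits <- find_haca_targets(ann, p$mature, targets, locus_id = "x")
    expect_true(any(hits$guide_box == "pocket1" &
                      hits$target_molecule_id == p$loc$target_molecule_id &
                      hits$predicted_residue == p$loc$target_position))
    expect_true(all(hits$modification == "Psi"))
    ## every predicted residue is a target uridine
    for (i in seq_len(nrow(hits))) {
      t <- targets$sequence[targets$molecule_id == hits$target_molecule_id[i]]
      expect_identical(substr(t, hits$predicted_residue[i],
                              hits$predicted_residue[i]), "T")
    }
  }
})

test_that("guide duplex scan equals the all-substrings oracle", {
  set.seed(204)
  targets <- test_targets()
  for (k in 1:40) {
    s <- rand_dna(80)
    box <- 60L
    tg <- targets$sequence[1L + (k %% 2)]
    if (k %% 3 == 0) {       # plant an ASE so hits actually occur
      u <- sample(20:(nchar(tg) - 30), 1)
      substr(s, box - 12L, box - 1L) <-
        snoforge:::revcomp(substr(tg, u - 4L, u + 7L))
    }
    impl <- snoforge:::.resolve_hits(
      snoforge:::cpp_cd_duplex_scan(s, box, 20L, 2L, tg, 10L, 2L))
    orc <- oracle_cd_duplexes(s, box, tg)
    no <- if (is.null(orc)) 0L else nrow(orc)
    expect_identical(nrow(impl), no)
    if (no > 0L) {
      expect_true(all(as.matrix(orc[, colnames(impl)]) == impl))
    }
  }
})

test_that("bipartite pocket scan equals the brute-force oracle", {
  set.seed(205)
  targets <- test_targets()
  for (k in 1:40) {
    s <- rand_dna(60)
    pl <- c(9L, 15L); pr <- c(38L, 44L)
    tg <- targets$sequence[1L + (k %% 2)]
    if (k %% 3 == 0) {
      tch <- strsplit(tg, "")[[1]]
      us <- which(tch == "T")
      u <- sample(us[us > 15 & us < nchar(tg) - 15], 1)
      pks <- snoforge:::.haca_pockets(tg, u)
      substr(s, pl[1], pl[2]) <- pks$left
      substr(s, pr[1], pr[2]) <- pks$right
    }
    impl <- snoforge:::cpp_bipartite_scan(s, pl[1], pl[2], pr[1], pr[2],
                                          tg, 4L, 9L, FALSE)
    orc <- oracle_bipartite(s, pl, pr, tg)
    no <- if (is.null(orc)) 0L else nrow(orc)
    expect_identical(nrow(impl), no)
    if (no > 0L) expect_true(all(as.matrix(orc[, colnames(impl)]) == impl))
  }
})

test_that("every reported duplex position pairs in antisense register", {
  set.seed(206)
  targets <- test_targets()
  p <- planted_cd(targets, "rRNA")
  ann <- scan_cd(p$seq, flank = 15L)
  hits <- find_cd_targets(ann, p$seq, targets, locus_id = "x")
  g <- o_chars(p$seq)
  for (i in seq_len(nrow(hits))) {
    t <- o_chars(targets$sequence[targets$molecule_id ==
                                    hits$target_molecule_id[i]])
    L <- hits$duplex_length[i]
    for (k in 0:(L - 1L)) {
      a <- g[hits$guide_end[i] - k]
      b <- t[hits$target_start[i] + k]
      expect_true(o_pair(a, b))
      ## reverse-complementing both partners preserves pairing
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      expect_true(o_pair(comp[[b]], comp[[a]]))
    }
  }
})

test_that("raising the minimum duplex length never adds matches", {
  set.seed(207)
  targets <- test_targets()
  p <- planted_cd(targets, "dual")
  ann <- scan_cd(p$seq, flank = 15L)
  m10 <- find_cd_targets(ann, p$seq, targets, params = target_params())
  m12 <- find_cd_targets(ann, p$seq, targets,
                         params = target_params(min_duplex = 12L))
  expect_lte(nrow(m12), nrow(m10))
  key <- function(m) paste(m$guide_box, m$target_molecule_id, m$target_start)
  expect_true(all(key(m12) %in% key(m10)))
})

test_that("function classification follows the target kinds", {
  targets <- test_targets()
  mk <- function(mols) data.frame(target_molecule_id = mols)
  expect_identical(classify_function(mk("SSU_rRNA"), targets), "rRNA_guide")
  expect_identical(classify_function(mk("U2_snRNA"), targets), "snRNA_guide")
  expect_identical(classify_function(mk(c("SSU_rRNA", "U2_snRNA")), targets),
                   "dual")
  expect_identical(classify_function(mk(character(0)), targets), "orphan")
  expect_identical(classify_function(NULL, targets), "orphan")
})
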