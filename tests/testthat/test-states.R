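empty_regs <- function(tr) make_region(tr, 1)[0, , drop = FALSE]

test_that("the transition alphabet yields 15 pairs in 3 categories", {
  tp <- transition_pairs()
  expect_equal(nrow(tp), 15L)
  expect_false(any(tp$state_normal == "NONE" & tp$state_tumor == "NONE"))
  # hand-written category table from the grouping rule
  expected <- c(
    "K4 NONE" = "single_mark_change", "K27 NONE" = "single_mark_change",
    "BIV NONE" = "both_marks_change",
    "NONE K4" = "single_mark_change", "K4 K4" = "mark_kept",
    "K27 K4" = "both_marks_change", "BIV K4" = "single_mark_change",
    "NONE K27" = "single_mark_change", "K4 K27" = "both_marks_change",
    "K27 K27" = "mark_kept", "BIV K27" = "single_mark_change",
    "NONE BIV" = "both_marks_change", "K4 BIV" = "single_mark_change",
    "K27 BIV" = "single_mark_change", "BIV BIV" = "mark_kept")
  got <- vapply(seq_len(nrow(tp)), function(i)
    transition_category(tp$state_normal[i], tp$state_tumor[i]), character(1))
  expect_identical(got,
                   unname(expected[paste(tp$state_normal, tp$state_tumor)]))
  # the three categories partition the 15 pairs
  expect_equal(sort(as.integer(table(got))), c(3L, 4L, 8L))
  expect_equal(sum(table(got)), 15L)
  expect_error(transition_category("NONE", "NONE"), "not a transition")
})

test_that("bivalency requires 3 shared probes with 2 enriched", {
  pos <- seq(0, by = 35, length.out = 10)
  k4 <- make_track(pos, c(rep(8, 5), rep(0, 5)), mark = "K4")
  k27 <- make_track(pos, c(0, 0, rep(8, 5), 0, 0, 0), mark = "K27")
  k4r <- make_region(k4, 1:5, "k4_1")
  # shares probes 3,4,5 with the K4 region; enriched in both marks there
  k27r <- make_region(k27, 3:7, "k27_1")
  bv <- find_bivalent_regions(k4r, k27r, k4, k27)
  expect_equal(nrow(bv), 1L)
  expect_equal(bv$probe_idx[[1]], 3:5)
  expect_equal(bv$start, k4$start[3])
  expect_equal(bv$end, k4$end[5])
  # only 2 shared probes: not bivalent
  k27r2 <- make_region(k27, 4:8, "k27_2")
  expect_equal(nrow(find_bivalent_regions(k4r, k27r2, k4, k27)), 0L)
  # disjoint regions: not bivalent
  k27r3 <- make_region(k27, 6:8, "k27_3")
  expect_equal(nrow(find_bivalent_regions(k4r, k27r3, k4, k27)), 0L)
  # strict default needs enrichment in each mark; "either" relaxes it
  k27lo <- make_track(pos, c(0, 0, rep(5, 5), 0, 0, 0), mark = "K27")
  expect_equal(nrow(find_bivalent_regions(k4r, k27r, k4, k27lo)), 0L)
  expect_equal(nrow(find_bivalent_regions(
    k4r, k27r, k4, k27lo, state_params(biv_enriched_in = "either"))), 1L)
})

test_that("locus states reflect the present marks and bivalency", {
  pos <- seq(0, by = 35, length.out = 12)
  k4 <- make_track(pos, c(rep(8, 5), rep(0, 7)))
  k27 <- make_track(pos, c(0, 0, rep(8, 5), rep(0, 5)))
  k4r <- make_region(k4, 1:5, "k4_1")
  k27r <- make_region(k27, 3:7, "k27_1")
  regions_by <- list(normal = list(K4 = k4r, K27 = k27r),
                     tumor = list(K4 = empty_regs(k4),
                                  K27 = empty_regs(k27)))
  loci <- build_loci(regions_by)
  expect_equal(nrow(loci), 1L)
  bv <- find_bivalent_regions(k4r, k27r, k4, k27)
  st <- assign_locus_states(loci, bv, "normal")
  expect_equal(st$state, "BIV")
  expect_false(st$semi)
  # without a bivalent pair the two-mark locus is flagged semi
  st2 <- assign_locus_states(loci, bv[0, , drop = FALSE], "normal")
  expect_equal(st2$state, "K4+K27")
  expect_true(st2$semi)
  # the tumor condition contributes nothing: NONE
  st3 <- assign_locus_states(loci, bv[0, , drop = FALSE], "tumor")
  expect_equal(st3$state, "NONE")
  # single-mark locus
  regions_by2 <- list(normal = list(K4 = k4r, K27 = empty_regs(k27)),
                      tumor = list(K4 = empty_regs(k4),
                                   K27 = empty_regs(k27)))
  loci2 <- build_loci(regions_by2)
  expect_equal(assign_locus_states(loci2, bv[0, , drop = FALSE],
                                   "normal")$state, "K4")
})

test_that("transition classification applies support and delta-Z rules", {
  pos <- seq(0, by = 35, length.out = 10)
  none <- function(z = 0) make_track(pos, rep(z, 10))
  setup <- function(k4n_z, k4t_z, k4n_reg, k4t_reg) {
    tracks <- list(normal = list(K4 = make_track(pos, k4n_z), K27 = none()),
                   tumor = list(K4 = make_track(pos, k4t_z), K27 = none()))
    regions_by <- list(
      normal = list(K4 = k4n_reg(tracks$normal$K4),
                    K27 = empty_regs(none())),
      tumor = list(K4 = k4t_reg(tracks$tumor$K4), K27 = empty_regs(none())))
    loci <- build_loci(regions_by)
    nobiv <- find_bivalent_regions(empty_regs(none()), empty_regs(none()),
                                   none(), none())
    sn <- assign_locus_states(loci, nobiv, "normal")
    st <- assign_locus_states(loci, nobiv, "tumor")
    classify_transitions(loci, sn, st, tracks)
  }
  # identical K4 regions in both conditions: kept mark, resolved
  z <- c(0, 0, rep(8, 5), 0, 0, 0)
  reg <- function(tr) make_region(tr, 3:7, "r")
  t1 <- setup(z, z, reg, reg)
  expect_equal(t1$state_normal, "K4")
  expect_equal(t1$state_tumor, "K4")
  expect_equal(t1$category, "mark_kept")
  expect_equal(t1$status, "ok")
  # normal K4 with tumor Z dropping from 8 to 2: delta 6 >= 3, K4 lost
  t2 <- setup(z, rep(2, 10), reg, empty_regs)
  expect_equal(t2$state_tumor, "NONE")
  expect_equal(t2$category, "single_mark_change")
  expect_equal(t2$status, "ok")
  # normal max Z 6.2 vs tumor 5.8: delta 0.4 < 3, unresolved
  z62 <- c(0, 0, rep(6.2, 5), 0, 0, 0)
  t3 <- setup(z62, rep(5.8, 10), reg, empty_regs)
  expect_equal(t3$status, "unresolved")
  expect_true(is.na(t3$category))
  # kept mark without common enriched support is unresolved too
  zl <- c(rep(8, 3), rep(0, 7)); zr <- c(rep(0, 7), rep(8, 3))
  t4 <- setup(zl, zr, function(tr) make_region(tr, 1:3, "rl"),
              function(tr) make_region(tr, 8:10, "rr"))
  # separate loci: each is a one-sided change with delta 8
  expect_equal(nrow(t4), 2L)
  expect_true(all(t4$status == "ok"))
  # overlapping but shifted regions sharing < 3 probes: unresolved kept mark
  zs1 <- c(rep(8, 5), rep(0, 5)); zs2 <- c(rep(0, 4), 8, 8, 8, 8, 0, 0)
  t5 <- setup(zs1, zs2, function(tr) make_region(tr, 1:5, "a"),
              function(tr) make_region(tr, 5:8, "b"))
  expect_equal(t5$status, "unresolved")
})

test_that("identical condition data yields only kept marks", {
  p <- sim_params(noise_sd = 0.15)
  d <- generate_array_design(20, p, seed = 11)
  states <- c("K4", "K27", "BIV", rep("NONE", 17))
  truth <- plant_states(d, states, states, p)
  raw <- simulate_chip_experiment(d, truth, p, seed = 12)
  tracks <- list(); regions <- list(); biv <- list()
  for (cond in c("normal", "tumor")) {
    tracks[[cond]] <- list(); regions[[cond]] <- list()
    for (mark in c("K4", "K27")) {
      tracks[[cond]][[mark]] <- build_signal_track(d, raw[[cond]][[mark]],
                                                   mark = mark,
                                                   sample_label = cond)
      regions[[cond]][[mark]] <-
        call_enriched_regions(tracks[[cond]][[mark]])
    }
    biv[[cond]] <- find_bivalent_regions(regions[[cond]]$K4,
                                         regions[[cond]]$K27,
                                         tracks[[cond]]$K4,
                                         tracks[[cond]]$K27)
  }
  loci <- build_loci(regions)
  sn <- assign_locus_states(loci, biv$normal, "normal")
  st <- assign_locus_states(loci, biv$tumor, "tumor")
  tr <- classify_transitions(loci, sn, st, tracks)
  expect_gte(nrow(tr), 3L)
  expect_true(all(tr$status == "ok"))
  expect_true(all(tr$category == "mark_kept"))
  expect_setequal(unique(c(tr$state_normal, tr$state_tumor)),
                  c("K4", "K27", "BIV"))
})

test_that("footprints bin strand-aware offsets of the merged signal", {
  pos <- seq(0, by = 100, length.out = 10)
  tr <- make_track(pos, z = rep(0, 10), ratio = 1:10)
  anchors <- data.frame(chrom = "chr1", position = 500, strand = "+")
  fp <- footprint(tr, anchors, flank_bp = 300, bin_bp = 100)
  expect_equal(nrow(fp), 6L)
  # probe centers at pos + 12.5; those within +/-300 of 500 fall one per bin
  expect_equal(fp$mean, c(3, 4, 5, 6, 7, 8))
  expect_equal(fp$n_probes, rep(1L, 6))
  # minus strand reverses the profile
  anchors_m <- data.frame(chrom = "chr1", position = 500, strand = "-")
  fp_m <- footprint(tr, anchors_m, flank_bp = 300, bin_bp = 100)
  expect_equal(fp_m$mean, c(8, 7, 6, 5, 4, 3))
  # constant track gives a flat profile
  trc <- make_track(pos, z = rep(0, 10), ratio = rep(1.5, 10))
  fpc <- footprint(trc, anchors, flank_bp = 300, bin_bp = 100)
  expect_true(all(fpc$mean == 1.5))
  # empty bins are NA
  tr2 <- make_track(c(0, 1000), z = c(0, 0), ratio = c(1, 2))
  fp2 <- footprint(tr2, data.frame(chrom = "chr1", position = 100,
                                   strand = "+"), 500, 100)
  expect_true(any(is.na(fp2$mean)))
  expect_error(footprint(tr, anchors[0, ], 300, 100), "empty")
  expect_error(footprint(tr, anchors, 300, 90), "divide")
})

test_that("footprint of a symmetric signal is symmetric", {
  pos <- seq(0, by = 50, length.out = 41)
  # anchor midway between two probe centers so offsets avoid bin edges
  anchor <- pos[21] + 12.5 + 25
  ratio <- exp(-((pos + 12.5 - anchor) / 300)^2)
  tr <- make_track(pos, z = rep(0, 41), ratio = ratio)
  fp <- footprint(tr, data.frame(chrom = "chr1", position = anchor,
                                 strand = "+"), flank_bp = 500,
                  bin_bp = 100)
  expect_equal(fp$mean, rev(fp$mean), tolerance = 1e-10)
})
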