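# Primer design and in-silico PCR: Tm formulas, constraint checking, the
# exhaustive-enumeration oracle, the assay-table primer pair worked example,
# mismatch/clamp behaviour and strand symmetry.

ZEAE_F <- "CATGGCCGATATGCAGCATT"
ZEAE_R <- "GATCTGCCAGGTTCCATGAC"

test_that("Wallace rule Tm matches direct counts", {
  expect_equal(wallace_tm(ZEAE_F), 60)   # 10 GC, 10 AT
  expect_equal(wallace_tm(ZEAE_R), 62)   # 11 GC, 9 AT
  expect_equal(wallace_tm("AAAA"), 8)
  expect_error(wallace_tm(strrep("A", 31)), "30 nt")
  expect_error(wallace_tm("ACGN"), "unambiguous")
})

test_that("product Tm follows the salt-adjusted duplex formula", {
  # 128 bp at 50% GC, 50 mM Na+: 81.5 + 20.5 - 5.273 + 16.6*log10(0.05)
  s <- strrep("AT", 32) |> paste0(strrep("GC", 32))
  expect_equal(nchar(s), 128L)
  expect_equal(compute_gc(s), 0.5)
  expect_equal(product_tm(s, round = FALSE), 75.129, tolerance = 1e-3)
  expect_equal(product_tm(s), 75.0)
  # the linear GC term: +20 GC points -> +8.2 degrees at fixed N and salt
  s40 <- paste0(strrep("AT", 30), strrep("GC", 20))
  s60 <- paste0(strrep("AT", 20), strrep("GC", 30))
  expect_equal(product_tm(s60, round = FALSE) - product_tm(s40, round = FALSE),
               8.2, tolerance = 1e-9)
  # long-product, 1 M Na+ limit: 81.5 + 20.5 -> 102 as N grows
  expect_equal(product_tm(strrep("AT", 5e4) |> paste0(strrep("GC", 5e4)),
                          na_conc = 1, round = FALSE), 102, tolerance = 0.01)
  expect_error(product_tm(strrep("AT", 20)), "50 bp")
})

test_that("the published assay primers pass the primer-level constraints", {
  cn <- primer_constraints()
  expect_true(panmarker:::primer_ok(ZEAE_F, cn))
  expect_true(panmarker:::primer_ok(ZEAE_R, cn))
  expect_equal(nchar(ZEAE_F), 20L)
  expect_equal(compute_gc(ZEAE_F), 0.50)
  expect_equal(compute_gc(ZEAE_R), 0.55)
  # and obviously bad primers fail
  expect_false(panmarker:::primer_ok(strrep("A", 20), cn))    # homopolymer/GC
  expect_false(panmarker:::primer_ok("ACGTACGT", cn))         # too short
})

test_that("design enumerates exactly the compliant windows (oracle check)", {
  # background that cannot host a primer (AT-only fails GC), with one
  # engineered compliant region: F site + 90 nt insert + R binding site
  set.seed(61)
  insert <- rand_seq(90, gc = 0.5)
  bg <- function(n) paste(sample(c("A", "T"), n, TRUE), collapse = "")
  marker <- paste0(bg(150), ZEAE_F, insert, reverse_complement(ZEAE_R), bg(150))
  pairs <- design_primers(marker)
  expect_s3_class(pairs, "primer_set")
  # independent exhaustive oracle over all windows and pairings
  cn <- primer_constraints()
  wins <- list()
  for (len in 18:24) for (st in 1:(nchar(marker) - len + 1)) {
    w <- substr(marker, st, st + len - 1)
    for (dir in c("F", "R")) {
      p <- if (dir == "F") w else reverse_complement(w)
      if (panmarker:::primer_ok(p, cn))
        wins[[length(wins) + 1]] <- data.frame(dir = dir, start = st,
                                               end = st + len - 1, seq = p)
    }
  }
  wins <- do.call(rbind, wins)
  fw <- wins[wins$dir == "F", ]; rv <- wins[wins$dir == "R", ]
  want <- 0L
  for (i in seq_len(nrow(fw))) {
    size <- rv$end - fw$start[i] + 1
    ok <- size >= 80 & size <= 200 & rv$start > fw$end[i] &
      abs(vapply(rv$seq, wallace_tm, 0) - wallace_tm(fw$seq[i])) <= 3
    want <- want + sum(ok)
  }
  all_pairs <- design_primers(marker, n_max = Inf)
  expect_equal(nrow(all_pairs), want)
  # the engineered pair itself is among the candidates
  expect_true(any(all_pairs$forward_seq == ZEAE_F &
                    all_pairs$reverse_seq == ZEAE_R))
  expect_error(design_primers(paste(rep("AT", 200), collapse = "")),
               "no forward primer window|no reverse primer window")
})

test_that("in-silico PCR finds the one forced amplicon on a constructed template", {
  set.seed(62)
  insert <- rand_seq(88, gc = 0.5)
  template <- paste0(ZEAE_F, insert, reverse_complement(ZEAE_R))
  gs <- toy_genome_set(list(
    t1 = list(species = "T", genes = c(tpl = template)),
    o1 = list(species = "O", genes = c(bg = rand_seq(400)))), "T")
  pp <- primer_pair(ZEAE_F, ZEAE_R)
  rep <- insilico_pcr(pp, gs)
  expect_equal(nrow(rep$hits), 1L)
  expect_equal(rep$hits$product_size, 128L)
  expect_identical(rep$hits$genome_id, "t1")
  expect_true(rep$specific)
  # zero-mismatch product starts with F and ends with revcomp(R)
  prod <- substr(template, rep$hits$fw_start, rep$hits$rv_end)
  expect_identical(substr(prod, 1, 20), ZEAE_F)
  expect_identical(substr(prod, 109, 128), reverse_complement(ZEAE_R))
})

test_that("missing sites and single sites do not amplify", {
  set.seed(63)
  gs <- toy_genome_set(list(
    t1 = list(species = "T", genes = c(g = paste0(ZEAE_F, rand_seq(100)))),
    o1 = list(species = "O", genes = c(g = rand_seq(300)))), "T")
  rep <- insilico_pcr(primer_pair(ZEAE_F, ZEAE_R), gs)
  expect_equal(nrow(rep$hits), 0L)
  expect_false(any(rep$verdicts$amplified))
  expect_false(rep$specific)   # target did not amplify
})

test_that("internal mismatches within tolerance amplify; 3'-clamp mismatches kill", {
  set.seed(64)
  insert <- rand_seq(88, gc = 0.5)
  flip <- function(s, pos) {
    v <- strsplit(s, "")[[1]]
    v[pos] <- setdiff(c("A", "C", "G", "T"), v[pos])[1]
    paste(v, collapse = "")
  }
  tpl_ok <- paste0(flip(ZEAE_F, 5), insert, reverse_complement(ZEAE_R))
  tpl_bad <- paste0(flip(ZEAE_F, 20), insert, reverse_complement(ZEAE_R))
  gs <- toy_genome_set(list(
    a = list(species = "T", genes = c(ok = tpl_ok)),
    b = list(species = "O", genes = c(bad = tpl_bad))), "T")
  rep <- insilico_pcr(primer_pair(ZEAE_F, ZEAE_R), gs, max_mismatch = 2)
  expect_true(rep$verdicts$amplified[rep$verdicts$genome_id == "a"])
  expect_false(rep$verdicts$amplified[rep$verdicts$genome_id == "b"])
  expect_equal(rep$hits$fw_mismatches, 1L)
  # three internal mismatches exceed the default tolerance
  tpl3 <- paste0(flip(flip(flip(ZEAE_F, 5), 9), 13), insert,
                 reverse_complement(ZEAE_R))
  gs3 <- toy_genome_set(list(
    a = list(species = "T", genes = c(g = tpl3)),
    b = list(species = "O", genes = c(g = rand_seq(200)))), "T")
  rep3 <- insilico_pcr(primer_pair(ZEAE_F, ZEAE_R), gs3)
  expect_false(any(rep3$verdicts$amplified))
})

test_that("reverse-complementing every gene leaves product lengths unchanged", {
  set.seed(65)
  insert <- rand_seq(88)
  template <- paste0(ZEAE_F, insert, reverse_complement(ZEAE_R))
  gs <- toy_genome_set(list(
    a = list(species = "T", genes = c(g1 = template, g2 = rand_seq(300))),
    b = list(species = "O", genes = c(g1 = rand_seq(250)))), "T")
  gs_rc <- gs
  gs_rc$genomes <- lapply(gs_rc$genomes, function(g) {
    g$genes <- setNames(reverse_complement(g$genes), names(g$genes)); g
  })
  pp <- primer_pair(ZEAE_F, ZEAE_R)
  expect_equal(sort(insilico_pcr(pp, gs)$hits$product_size),
               sort(insilico_pcr(pp, gs_rc)$hits$product_size))
})

test_that("impossible constraint sets are rejected up front", {
  expect_error(primer_constraints(gc = c(0.7, 0.3)), "empty GC interval")
  expect_error(primer_constraints(tm = c(65, 55)), "empty Tm interval")
  expect_error(design_primers("ACGTACGT"), "shorter than the minimum product")
})
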