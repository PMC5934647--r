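test_that("scan finds exactly the planted sites, matching a naive search", {
  set.seed(11)
  bg <- c("A", "C", "G")                     # T-free background: no stray TTAC
  mk <- function(n) paste(sample(bg, n, replace = TRUE), collapse = "")
  genome <- paste0(mk(150), "TTACC", mk(200), "TTACC", mk(120), "TTACG",
                   mk(180), "TTACC", mk(90), "TTACG", mk(255))
  sites <- scan_sites(c(chr = genome), both_strands = FALSE)
  expect_equal(nrow(sites), 5L)
  expect_equal(sites$ct_start, oracle_find_all(genome, "TTAC") - 1L)
  expect_equal(sort(sites$plus1), sort(c("C", "C", "C", "G", "G")))
  expect_true(all(sites$ct_seq == "TTAC"))

  # minus-strand occurrences are found at BED-compatible coordinates
  genome2 <- paste0(mk(50), "GGTAAG", mk(50))   # revcomp(TTAC) = GTAA
  both <- scan_sites(c(chr = genome2), both_strands = TRUE)
  minus <- both[both$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(substr(genome2, minus$ct_start + 1, minus$ct_start + 4), "GTAA")

  expect_equal(nrow(scan_sites(c(chr = mk(300)), both_strands = TRUE)), 0L)
  expect_error(scan_sites(c(chr = "ACGT"), ct = "TTACC"),
               class = "peelpaste_parameter_error")
})

test_that("scan agrees with the naive quadratic search on random sequences", {
  set.seed(12)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:120, 1), replace = TRUE),
               collapse = "")
    hits <- scan_sites(c(x = s), both_strands = FALSE)$ct_start
    expect_equal(hits, oracle_find_all(s, "TTAC") - 1L, info = s)
  }
})

test_that("+1 weights encode the C > T > purines preference", {
  expect_equal(plus1_weight("C"), 1.0)
  expect_equal(plus1_weight("A"), plus1_weight("G"))
  expect_lt(plus1_weight("A"), plus1_weight("T"))
  w <- plus1_defaults()
  expect_true(all(w > 0 & w <= 1))
  expect_equal(names(which.max(w)), "C")
  expect_error(plus1_weight("N"), class = "peelpaste_parse_error")
})

test_that("match_len counts the longest contiguous register-correct run", {
  fx <- default_fixture()
  d <- fx$design
  expect_equal(match_len(d$site, d), 8L)      # intended site: full match

  pool <- default_pool()
  tr_site <- scan_sites(stats::setNames(pool$oligo[pool$id == "Tr"], "Tr"),
                        both_strands = FALSE)[1, ]
  expect_lte(match_len(tr_site, d), 4L)

  # a 5-match target: keep 5 window positions, force mismatches elsewhere
  up <- d$site$upstream
  U <- nchar(up)
  wstart <- U - d$linker_len - d$ext_len + 1L
  wchars <- strsplit(substr(up, wstart, U - d$linker_len), "")[[1]]
  extc <- strsplit(d$extension, "")[[1]]
  for (t in 1:3) {                            # ext positions 1..3 mismatch
    wpos <- d$ext_len + 1L - t
    wchars[wpos] <- extc[t]                   # a base never pairs itself
  }
  up5 <- up
  substr(up5, wstart, U - d$linker_len) <- paste(wchars, collapse = "")
  site5 <- d$site
  site5$upstream <- up5
  expect_equal(match_len(site5, d), 5L)

  short <- d$site
  short$upstream <- "ACGT"
  expect_error(match_len(short, d), class = "peelpaste_bounds_error")
})

test_that("cooperative weighting is calibrated to the competition outcomes", {
  p <- coop_params()
  m <- 0:13
  expect_true(all(diff(coop(m, p)) >= 0))
  expect_gte(coop(8, p) / coop(0, p), 40)
  expect_lte(coop(5, p) / coop(0, p), 3)
  # invalid user calibrations are rejected at load, naming the constraint
  expect_error(coop_params(amp = 5), class = "peelpaste_config_error")
  expect_error(coop_params(K = 2, h = 1), class = "peelpaste_config_error")
})

test_that("competition fractions normalize, scale-invariantly, and select Tic", {
  fx <- default_fixture()
  d <- fx$design
  pool <- default_pool()

  single <- pool[pool$id == "Tic", ]
  expect_equal(competition(single, d)$fraction, 1.0)

  sc <- competition(pool, d)
  expect_equal(sum(sc$fraction), 1.0, tolerance = 1e-9)
  expect_gte(sc$fraction[sc$id == "Tic"], 0.9)

  # equimolar Tic vs Tr with the same +1 base
  two <- pool[pool$id %in% c("Tic", "Tr"), ]
  sc2 <- competition(two, d)
  expect_gte(sc2$fraction[sc2$id == "Tic"], 0.95)

  # uniform rescaling of concentrations leaves fractions unchanged
  scaled <- pool
  scaled$rel_conc <- scaled$rel_conc * 7.3
  expect_equal(competition(scaled, d)$fraction, sc$fraction, tolerance = 1e-12)

  # 20-fold molar excess of non-complementary targets: Tic still wins
  excess <- pool
  excess$rel_conc[excess$id != "Tic"] <- 4       # 5 members x 4 = 20-fold
  sc20 <- competition(excess, d)
  expect_gt(sc20$fraction[sc20$id == "Tic"], 0.5)

  bad <- pool
  bad$rel_conc <- c(1, rep(0, 5))
  bad$oligo[1] <- gsub("TTAC", "GGGG", bad$oligo[1])
  expect_error(competition(bad, d), class = "peelpaste_parameter_error")
})

test_that("off-target report flags long matches with a +1 C", {
  fx <- default_fixture()
  d <- fx$design
  ot <- offtarget_report(fx$locus, d)
  intended <- ot[ot$ct_start == d$site$ct_start & ot$strand == "+", ]
  expect_equal(intended$match_len, 8L)
  expect_true(intended$high_risk)
  expect_true(all(!ot$high_risk[!(ot$ct_start == d$site$ct_start &
                                    ot$strand == "+")], na.rm = TRUE))

  # plant a second perfect site: it must be flagged
  window <- revcomp(d$extension)
  linker <- substr(d$site$upstream, nchar(d$site$upstream) - 2,
                   nchar(d$site$upstream))
  decoy <- paste0(strrep("G", 30), window, linker, "TTACC", strrep("G", 30))
  ot2 <- offtarget_report(c(decoy = decoy), d)
  expect_true(any(ot2$high_risk))
})

test_that("BED output carries match, +1 and clamped fraction score", {
  fx <- default_fixture()
  sc <- competition(default_pool(), fx$design)
  sites <- offtarget_report(fx$locus, fx$design)
  sites$fraction <- seq(0, 1.2, length.out = nrow(sites))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(sites, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(ncol(bed), 6L)
  expect_true(all(bed$V5 >= 0 & bed$V5 <= 1000))
  expect_equal(bed$V3 - bed$V2, rep(4L, nrow(bed)))
})
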