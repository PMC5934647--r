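# A wild-type-like design: the engineered extension reproduces the native
# +44..+51 bases of an LE that still carries the occluding second hairpin,
# so the extension window starts out buried.
mk_wt_design <- function(seed) {
  le <- make_synthetic_le(seed, ext_len = 0L, with_second_hairpin = TRUE)
  window <- revcomp(substr(le$seq, 44, 51))
  set.seed(seed + 500)
  bg <- c("A", "C", "G")
  rnd <- function(n) paste(sample(bg, n, replace = TRUE), collapse = "")
  locus <- paste0(rnd(40), window, "GCA", "TTAC", "C", rnd(40))
  sites <- scan_sites(c(locus = locus), both_strands = FALSE)
  stopifnot(nrow(sites) == 1)
  design_extension(locus, sites[1, ], ext_len = 8, linker_len = 3, end = le)
}

test_that("design geometry: recognized site length is 4 + ext_len", {
  fx <- default_fixture()
  d <- fx$design
  expect_equal(d$ext_len, 8L)
  expect_equal(d$recognized_len, 12L)
  d13 <- design_extension(fx$locus[[1]], fx$site, ext_len = 13)
  expect_equal(d13$recognized_len, 17L)
  expect_equal(nchar(d13$extension), 13L)
  expect_equal(d13$le$features$EXT, c(44L, 56L))
})

test_that("the extension is the reverse complement of the addressed window", {
  fx <- default_fixture()
  site <- fx$site
  up <- site$upstream
  U <- nchar(up)
  window <- substr(up, U - 3L - 8L + 1L, U - 3L)     # target -15..-8
  expect_equal(fx$design$extension, revcomp(window))
  expect_equal(get_le_seq_public(fx$design), fx$design$extension)

  # homopolymer window and an enumerated example, via an independent oracle
  site_a <- list(source_id = "x", ct_start = 20L, strand = "+",
                 ct_seq = "TTAC", plus1 = "C",
                 upstream = paste0("GGGGG", "AAAAAAAA", "GGG"))
  d_a <- design_extension("unused", site_a, ext_len = 8)
  expect_equal(d_a$extension, "TTTTTTTT")
  site_b <- list(source_id = "x", ct_start = 20L, strand = "+",
                 ct_seq = "TTAC", plus1 = "C",
                 upstream = paste0("GGGGG", "ACGTTGCA", "GGG"))
  d_b <- design_extension("unused", site_b, ext_len = 8)
  expect_equal(d_b$extension, oracle_revcomp("ACGTTGCA"))
})

test_that("design parameter bounds follow the demonstrated range", {
  fx <- default_fixture()
  expect_error(design_extension(fx$locus[[1]], fx$site, ext_len = 14),
               class = "peelpaste_parameter_error")
  expect_warning(design_extension(fx$locus[[1]], fx$site, ext_len = 5),
                 "selection")
  short_site <- fx$site
  short_site$upstream <- substr(short_site$upstream, 1, 6)
  expect_error(design_extension(fx$locus[[1]], short_site, ext_len = 8),
               class = "peelpaste_bounds_error")
})

test_that("register pairs antiparallel and anchors the guide and triplets", {
  reg <- default_fixture()$design$register
  expect_true(all(c("WC", "triplet") %in% reg$kind))
  expect_true(nrow(reg[reg$le_pos == 17 & reg$target_pos == -4, ]) == 1)
  expect_true(nrow(reg[reg$le_pos == 16 & reg$target_pos == -3, ]) == 1)
  expect_true(nrow(reg[reg$le_pos == 42 & reg$target_pos == -4 &
                         reg$kind == "triplet", ]) == 1)
  expect_true(nrow(reg[reg$le_pos == 43 & reg$target_pos == -3 &
                         reg$kind == "triplet", ]) == 1)
  wc <- reg[reg$kind == "WC", ]
  expect_true(all(diff(wc$le_pos) > 0))
  expect_true(all(diff(wc$target_pos) < 0))
  # extension anchor: +44 pairs -(linker + 5)
  expect_true(nrow(wc[wc$le_pos == 44 & wc$target_pos == -8, ]) == 1)
})

test_that("structural unlocking opens the hairpin with edits confined to {+42} u [+55,+60]", {
  d <- mk_wt_design(11)
  acc0 <- accessibility(fold(d$junction$seq), c(d$junction$le_start + 43L,
                                                d$junction$le_start + 50L))
  expect_lt(acc0, 0.9)
  du <- apply_structural_unlocking(d)
  ul <- du$validation$unlocking
  expect_true(ul$pass)
  expect_gte(ul$accessibility, 0.9)
  pos <- vapply(ul$edits, function(e) e$pos, numeric(1))
  expect_true(all(pos %in% c(42, 55:60)))
  expect_true(42 %in% pos)
  expect_true(any(pos >= 55 & pos <= 60))
  # never edits G_L, IP_L, +43 or the extension
  expect_equal(get_le_seq_pub(du, 16, 19), get_le_seq_pub(d, 16, 19))
  expect_equal(get_le_seq_pub(du, 20, 41), get_le_seq_pub(d, 20, 41))
  expect_equal(get_le_seq_pub(du, 43, 43), "T")
  expect_equal(du$extension, d$extension)
  # idempotence
  expect_identical(apply_structural_unlocking(du)$junction$seq, du$junction$seq)
})

test_that("already-accessible designs get only the +42 A->T edit", {
  fx <- get_fixture("open_locus", function() {
    make_target_locus(21, end = make_synthetic_le(21, ext_len = 8,
                                                  with_second_hairpin = FALSE))
  })
  ul <- fx$design$validation$unlocking
  pos <- vapply(ul$edits, function(e) e$pos, numeric(1))
  expect_equal(pos, 42)
  expect_true(ul$pass)
})

test_that("C_T resetting edits exactly the mapped guide bases", {
  d <- default_fixture()$design
  expect_equal(d$site$ct_seq, "TTAC")

  # identity reset: zero edits
  d0 <- reset_ct(d, "TTAC")
  expect_identical(d0$junction$seq, d$junction$seq)
  expect_length(d0$validation$ct_reset$edits, 0L)

  # -4 only: one edit, at +17, restoring complementarity
  d1 <- reset_ct(d, "GTAC")
  ed <- d1$validation$ct_reset$edits
  expect_length(ed, 1L)
  expect_equal(ed[[1]]$le_pos, 17L)
  expect_equal(get_le_seq_pub(d1, 17, 17), "C")       # complement of G at -4
  expect_equal(d1$site$ct_seq, "GTAC")

  # -4 and -3: two edits, at +17 and +16
  d2 <- reset_ct(d, "GCAC")
  ed2 <- d2$validation$ct_reset$edits
  expect_length(ed2, 2L)
  expect_setequal(vapply(ed2, function(e) e$le_pos, integer(1)), c(17L, 16L))
  expect_equal(get_le_seq_pub(d2, 16, 17), paste0(complement("C"), complement("G")))
  # register kinds at reset positions become WC
  expect_true(all(d2$register$kind[d2$register$le_pos %in% c(16, 17) &
                                     d2$register$kind != "triplet"] == "WC"))

  # unmapped positions (-2, -1) are refused with a position list
  expect_error(reset_ct(d, "TTCC"),
               class = "peelpaste_unsupported_position_error")
  err <- tryCatch(reset_ct(d, "TTCG"), condition = function(e) conditionMessage(e))
  expect_match(err, "-2|-1")
})

test_that("C_T resetting and unlocking commute on an open design", {
  fx <- get_fixture("open_locus", function() {
    make_target_locus(21, end = make_synthetic_le(21, ext_len = 8,
                                                  with_second_hairpin = FALSE))
  })
  base <- design_extension(fx$locus[[1]], fx$site,
                           end = make_synthetic_le(21, ext_len = 8,
                                                   with_second_hairpin = FALSE))
  a <- reset_ct(apply_structural_unlocking(base), "GTAC")
  b <- apply_structural_unlocking(reset_ct(base, "GTAC"))
  expect_identical(a$junction$seq, b$junction$seq)
})

test_that("validated designs pair perfectly with their intended target", {
  fx <- default_fixture()
  d <- fx$design
  expect_true(d$validation$overall)
  up <- d$site$upstream
  U <- nchar(up)
  # every WC register pair is complementary: extension vs window, guide vs C_T
  window <- substr(up, U - d$linker_len - d$ext_len + 1L, U - d$linker_len)
  expect_equal(match_len(d$site, d), d$ext_len)
  expect_equal(revcomp(window), d$extension)
  ct <- d$site$ct_seq
  expect_equal(get_le_seq_pub(d, 17, 17), complement(substr(ct, 1, 1)))
  expect_equal(get_le_seq_pub(d, 16, 16), complement(substr(ct, 2, 2)))
})

test_that("validation catches planted self-complementarity and stray C_T", {
  fx <- default_fixture()
  d <- fx$design

  # extension equal to the reverse complement of the IP_L 5' arm folds back
  bad <- d
  arm_rc <- revcomp(substr(bad$le$seq, 20, 27))
  bad$le <- peelpaste:::set_le_seq(bad$le, 44, 51, arm_rc)
  bad$extension <- arm_rc
  bad$junction <- peelpaste:::junction_from_le(bad$le)
  v <- validate_design(bad)
  ck <- tidy(v)
  expect_false(ck$pass[ck$check == "self_complementarity"])
  expect_false(v$validation$overall)

  # extension containing the C_T motif creates an unintended cleavage site
  bad2 <- d
  bad2$le <- peelpaste:::set_le_seq(bad2$le, 44, 51, "GGTTACGG")
  bad2$extension <- "GGTTACGG"
  bad2$junction <- peelpaste:::junction_from_le(bad2$le)
  ck2 <- tidy(validate_design(bad2))
  expect_false(ck2$pass[ck2$check == "unintended_ct"])
})

test_that("design report JSON round-trips feature intervals and checks", {
  d <- default_fixture()$design
  path <- withr::local_tempfile(fileext = ".json")
  design_report(d, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$junction$features$EXT, as.integer(d$junction$features$EXT))
  expect_equal(back$junction$features$GL, as.integer(d$junction$features$GL))
  expect_equal(back$extension, d$extension)
  expect_true(back$overall)
})
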