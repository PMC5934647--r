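test_that("target cleavage cuts 3' of C_T with covalent bookkeeping", {
  ti <- make_covalent_target(3)
  ev <- cleave_target(ti)
  expect_equal(ev$downstream_len, 16L)
  expect_equal(ev$covalent_attachment, "enzyme_5prime_phosphotyrosine")
  expect_equal(ev$upstream_len + ev$downstream_len, nchar(ti[[1]]))
  expect_equal(substr(ti[[1]], ev$upstream_len - 3L, ev$upstream_len), "TTAC")

  # oligo ending exactly at C_T: empty downstream, no covalent attachment
  edge <- c(x = paste0(strrep("G", 12), "TTAC"))
  ev0 <- cleave_target(edge)
  expect_equal(ev0$downstream_len, 0L)
  expect_equal(ev0$covalent_attachment, "none")

  # conservation on random substrates
  set.seed(31)
  for (i in 1:20) {
    bg <- paste(sample(c("A", "C", "G"), sample(20:60, 1), replace = TRUE),
                collapse = "")
    cut_at <- sample(5:15, 1)
    oligo <- paste0(substr(bg, 1, cut_at), "TTAC",
                    substr(bg, cut_at + 1, nchar(bg)))
    ev <- cleave_target(c(o = oligo))
    expect_equal(ev$upstream_len + ev$downstream_len, nchar(oligo))
  }

  expect_error(cleave_target(c(x = "GGGGCCCC")),
               class = "peelpaste_ambiguity_error")
  expect_error(cleave_target(c(x = "TTACGGTTACG")),
               class = "peelpaste_ambiguity_error")
})

test_that("excision seals the donor, retains C_L, and conserves length", {
  don <- make_donor(5)
  ex <- excise(don)
  expect_equal(nchar(ex$sealed_donor) + nchar(ex$junction$seq), nchar(don$seq))
  expect_true(grepl("TTAC", ex$sealed_donor, fixed = TRUE))
  expect_true(ex$junction$circular)
  # sealed donor = flanks joined, with C_L at the joint
  joint <- don$le_start - 1L
  expect_equal(substr(ex$sealed_donor, joint - 3L, joint), "TTAC")

  bad <- don
  bad$le_start <- don$le_start + 2L
  expect_error(excise(bad), class = "peelpaste_precondition_error")
})

test_that("excision then reintegration at the retained C_L is scarless", {
  for (s in c(5, 6, 7)) {
    don <- make_donor(s)
    ex <- excise(don)
    back <- integrate(ex$junction, c(sealed = ex$sealed_donor), "TTAC")
    expect_equal(back$length, nchar(don$seq))
    expect_identical(back$seq, don$seq)
    expect_false(back$labeled)
  }
})

test_that("assay junction transfer products have the gel-resolvable layout", {
  fx <- default_fixture()
  d <- fx$design
  pool <- default_pool()
  j <- make_canonical_junction(1, design = d)
  tic <- stats::setNames(pool$oligo[pool$id == "Tic"], "Tic")
  tr <- stats::setNames(pool$oligo[pool$id == "Tr"], "Tr")

  pb <- integrate(j, tic)
  pc <- integrate(j, tr)
  expect_equal(pb$length, 50L + 38L)
  expect_equal(pc$length, 50L + 30L)
  expect_true(pb$labeled && pc$labeled)
  expect_false(pb$length == pc$length)          # products distinguishable
  # composition: junction 5' segment then target 3' segment
  expect_equal(pb$composition$source_id, c("junction", "Tic"))
  expect_equal(pb$composition$end[1] - pb$composition$start[1] + 1L, 50L)

  # integrating into a target cut at its 3' terminus leaves the 5' segment alone
  edge <- c(edge = paste0(strrep("G", 12), "TTAC"))
  pe <- integrate(j, edge)
  expect_equal(pe$length, 50L)
  expect_equal(pe$composition$source_id, "junction")
})

test_that("label propagation: one labeled species before and after transfer", {
  fx <- default_fixture()
  j <- make_canonical_junction(1, design = fx$design)
  pool <- default_pool()
  tic <- stats::setNames(pool$oligo[pool$id == "Tic"], "Tic")
  before <- c(junction = j$label_5prime, target = FALSE)
  expect_equal(sum(before), 1L)
  p <- integrate(j, tic)
  jev <- cleave_end(j)
  # after transfer the label sits on the product; the junction 3' segment and
  # target 5' segment are unlabeled
  expect_true(p$labeled)
  expect_equal(sum(p$labeled, FALSE, FALSE), 1L)
  expect_true(jev$labeled_5prime)               # 5' segment carries the label
})

test_that("the virtual gel shows the four distinct labeled species", {
  fx <- default_fixture()
  d <- fx$design
  pool <- default_pool()
  j <- make_canonical_junction(1, design = d)
  sc <- competition(pool[pool$id %in% c("Tic", "Tr"), ], d)
  products <- list(
    cleave_end(j),
    integrate(j, stats::setNames(pool$oligo[pool$id == "Tic"], "Tic")),
    integrate(j, stats::setNames(pool$oligo[pool$id == "Tr"], "Tr"))
  )
  gel <- virtual_gel(products, substrates = list(j),
                     fractions = stats::setNames(sc$fraction, sc$id))
  expect_equal(nrow(gel), 4L)
  expect_equal(anyDuplicated(gel$length), 0L)
  expect_true(all(diff(gel$length) < 0))        # sorted by descending length
  ip <- gel[gel$species == "integration_product", ]
  expect_equal(sum(ip$intensity), 1.0, tolerance = 1e-9)

  expect_equal(nrow(virtual_gel(list())), 0L)
})
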