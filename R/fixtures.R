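#' Generate a synthetic target locus with a designable planted site
#'
#' Builds a seeded locus carrying exactly one C_T occurrence, preceded by a
#' linker and a random extension-complementarity window, and runs the full
#' design pipeline (extension design, structural unlocking, validation)
#' against it, resampling the window deterministically until the design
#' validates. This emulates the experimental practice of choosing workable
#' junction/target sequence pairs; arbitrary genomic windows can and do fail
#' validation, which is what [validate_design()] reports.
#'
#' @param seed Integer seed.
#' @param ext_len,linker_len Design geometry (see [design_extension()]).
#' @param ct Target motif (default TTAC).
#' @param plus1 Planted +1 base (default C, the preferred base).
#' @param locus_len Total locus length (default 600).
#' @param end Optional LE template passed to [design_extension()].
#' @param threshold Accessibility threshold for unlocking/validation.
#' @param params Fold parameters.
#' @return A list with `locus` (named character), `site` (one-row tibble) and
#'   `design` (validated `retarget_design`).
#' @export
make_target_locus <- function(seed, ext_len = 8L, linker_len = 3L,
                              ct = "TTAC", plus1 = "C", locus_len = 600L,
                              end = NULL, threshold = 0.9,
                              params = fold_params()) {
  ct <- check_dna(ct, allow_n = FALSE)
  with_seed(seed, {
    bg <- c("A", "C", "G")                      # T-free background: no stray C_T
    pos <- locus_len %/% 2L                     # 1-based start of the window
    left <- random_dna(pos - 1L, bg)
    linker <- random_dna(linker_len, bg)
    right_len <- locus_len - (pos - 1L) - ext_len - linker_len - 5L
    right <- random_dna(right_len, bg)
    for (attempt in 1:100) {
      window <- random_dna(ext_len, DNA_BASES)
      locus <- paste0(left, window, linker, ct, plus1, right)
      if (length(find_all(locus, ct)) != 1L) next
      sites <- scan_sites(c(locus = locus), ct = ct, both_strands = FALSE)
      site <- sites[sites$ct_start == pos - 1L + ext_len + linker_len, ]
      if (nrow(site) != 1L) next
      d <- suppressWarnings(
        design_extension(locus, site, ext_len = ext_len,
                         linker_len = linker_len, end = end)
      )
      d <- apply_structural_unlocking(d, threshold = threshold, params = params)
      if (!d$validation$unlocking$pass) next
      d <- validate_design(d, genome = c(locus = locus),
                           threshold = threshold, params = params)
      if (!isTRUE(d$validation$overall)) next
      return(list(locus = c(locus = locus), site = site, design = d))
    }
    abort("no designable window found after 100 draws",
          class = "peelpaste_generation_error")
  })
}

#' Generate the competition-assay target oligo pool
#'
#' Builds the strand-transfer competition fixtures: `Tic`, the fully
#' complementary target with a 38-nt 3' segment after the cleavage site;
#' `Tr`, a random target sharing only the C_T (and a shorter, 30-nt 3'
#' segment so its integration product is distinguishable on a gel); and
#' `n_scrambled` targets whose variable window is a scramble of the
#' complementary window. All members share the design's C_T; random and
#' scrambled windows are constrained to fewer than 5 contiguous matches to
#' the design extension (5 bp of complementarity selects nothing, so matches
#' below that cap behave as background) and every member carries exactly one
#' C_T occurrence.
#'
#' @param seed Integer seed.
#' @param design A validated `retarget_design`.
#' @param n_scrambled Number of scrambled-window members.
#' @return An [oligo_pool()] of `2 + n_scrambled` members, equimolar.
#' @export
make_target_fixtures <- function(seed, design, n_scrambled = 4L) {
  ct <- design$site$ct_seq
  ext <- design$extension
  L <- nchar(ext)
  k <- design$linker_len
  upstream <- design$site$upstream
  U <- nchar(upstream)
  if (U < k + L) abort("design site lacks upstream context",
                       class = "peelpaste_bounds_error")
  prefix <- substr(upstream, 1L, U - k - L)
  linker <- substr(upstream, U - k + 1L, U)
  window_c <- substr(upstream, U - k - L + 1L, U - k)   # complementary window
  plus1 <- if (is.na(design$site$plus1)) "C" else design$site$plus1
  bg <- c("A", "C", "G")

  with_seed(seed, {
    draw_tail <- function(n) paste0(plus1, random_dna(n - 1L, bg))
    ok_member <- function(oligo) length(find_all(oligo, ct)) == 1L
    run_vs_ext <- function(window) {
      longest_run(seq_chars(revcomp(window)) == seq_chars(ext))
    }
    draw_constrained <- function(make_window, tail_len) {
      for (i in 1:1000) {
        w <- make_window()
        oligo <- paste0(prefix, w, linker, ct, draw_tail(tail_len))
        if (run_vs_ext(w) < 5L && ok_member(oligo)) return(oligo)
      }
      abort("could not satisfy the scramble constraint after 1000 draws",
            class = "peelpaste_generation_error")
    }
    tic <- paste0(prefix, window_c, linker, ct, draw_tail(38L))
    if (!ok_member(tic)) {
      abort("intended target carries a stray C_T; regenerate the locus",
            class = "peelpaste_generation_error")
    }
    tr <- draw_constrained(function() random_dna(L, DNA_BASES), 30L)
    ts <- vapply(seq_len(n_scrambled), function(i) {
      draw_constrained(function() paste(sample(seq_chars(window_c)), collapse = ""),
                       30L)
    }, character(1))
    oligo_pool(
      oligo = c(tic, tr, ts),
      id = c("Tic", "Tr", if (n_scrambled) paste0("Ts", seq_len(n_scrambled))),
      rel_conc = 1,
      role = c("complementary", "random", rep("scrambled", n_scrambled))
    )
  })
}

#' Generate a covalent-complex assay target
#'
#' A target oligo with the cleavage-assay layout: variable upstream context,
#' the C_T motif, and a 16-nt variable sequence downstream of the cleavage
#' position — the segment that ends up covalently attached to the
#' transposase's catalytic tyrosine after cleavage.
#'
#' @param seed Integer seed.
#' @param ct Target motif.
#' @param plus1 +1 base (default C).
#' @param upstream_len Upstream context length (default 20).
#' @return Named character vector of length 1 (name `"Ti"`).
#' @export
make_covalent_target <- function(seed, ct = "TTAC", plus1 = "C",
                                 upstream_len = 20L) {
  with_seed(seed, {
    bg <- c("A", "C", "G")
    c(Ti = paste0(random_dna(upstream_len, bg), ct, plus1, random_dna(15L, bg)))
  })
}

#' Generate a synthetic single-stranded donor
#'
#' A top-strand donor molecule: left flank ending in the C_L motif (TTAC,
#' retained in the donor after excision and required for further rounds),
#' the transposon (a synthetic LE, a cargo core, and an RE ending in the C_R
#' motif TCAA), and a right flank. Flanks and cargo are drawn over a T-free
#' alphabet so the planted cleavage motifs are unique.
#'
#' @param seed Integer seed.
#' @param core_len Cargo length between LE and RE (default 30).
#' @param with_second_hairpin Build the LE with the wild-type second hairpin?
#' @return List with `seq`, `le_start`, `re_end` and `features`.
#' @export
make_donor <- function(seed, core_len = 30L, with_second_hairpin = TRUE) {
  le <- make_synthetic_le(seed, ext_len = 0L,
                          with_second_hairpin = with_second_hairpin)
  with_seed(seed + 101L, {
    bg <- c("A", "C", "G")
    left <- paste0(random_dna(16L, bg), "TTAC")
    core <- random_dna(core_len, bg)
    re <- paste0(random_dna(21L, bg), "TCAA")
    right <- random_dna(20L, bg)
    seq <- paste0(left, le$seq, core, re, right)
    le_start <- nchar(left) + 1L
    re_end <- nchar(left) + nchar(le$seq) + core_len + nchar(re)
    list(
      seq = seq, le_start = le_start, re_end = re_end,
      features = list(
        CL = c(le_start - 4L, le_start - 1L),
        LE = c(le_start, le_start + nchar(le$seq) - 1L),
        RE = c(re_end - 24L, re_end),
        CR = c(re_end - 3L, re_end)
      )
    )
  })
}
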