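#' Folding parameters for single-stranded DNA
#'
#' Parameters for the weighted base-pair maximization fold used to detect
#' stem-loops (the subterminal imperfect palindrome and any occluding second
#' hairpin) on single-stranded transposon intermediates. The model scores a
#' nested (pseudoknot-free) set of base pairs by the sum of per-pair weights
#' and is used qualitatively: to ask whether a hairpin forms over a window and
#' whether designed bases are left unpaired.
#'
#' @param pair_weights Named numeric vector of non-negative pair weights for
#'   `AT`, `GC` and `GT` pairs (orientation-symmetric).
#' @param min_loop Minimum number of unpaired bases enclosed by a pair; a pair
#'   `(i, j)` requires `j - i > min_loop`. Must be >= 3.
#' @param allow_GT Score G:T wobble pairs? Off by default: the hairpins of the
#'   IS608 left end are drawn with canonical pairs.
#' @param min_helix Minimum number of contiguously stacked pairs per helix.
#'   The default 2 forbids lonely base pairs, the usual convention in
#'   secondary-structure prediction; isolated one-off pairs otherwise swamp
#'   accessibility estimates on A/T-rich single strands.
#' @return A `fold_params` list.
#' @export
fold_params <- function(pair_weights = c(AT = 2, GC = 3, GT = 1),
                        min_loop = 3L, allow_GT = FALSE, min_helix = 2L) {
  stopifnot(all(c("AT", "GC") %in% names(pair_weights)))
  if (any(pair_weights < 0)) abort("pair weights must be >= 0")
  min_loop <- as.integer(min_loop)
  if (min_loop < 3L) abort("`min_loop` must be >= 3")
  min_helix <- as.integer(min_helix)
  if (min_helix < 1L) abort("`min_helix` must be >= 1")
  structure(
    list(pair_weights = pair_weights, min_loop = min_loop,
         allow_GT = isTRUE(allow_GT), min_helix = min_helix),
    class = "fold_params"
  )
}

# 4x4 weight matrix over A,C,G,T indices
pair_weight_matrix <- function(params) {
  w <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  w["A", "T"] <- w["T", "A"] <- params$pair_weights[["AT"]]
  w["G", "C"] <- w["C", "G"] <- params$pair_weights[["GC"]]
  if (params$allow_GT) {
    gt <- if ("GT" %in% names(params$pair_weights)) params$pair_weights[["GT"]] else 1
    w["G", "T"] <- w["T", "G"] <- gt
  }
  w
}

#' Fold a single-stranded DNA sequence
#'
#' Computes a maximum-total-weight nested pairing of `seq` by dynamic
#' programming under `params`, with deterministic traceback (ties are resolved
#' by closing the 5'-most pair first, then by extending the current helix).
#'
#' @param seq DNA string over ACGTN (N never pairs). Length at most 10000.
#' @param params A [fold_params()] object.
#' @return A `secondary_structure` object: list with `seq`, `pairs` (two-column
#'   integer matrix, `i < j`, 1-based), `score`, and `params`.
#' @examples
#' fold("GGGAAATCCC")
#' @export
fold <- function(seq, params = fold_params()) {
  seq <- check_dna(seq)
  n <- nchar(seq)
  if (n > 10000L) abort("sequences longer than 10000 nt are not supported")
  s <- seq_chars(seq)
  out <- structure(
    list(seq = seq, pairs = matrix(integer(), 0, 2,
                                   dimnames = list(NULL, c("i", "j"))),
         score = 0, params = params),
    class = "secondary_structure"
  )
  ml <- params$min_loop
  H <- params$min_helix
  if (n <= ml + 1L) return(out)

  pw <- pair_weight_matrix(params)
  si <- match(s, DNA_BASES)               # NA for N
  # W[i, j] weight of pairing i with j (0 if unpairable base combination)
  bigW <- matrix(0, n, n)
  ok <- !is.na(si)
  bigW[ok, ok] <- pw[si[ok], si[ok], drop = FALSE]

  Fm <- matrix(0, n + 1L, n + 1L)          # free structure score on [i, j]
  Bm <- matrix(-Inf, n + 1L, n + 1L)       # (i, j) paired, inner free

  for (span in (ml + 1L):(n - 1L)) {
    for (i in 1L:(n - span)) {
      j <- i + span
      # B: (i, j) paired
      w <- bigW[i, j]
      if (w > 0) {
        inner <- Fm[i + 1L, j - 1L]
        if (j - 1L - (i + 1L) > ml && is.finite(Bm[i + 1L, j - 1L])) {
          inner <- max(inner, Bm[i + 1L, j - 1L])
        }
        Bm[i, j] <- w + inner
      }
      # F: i unpaired, or i pairs k opening a helix of >= H stacked pairs
      best <- Fm[i + 1L, j]
      ks <- (i + ml + 1L):j
      wk <- bigW[i, ks]
      if (H >= 2L) {
        sv <- wk + Bm[i + 1L, ks - 1L]     # forces (i+1, k-1) paired too
      } else {
        sv <- ifelse(wk > 0, Bm[i, ks], -Inf)
        sv[wk <= 0] <- -Inf
      }
      sv[wk <= 0] <- -Inf
      cand <- sv + Fm[ks + 1L, j]
      m <- suppressWarnings(max(cand))
      if (is.finite(m) && m > best) best <- m
      Fm[i, j] <- best
    }
  }

  eps <- 1e-9
  pairs_i <- integer(0); pairs_j <- integer(0)
  push <- function(i, j) {
    pairs_i[[length(pairs_i) + 1L]] <<- i
    pairs_j[[length(pairs_j) + 1L]] <<- j
  }
  helix_score <- function(i, k) {
    if (bigW[i, k] <= 0) return(-Inf)
    if (H >= 2L) {
      if (!is.finite(Bm[i + 1L, k - 1L])) return(-Inf)
      bigW[i, k] + Bm[i + 1L, k - 1L]
    } else {
      Bm[i, k]
    }
  }
  tbB <- function(a, b) {
    push(a, b)
    inner_ok <- (b - 1L) - (a + 1L) > ml && is.finite(Bm[a + 1L, b - 1L])
    if (inner_ok &&
        abs(Bm[a, b] - (bigW[a, b] + Bm[a + 1L, b - 1L])) < eps) {
      tbB(a + 1L, b - 1L)
    } else if ((b - 1L) >= (a + 1L)) {
      tbF(a + 1L, b - 1L)
    }
  }
  tbF <- function(i, j) {
    while (j - i > ml) {
      if (abs(Fm[i, j]) < eps) return()
      paired <- FALSE
      for (k in (i + ml + 1L):j) {
        sv <- helix_score(i, k)
        if (is.finite(sv) && abs(sv + Fm[k + 1L, j] - Fm[i, j]) < eps) {
          if (H >= 2L) {
            push(i, k)
            tbB(i + 1L, k - 1L)
          } else {
            tbB(i, k)
          }
          i <- k + 1L
          paired <- TRUE
          break
        }
      }
      if (!paired) i <- i + 1L
    }
  }
  tbF(1L, n)

  ord <- order(pairs_i)
  out$pairs <- cbind(i = pairs_i[ord], j = pairs_j[ord])
  out$score <- Fm[1L, n]
  out
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d pairs, score %.1f\n",
              nchar(x$seq), nrow(x$pairs), x$score))
  cat(x$seq, "\n")
  cat(dot_bracket(x), "\n")
  invisible(x)
}

#' Dot-bracket notation of a fold
#'
#' @param struct A `secondary_structure` from [fold()].
#' @return A string of `(`, `)` and `.` characters.
#' @export
dot_bracket <- function(struct) {
  db <- rep(".", nchar(struct$seq))
  db[struct$pairs[, "i"]] <- "("
  db[struct$pairs[, "j"]] <- ")"
  paste(db, collapse = "")
}

#' Decompose a fold into helices (stem-loops)
#'
#' Returns the maximal runs of contiguously stacked pairs
#' (`(i, j), (i+1, j-1), ...`) with at least `min_stem` pairs.
#'
#' @param struct A `secondary_structure`.
#' @param min_stem Minimum stacked pairs per reported helix.
#' @return A tibble with columns `outer_start`, `outer_end` (outermost pair of
#'   the helix), `stem_len`, `loop_len` (bases enclosed by the innermost pair),
#'   sorted by `outer_start`.
#' @export
find_hairpins <- function(struct, min_stem = 3L) {
  p <- struct$pairs
  empty <- tibble(outer_start = integer(), outer_end = integer(),
                  stem_len = integer(), loop_len = integer())
  if (nrow(p) == 0L) return(empty)
  p <- p[order(p[, "i"]), , drop = FALSE]
  key <- paste(p[, "i"], p[, "j"])
  has_outer <- paste(p[, "i"] - 1L, p[, "j"] + 1L) %in% key
  out <- list()
  for (r in which(!has_outer)) {
    i <- p[r, "i"]; j <- p[r, "j"]; len <- 1L
    while (paste(i + len, j - len) %in% key) len <- len + 1L
    if (len >= min_stem) {
      out[[length(out) + 1L]] <- tibble(
        outer_start = unname(i), outer_end = unname(j), stem_len = len,
        loop_len = unname((j - len + 1L) - (i + len - 1L) - 1L)
      )
    }
  }
  if (length(out) == 0L) return(empty)
  arrange(bind_rows(out), .data$outer_start)
}

#' Accessibility of a sequence window
#'
#' Fraction of window positions left unpaired by the fold. A designed
#' extension window must be essentially fully accessible (>= 0.9 by default
#' elsewhere in the package) to be available for pairing with target DNA.
#'
#' @param struct A `secondary_structure`.
#' @param window Length-2 integer vector `c(start, end)`, 1-based, inclusive.
#' @return Fraction in `[0, 1]`.
#' @export
accessibility <- function(struct, window) {
  window <- as.integer(window)
  if (length(window) != 2L || window[1] > window[2] ||
      window[1] < 1L || window[2] > nchar(struct$seq)) {
    abort("`window` outside sequence bounds.", class = "peelpaste_bounds_error")
  }
  pos <- window[1]:window[2]
  paired <- unique(c(struct$pairs[, "i"], struct$pairs[, "j"]))
  mean(!(pos %in% paired))
}

#' Write a connectivity-table (.ct) file for a fold
#'
#' @param struct A `secondary_structure`.
#' @param path Output path.
#' @param name Sequence name placed on the header line.
#' @return `path`, invisibly.
#' @export
write_ct <- function(struct, path, name = "seq") {
  n <- nchar(struct$seq)
  partner <- integer(n)
  partner[struct$pairs[, "i"]] <- struct$pairs[, "j"]
  partner[struct$pairs[, "j"]] <- struct$pairs[, "i"]
  s <- seq_chars(struct$seq)
  lines <- c(
    sprintf("%d %s score=%.1f", n, name, struct$score),
    sprintf("%d %s %d %d %d %d", 1:n, s, 0:(n - 1L),
            c(2:n, 0L), partner, 1:n)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @method tidy secondary_structure
#' @export
tidy.secondary_structure <- function(x, ...) {
  n <- nchar(x$seq)
  partner <- rep(NA_integer_, n)
  if (nrow(x$pairs)) {
    partner[x$pairs[, "i"]] <- x$pairs[, "j"]
    partner[x$pairs[, "j"]] <- x$pairs[, "i"]
  }
  tibble(position = 1:n, base = seq_chars(x$seq), partner = partner,
         paired = !is.na(partner))
}

#' @method glance secondary_structure
#' @export
glance.secondary_structure <- function(x, ...) {
  tibble(length = nchar(x$seq), n_pairs = nrow(x$pairs), score = x$score,
         n_helices = nrow(find_hairpins(x, min_stem = 1L)))
}
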