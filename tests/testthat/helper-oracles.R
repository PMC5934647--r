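# Independent brute-force oracles, kept free of the package's DP/search code.

oracle_complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Per-base reverse complement, assembled character by character.
oracle_revcomp <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  paste(rev(unname(oracle_complement[ch])), collapse = "")
}

# Exhaustive enumeration of all nested pairings of `seq`; returns the best
# total weight over structures whose maximal stacked runs all have length
# >= min_helix. Feasible for length <= 12.
oracle_fold_score <- function(seq, pair_weights = c(AT = 2, GC = 3, GT = 1),
                              min_loop = 3, allow_GT = FALSE, min_helix = 2) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  wt <- function(a, b) {
    p <- paste0(sort(c(ch[a], ch[b])), collapse = "")
    if (p == "AT") return(pair_weights[["AT"]])
    if (p == "CG") return(pair_weights[["GC"]])
    if (allow_GT && p == "GT") return(pair_weights[["GT"]])
    0
  }
  best <- 0
  # all maximal stacked runs must reach min_helix
  legal_runs <- function(pairs) {
    if (length(pairs) == 0) return(TRUE)
    key <- vapply(pairs, function(p) paste(p[1], p[2]), character(1))
    for (p in pairs) {
      run <- 1
      a <- p[1] - 1; b <- p[2] + 1
      while (paste(a, b) %in% key) { run <- run + 1; a <- a - 1; b <- b + 1 }
      a <- p[1] + 1; b <- p[2] - 1
      while (paste(a, b) %in% key) { run <- run + 1; a <- a + 1; b <- b - 1 }
      if (run < min_helix) return(FALSE)
    }
    TRUE
  }
  enum_all <- function(avail, pairs, score, k_done) {
    if (length(avail) == 0) return(k_done(pairs, score))
    i <- avail[1]
    enum_all(avail[-1], pairs, score, k_done)
    for (k in avail[-1]) {
      if (k - i <= min_loop) next
      w <- wt(i, k)
      if (w <= 0) next
      inside <- avail[avail > i & avail < k]
      outside <- avail[avail > k]
      enum_all(inside, c(pairs, list(c(i, k))), score + w, function(p2, s2) {
        enum_all(outside, p2, s2, k_done)
      })
    }
  }
  enum_all(seq_len(n), list(), 0, function(p, s) {
    if (legal_runs(p) && s > best) best <<- s
  })
  best
}

# Naive quadratic substring search for all occurrences of `pat` in `s`.
oracle_find_all <- function(s, pat) {
  n <- nchar(s); m <- nchar(pat)
  hits <- integer()
  if (m > n) return(hits)
  for (i in 1:(n - m + 1)) {
    if (substr(s, i, i + m - 1) == pat) hits <- c(hits, i)
  }
  hits
}

# Shared fixtures, built once per test run.
fixture_env <- new.env()
get_fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env, inherits = FALSE)
}

default_fixture <- function() {
  get_fixture("default_locus", function() make_target_locus(1))
}

default_pool <- function() {
  get_fixture("default_pool", function() {
    make_target_fixtures(1, default_fixture()$design, n_scrambled = 4L)
  })
}

# LE-relative sequence access on a design (test-side convenience)
get_le_seq_pub <- function(design, p1, p2) {
  peelpaste:::get_le_seq(design$le, p1, p2)
}

get_le_seq_public <- function(design) {
  get_le_seq_pub(design, 44L, 43L + design$ext_len)
}
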