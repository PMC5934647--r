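#' Scan sequences for candidate integration sites
#'
#' Finds every occurrence of the 4-nt cleavage/target motif (C_T, natively
#' TTAC for IS608) on the requested strands. Cleavage and integration occur
#' immediately 3' of the motif, so each site is reported with its `+1` base
#' (the first base 3' of the motif in strand orientation) and its upstream
#' context (5' of the motif in strand orientation), which holds the window an
#' engineered extension pairs with.
#'
#' @param seqs Named character vector of sequences, a single sequence, or a
#'   path to a FASTA file.
#' @param ct The 4-mer target motif (default `"TTAC"`).
#' @param both_strands Scan the reverse strand too?
#' @param upstream_len Upstream context length to record (default 20).
#' @return A tibble of sites ordered by source, coordinate and strand, with
#'   columns `source_id`, `ct_start` (0-based leftmost genome coordinate of
#'   the motif, BED-compatible), `strand`, `ct_seq`, `plus1` (NA at a
#'   sequence edge) and `upstream` (possibly shorter than `upstream_len` near
#'   an edge).
#' @export
scan_sites <- function(seqs, ct = "TTAC", both_strands = TRUE,
                       upstream_len = 20L) {
  ct <- check_dna(ct, allow_n = FALSE)
  if (nchar(ct) != 4L) abort("`ct` must be a 4-mer", class = "peelpaste_parameter_error")
  if (length(seqs) == 1L && is.null(names(seqs)) && file.exists(seqs) &&
      !grepl("^[ACGTNacgtn]+$", seqs)) {
    seqs <- read_fasta(seqs)
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  out <- list()
  for (id in names(seqs)) {
    s <- check_dna(seqs[[id]])
    n <- nchar(s)
    strands <- if (both_strands) c("+", "-") else "+"
    for (strand in strands) {
      view <- if (strand == "+") s else revcomp(s)
      hits <- find_all(view, ct)   # 1-based on the strand view
      if (!length(hits)) next
      plus1 <- ifelse(hits + 4L <= n,
                      substring(view, hits + 4L, hits + 4L), NA_character_)
      up_start <- pmax(1L, hits - upstream_len)
      upstream <- substring(view, up_start, hits - 1L)
      ct_start <- if (strand == "+") hits - 1L else n - (hits + 3L)
      out[[length(out) + 1L]] <- tibble(
        source_id = id, ct_start = as.integer(ct_start), strand = strand,
        ct_seq = ct, plus1 = plus1, upstream = upstream
      )
    }
  }
  if (!length(out)) {
    return(tibble(source_id = character(), ct_start = integer(),
                  strand = character(), ct_seq = character(),
                  plus1 = character(), upstream = character()))
  }
  arrange(bind_rows(out), .data$source_id, .data$ct_start, .data$strand)
}

#' Weight of the +1 target base
#'
#' Encodes the measured preference of TnpA for the base immediately 3' of the
#' cleavage site: cytosine supports cleavage best, thymine is intermediate,
#' and the bulkier purines are disfavored by the tight +1 binding pocket. The
#' values are ordinal conventions on (0, 1] with the maximum at C, not
#' measured rates.
#'
#' @param base Single base (or vector of bases) in ACGT.
#' @param weights Named numeric weights in (0, 1].
#' @return Numeric weight(s).
#' @export
plus1_weight <- function(base, weights = plus1_defaults()) {
  base <- toupper(base)
  if (any(is.na(base)) || !all(base %in% DNA_BASES)) {
    abort("`base` must be A, C, G or T", class = "peelpaste_parse_error")
  }
  if (any(weights <= 0) || any(weights > 1)) {
    abort("+1 weights must lie in (0, 1]", class = "peelpaste_config_error")
  }
  unname(weights[base])
}

#' @rdname plus1_weight
#' @export
plus1_defaults <- function() c(A = 0.15, C = 1.0, G = 0.15, T = 0.5)

#' Cooperative match-length weighting
#'
#' Converts the length of contiguous extension/target complementarity into a
#' relative integration weight with a Hill-type curve
#' `coop(m) = floor + (amp - floor) * m^h / (m^h + K^h)`. The shipped
#' calibration encodes two in vitro outcomes: an 8-match target dominates
#' zero-match competitors even at 20-fold excess (`coop(8)/coop(0) >= 40`),
#' while 5 matches give essentially no selection (`coop(5)/coop(0) <= 3`).
#' Both constraints are re-checked numerically on construction.
#'
#' @param floor Weight at zero matched bases.
#' @param amp Weight scale at saturation.
#' @param K Midpoint in matched bases.
#' @param h Hill steepness.
#' @return A `coop_params` list.
#' @export
coop_params <- function(floor = 1, amp = 60, K = 6.8, h = 12) {
  p <- structure(list(floor = floor, amp = amp, K = K, h = h),
                 class = "coop_params")
  validate_coop_params(p)
  p
}

validate_coop_params <- function(p) {
  if (p$floor <= 0 || p$amp < p$floor || p$K <= 0 || p$h <= 0) {
    abort("coop parameters must satisfy 0 < floor <= amp, K > 0, h > 0",
          class = "peelpaste_config_error")
  }
  m <- 0:13
  cc <- coop(m, p)
  if (any(diff(cc) < -1e-12)) {
    abort("coop(m) must be nondecreasing in m", class = "peelpaste_config_error")
  }
  if (coop(8, p) / coop(0, p) < 40) {
    abort("calibration violated: coop(8)/coop(0) must be >= 40 (8-match selectivity)",
          class = "peelpaste_config_error")
  }
  if (coop(5, p) / coop(0, p) > 3) {
    abort("calibration violated: coop(5)/coop(0) must be <= 3 (5-match non-selectivity)",
          class = "peelpaste_config_error")
  }
  invisible(p)
}

#' @rdname coop_params
#' @param m Number of contiguously matched bases (vectorized).
#' @param params A `coop_params` object.
#' @export
coop <- function(m, params = coop_params()) {
  m <- as.numeric(m)
  frac <- ifelse(m <= 0, 0, m^params$h / (m^params$h + params$K^params$h))
  params$floor + (params$amp - params$floor) * frac
}

#' Contiguous complementarity between a design extension and a site
#'
#' Evaluates the design's pairing register against the site's upstream
#' context and returns the length of the longest run of consecutive correct
#' Watson-Crick pairs. Pairing nucleates as a contiguous duplex, so the run
#' length (not the total match count) drives selectivity.
#'
#' @param site A one-row site tibble (from [scan_sites()]) or a list with an
#'   `upstream` field.
#' @param design A `retarget_design`.
#' @return Integer match length, between 0 and the design's extension length.
#' @export
match_len <- function(site, design) {
  upstream <- site$upstream
  ext <- design$extension
  k <- design$linker_len
  L <- nchar(ext)
  U <- nchar(upstream)
  if (U < k + L) {
    abort("insufficient upstream context for the design register",
          class = "peelpaste_bounds_error")
  }
  window <- substr(upstream, U - k - L + 1L, U - k)
  hits <- seq_chars(revcomp(window)) == seq_chars(ext)
  longest_run(hits)
}

longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Build an oligo pool
#'
#' @param oligo Character vector of oligo sequences.
#' @param id Member identifiers.
#' @param rel_conc Relative molar concentrations (finite, at least one > 0).
#' @param role Optional member roles (e.g. `"Tic"`, `"Tr"`, `"Ts"`).
#' @return A tibble with class `oligo_pool`.
#' @export
oligo_pool <- function(oligo, id = paste0("oligo", seq_along(oligo)),
                       rel_conc = 1, role = NA_character_) {
  rel_conc <- rep_len(as.numeric(rel_conc), length(oligo))
  if (any(!is.finite(rel_conc)) || any(rel_conc < 0)) {
    abort("`rel_conc` values must be finite and non-negative",
          class = "peelpaste_parameter_error")
  }
  if (!any(rel_conc > 0)) {
    abort("at least one pool member must have rel_conc > 0",
          class = "peelpaste_parameter_error")
  }
  out <- tibble(id = id, oligo = toupper(oligo), rel_conc = rel_conc,
                role = rep_len(role, length(oligo)))
  class(out) <- c("oligo_pool", class(out))
  out
}

#' Predict competitive target selection within an oligo pool
#'
#' Implements the competition model calibrated to in vitro strand-transfer
#' outcomes: each pool member's integration weight is
#' `rel_conc * plus1_weight(+1 base) * coop(match_len)` and predicted
#' integration fractions are the normalized weights.
#'
#' @param pool An [oligo_pool()] (every member must contain the design's C_T).
#' @param design A `retarget_design`.
#' @param params [coop_params()] calibration.
#' @param plus1_weights +1 base weights, see [plus1_weight()].
#' @return A tibble with one row per member: `id`, `rel_conc`, `match_len`,
#'   `plus1`, `plus1_weight`, `coop`, `weight` and `fraction` (sums to 1).
#' @export
competition <- function(pool, design, params = coop_params(),
                        plus1_weights = plus1_defaults()) {
  ct <- design$site$ct_seq
  rows <- lapply(seq_len(nrow(pool)), function(r) {
    sites <- scan_sites(stats::setNames(pool$oligo[r], pool$id[r]), ct = ct,
                        both_strands = FALSE)
    if (nrow(sites) == 0L) {
      abort(sprintf("pool member %s does not contain C_T (%s)", pool$id[r], ct),
            class = "peelpaste_parameter_error")
    }
    site <- sites[which.max(nchar(sites$upstream)), ]
    m <- match_len(site, design)
    p1 <- site$plus1
    w1 <- if (is.na(p1)) min(plus1_weights) else plus1_weight(p1, plus1_weights)
    tibble(id = pool$id[r], rel_conc = pool$rel_conc[r], match_len = m,
           plus1 = p1, plus1_weight = w1, coop = coop(m, params),
           weight = pool$rel_conc[r] * w1 * coop(m, params))
  })
  out <- bind_rows(rows)
  total <- sum(out$weight)
  if (total <= 0) {
    abort("degenerate pool: all integration weights are zero",
          class = "peelpaste_degenerate_pool_error")
  }
  out$fraction <- out$weight / total
  out
}

#' Off-target survey of a genome for a design
#'
#' Scans a genome for the design's C_T, evaluates extension complementarity
#' at every site, and flags high-risk sites (contiguous match length >= 8,
#' the demonstrated selective length, with the preferred C at +1).
#'
#' @param genome Named character vector of sequences or FASTA path.
#' @param design A `retarget_design`.
#' @param both_strands Scan both strands?
#' @param plus1_weights +1 base weights.
#' @return Site tibble with `match_len`, `plus1_weight` and `high_risk`
#'   columns; sites lacking the register's upstream context get
#'   `match_len = NA`.
#' @export
offtarget_report <- function(genome, design, both_strands = TRUE,
                             plus1_weights = plus1_defaults()) {
  sites <- scan_sites(genome, ct = design$site$ct_seq,
                      both_strands = both_strands)
  if (nrow(sites) == 0L) {
    return(mutate(sites, match_len = integer(), plus1_weight = numeric(),
                  high_risk = logical()))
  }
  need <- design$linker_len + nchar(design$extension)
  sites$match_len <- vapply(seq_len(nrow(sites)), function(r) {
    if (nchar(sites$upstream[r]) < need) return(NA_integer_)
    as.integer(match_len(sites[r, ], design))
  }, integer(1))
  sites$plus1_weight <- ifelse(is.na(sites$plus1), NA_real_,
                               plus1_weight(ifelse(is.na(sites$plus1), "A", sites$plus1),
                                            plus1_weights))
  sites$high_risk <- !is.na(sites$match_len) & sites$match_len >= 8L &
    !is.na(sites$plus1) & sites$plus1 == "C"
  sites
}

#' Write sites as BED6
#'
#' Name encodes `match_len:plus1` when a design is available (otherwise the
#' motif), and the score column encodes `round(1000 * fraction)` clamped to
#' `[0, 1000]` when fractions are present.
#'
#' @param sites Site tibble (optionally with `match_len`/`fraction` columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  if (nrow(sites) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  name <- if ("match_len" %in% names(sites)) {
    paste0(ifelse(is.na(sites$match_len), ".", sites$match_len), ":",
           ifelse(is.na(sites$plus1), ".", sites$plus1))
  } else {
    paste0(sites$ct_seq, ":", ifelse(is.na(sites$plus1), ".", sites$plus1))
  }
  score <- if ("fraction" %in% names(sites)) {
    pmin(1000L, pmax(0L, as.integer(round(1000 * sites$fraction))))
  } else rep(0L, nrow(sites))
  df <- data.frame(sites$source_id, sites$ct_start, sites$ct_start + 4L,
                   name, score, sites$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
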