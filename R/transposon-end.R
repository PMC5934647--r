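#' Annotated single-stranded transposon end
#'
#' The central sequence container of the package: the top strand (5'->3') of a
#' transposon left end (LE), right end (RE) or RE-LE junction, together with a
#' feature map of closed 1-based intervals. Transposon-end positions are
#' 1-based on the top strand and written with a `+` prefix in the IS608
#' literature (`+16...+19` is the guide sequence G_L, `+20...+41` the
#' subterminal palindrome IP_L, `+42`/`+43` the triplet-forming bases,
#' `+44` onward the engineerable extension, `+46...+60` the second hairpin).
#'
#' @param seq DNA string, top strand 5'->3'.
#' @param role One of `"LE"`, `"RE"`, `"junction"`.
#' @param features Named list of length-2 integer vectors `c(start, end)`.
#' @param label_5prime Radiolabel bookkeeping flag: is the 5' end labeled?
#' @param circular Is this a circularized junction represented linearly,
#'   opened at the RE-LE joint?
#' @param le_start For junction oligos, the 1-based position where the LE
#'   portion begins (so LE position `+p` sits at `le_start + p - 1`).
#' @return A `transposon_end` object.
#' @export
transposon_end <- function(seq, role = c("LE", "RE", "junction"),
                           features = list(), label_5prime = FALSE,
                           circular = FALSE, le_start = 1L) {
  seq <- check_dna(seq)
  role <- match.arg(role)
  x <- structure(
    list(seq = seq, role = role, features = features,
         label_5prime = isTRUE(label_5prime), circular = isTRUE(circular),
         le_start = as.integer(le_start)),
    class = "transposon_end"
  )
  validate_transposon_end(x)
  x
}

validate_transposon_end <- function(x) {
  n <- nchar(x$seq)
  for (nm in names(x$features)) {
    iv <- x$features[[nm]]
    if (length(iv) != 2L || iv[1] < 1L || iv[2] > n || iv[1] > iv[2]) {
      abort(sprintf("feature %s outside [1, %d]", nm, n),
            class = "peelpaste_feature_error")
    }
  }
  if (x$role == "LE") {
    need <- c("GL", "IPL")
    miss <- setdiff(need, names(x$features))
    if (length(miss)) {
      abort(sprintf("LE missing feature(s): %s", paste(miss, collapse = ", ")),
            class = "peelpaste_feature_error")
    }
    gl <- x$features$GL; ipl <- x$features$IPL
    if (diff(gl) != 3L) abort("GL must span 4 nt", class = "peelpaste_feature_error")
    if (diff(ipl) < 9L) abort("IPL must span >= 10 nt", class = "peelpaste_feature_error")
    if (gl[2] >= ipl[1]) abort("GL must end before IPL begins", class = "peelpaste_feature_error")
    if (!is.null(x$features$EXT)) {
      ext <- x$features$EXT
      if (diff(ext) + 1L > 13L) abort("EXT longer than 13 nt", class = "peelpaste_feature_error")
      if (ext[1] <= ipl[2]) abort("EXT must begin after IPL ends", class = "peelpaste_feature_error")
    }
  }
  invisible(x)
}

#' @export
print.transposon_end <- function(x, ...) {
  cat(sprintf("<transposon_end:%s> %d nt%s%s\n", x$role, nchar(x$seq),
              if (x$label_5prime) ", 5'-labeled" else "",
              if (x$circular) ", circular (opened at RE-LE joint)" else ""))
  cat(x$seq, "\n")
  if (length(x$features)) {
    f <- tidy(x)
    cat(paste(sprintf("  %s [%d,%d]", f$feature, f$start, f$end), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @method tidy transposon_end
#' @export
tidy.transposon_end <- function(x, ...) {
  if (!length(x$features)) {
    return(tibble(feature = character(), start = integer(), end = integer(),
                  seq = character()))
  }
  tibble(
    feature = names(x$features),
    start = vapply(x$features, `[`, integer(1), 1L),
    end = vapply(x$features, `[`, integer(1), 2L),
    seq = vapply(x$features, function(iv) subseq_str(x$seq, iv[1], iv[2]), character(1))
  )
}

# Sequence at a feature, or "" when absent.
feature_seq <- function(end, name) {
  iv <- end$features[[name]]
  if (is.null(iv)) return("")
  subseq_str(end$seq, iv[1], iv[2])
}

# LE-relative position +p expressed in the object's own coordinates.
le_pos <- function(end, p) end$le_start + as.integer(p) - 1L

# Replace LE-relative positions [p1, p2] with `value`.
set_le_seq <- function(end, p1, p2, value) {
  a <- le_pos(end, p1); b <- le_pos(end, p2)
  subseq_str(end$seq, a, b) <- toupper(value)
  end
}

get_le_seq <- function(end, p1, p2) {
  subseq_str(end$seq, le_pos(end, p1), le_pos(end, p2))
}

# --- fixture architecture constants (LE-relative) ----------------------------
LE_LEN <- 65L
GL_IV <- c(16L, 19L)
IPL_IV <- c(20L, 41L)
IPL_ARM <- 9L
HP2_IV <- c(46L, 60L)
HP2_ARM <- 6L
JOINT_LEN <- 50L

# Placeholder extension content is neutral A filler: designs overwrite the
# extension window, and inert placeholders keep it fold-accessible.
build_le_seq <- function(arm, hp_arm, with_second_hairpin) {
  leader <- strrep("A", 15L)
  stem <- paste0(arm, "AAAA", revcomp(arm))              # +20..+41
  after <- rep("A", LE_LEN - 43L)                        # +44..+65
  if (with_second_hairpin) {
    hp <- paste0(hp_arm, "AAA", revcomp(hp_arm))         # +46..+60
    after[3:17] <- seq_chars(hp)
  }
  paste0(leader, "AAAG", stem, "A", "T", paste(after, collapse = ""))
}

#' Generate a synthetic transposon left end
#'
#' Builds a seeded, reproducible LE oligo with the IS608 left-end
#' architecture: guide sequence G_L = AAAG at +16...+19, a perfect-palindrome
#' IP_L stem-loop at +20...+41 (9 bp stem, 4 nt loop), A at +42 and T at +43,
#' an extension window starting at +44, and optionally a second hairpin whose
#' fold-detected span covers +46...+60. Stems are drawn over G/C and filler
#' over A so that the maximum-weight fold reproduces the intended secondary
#' structure; the generator verifies its structural postconditions with
#' [fold()] and resamples deterministically until they hold.
#'
#' @param seed Integer seed; identical seeds give identical ends.
#' @param ext_len Extension length at +44, between 0 and 13.
#' @param with_second_hairpin Plant the occluding +46...+60 hairpin?
#' @param params Fold parameters used for the structural self-check.
#' @return A `transposon_end` with role `"LE"`.
#' @examples
#' le <- make_synthetic_le(1, ext_len = 8)
#' substr(le$seq, 16, 19)  # AAAG
#' @export
make_synthetic_le <- function(seed, ext_len = 8L, with_second_hairpin = FALSE,
                              params = fold_params()) {
  ext_len <- as.integer(ext_len)
  if (is.na(ext_len) || ext_len < 0L || ext_len > 13L) {
    abort("`ext_len` must be between 0 and 13.", class = "peelpaste_parameter_error")
  }
  with_seed(seed, {
    for (attempt in 1:200) {
      arm <- random_dna(IPL_ARM, c("G", "C"))
      hp_arm <- random_dna(HP2_ARM, c("G", "C"))
      seq <- build_le_seq(arm, hp_arm, with_second_hairpin)
      if (grepl("TTAC", seq, fixed = TRUE) || grepl("TCAA", seq, fixed = TRUE)) next
      f <- fold(seq, params)
      hp <- find_hairpins(f, min_stem = 3L)
      ipl_ok <- any(hp$outer_start <= IPL_IV[1] & hp$outer_end >= IPL_IV[2])
      if (!ipl_ok) next
      acc <- accessibility(f, c(44L, 51L))
      if (with_second_hairpin) {
        hp2_ok <- any(hp$outer_start <= HP2_IV[1] & hp$outer_end >= HP2_IV[2])
        if (!hp2_ok || acc >= 0.9) next
      } else {
        if (acc < 0.9) next
      }
      features <- list(GL = GL_IV, IPL = IPL_IV)
      if (ext_len > 0L) features$EXT <- c(44L, 43L + ext_len)
      if (with_second_hairpin) features$HP2 <- HP2_IV
      return(transposon_end(seq, role = "LE", features = features))
    }
    abort("could not satisfy structural constraints after 200 draws",
          class = "peelpaste_generation_error")
  })
}

#' Build the canonical assay junction oligo
#'
#' Assembles a 5'-labeled RE-LE junction oligo with the strand-transfer assay
#' layout: the segment from the 5' terminus to the cleavage position is
#' exactly 50 nt and carries the RE-LE joint features (guide G_R = GAAT and
#' the joint cleavage motif C_R = TCAA, whose 3' boundary defines the cut);
#' the LE portion follows. The cleavage position is always recovered from the
#' feature map by the simulator, never from a stored length.
#'
#' @param seed Integer seed for the synthetic LE portion (ignored when a
#'   design is supplied).
#' @param design Optional `retarget_design`; its engineered LE is substituted
#'   into the LE portion.
#' @param ext_len,with_second_hairpin Passed to [make_synthetic_le()] when no
#'   design is supplied.
#' @return A `transposon_end` with role `"junction"`, `label_5prime = TRUE`.
#' @export
make_canonical_junction <- function(seed, design = NULL, ext_len = 8L,
                                    with_second_hairpin = FALSE) {
  le <- if (!is.null(design)) design$le else {
    make_synthetic_le(seed, ext_len = ext_len,
                      with_second_hairpin = with_second_hairpin)
  }
  junction_from_le(le)
}

# 50-nt joint segment: A filler, G_R GAAT at 20..23, C_R TCAA at 47..50.
joint_segment <- function() {
  j <- rep("A", JOINT_LEN)
  j[20:23] <- c("G", "A", "A", "T")
  j[47:50] <- c("T", "C", "A", "A")
  paste(j, collapse = "")
}

junction_from_le <- function(le) {
  joint <- joint_segment()
  feats <- list(JOINT = c(1L, JOINT_LEN), GR = c(20L, 23L), CR = c(47L, 50L))
  for (nm in names(le$features)) {
    feats[[nm]] <- le$features[[nm]] + JOINT_LEN
  }
  transposon_end(paste0(joint, le$seq), role = "junction", features = feats,
                 label_5prime = TRUE, le_start = JOINT_LEN + 1L)
}

# Extract the LE portion of a junction as a standalone LE object.
le_from_junction <- function(junction) {
  off <- junction$le_start - 1L
  le_feats <- junction$features[setdiff(names(junction$features),
                                        c("JOINT", "GR", "CR"))]
  le_feats <- lapply(le_feats, function(iv) iv - off)
  transposon_end(subseq_str(junction$seq, junction$le_start, nchar(junction$seq)),
                 role = "LE", features = le_feats)
}

#' Serialize a transposon end to JSON
#'
#' Feature intervals survive the round trip unchanged.
#'
#' @param end A `transposon_end`.
#' @param path Optional path; when given the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
end_to_json <- function(end, path = NULL) {
  x <- list(seq = end$seq, role = end$role,
            features = lapply(end$features, as.integer),
            label_5prime = end$label_5prime, circular = end$circular,
            le_start = end$le_start)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a transposon end from JSON
#'
#' @param json JSON string or path to a JSON file.
#' @return A `transposon_end`.
#' @export
end_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  transposon_end(x$seq, role = x$role,
                 features = lapply(x$features, as.integer),
                 label_5prime = x$label_5prime, circular = x$circular,
                 le_start = x$le_start)
}
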