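#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows group_by ungroup summarise
#' @importFrom stats runif
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Check a DNA string
#'
#' Validates that a string uses the ACGTN alphabet (uppercased first).
#'
#' @param seq A single character string.
#' @param allow_n Allow the ambiguity code N?
#' @return The validated, uppercased sequence (invisibly usable).
#' @keywords internal
check_dna <- function(seq, allow_n = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort("`seq` must be a single DNA string.", class = "peelpaste_parse_error")
  }
  seq <- toupper(seq)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", alphabet), "", seq)
  if (nzchar(bad)) {
    abort(
      sprintf("Non-IUPAC character(s) in sequence: %s", substr(bad, 1, 10)),
      class = "peelpaste_parse_error"
    )
  }
  seq
}

#' Reverse complement of a DNA sequence
#'
#' @param seq A DNA string over ACGTN (case-insensitive); N maps to N.
#' @return The reverse complement, uppercase.
#' @examples
#' revcomp("TTAC")
#' @export
revcomp <- function(seq) {
  seq <- check_dna(seq)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Complement (no reversal) of a DNA sequence
#' @inheritParams revcomp
#' @return The complemented sequence in the original orientation.
#' @export
complement <- function(seq) {
  seq <- check_dna(seq)
  chartr("ACGTN", "TGCAN", seq)
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

subseq_str <- function(seq, start, end) {
  if (start < 1L || end > nchar(seq) || start > end + 1L) {
    abort("Interval outside sequence bounds.", class = "peelpaste_bounds_error")
  }
  if (start > end) return("")
  substr(seq, start, end)
}

`subseq_str<-` <- function(seq, start, end, value) {
  stopifnot(nchar(value) == end - start + 1L)
  substr(seq, start, end) <- value
  seq
}

#' Read a FASTA file into a named character vector
#'
#' Uses Biostrings when available, with a minimal plain-text fallback.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    out <- toupper(as.character(x))
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  lines <- readLines(path)
  idx <- grep("^>", lines)
  if (length(idx) == 0L) {
    if (all(!nzchar(lines))) return(character())
    abort(sprintf("Malformed FASTA (no header): %s", path),
          class = "peelpaste_parse_error")
  }
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[idx])
  starts <- idx + 1L
  ends <- c(idx[-1L] - 1L, length(lines))
  out <- vapply(seq_along(idx), function(i) {
    if (starts[i] > ends[i]) return("")
    toupper(paste(lines[starts[i]:ends[i]], collapse = ""))
  }, character(1))
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i] %||% paste0("seq", i)), con)
    s <- seqs[[i]]
    if (nchar(s)) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

# Deterministic RNG scope: runs `expr` under a seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

random_dna <- function(n, alphabet = DNA_BASES) {
  if (n <= 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# All start positions (1-based) of fixed pattern `pat` in `seq`, overlaps included.
find_all <- function(seq, pat) {
  hits <- integer()
  from <- 1L
  repeat {
    p <- regexpr(pat, substr(seq, from, nchar(seq)), fixed = TRUE)
    if (p < 0L) break
    hits <- c(hits, from + as.integer(p) - 1L)
    from <- from + as.integer(p)
  }
  hits
}
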