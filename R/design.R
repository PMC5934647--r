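#' Guide-to-target position map for C_T resetting
#'
#' Maps cleavage-relative target positions (C_T occupies -4...-1) to the LE
#' guide positions that read them by base pairing. The target capture complex
#' names only two guide pairs (A+17 with T-4 and A+16 with T-3), so only -4
#' and -3 are resettable by default; users may extend the map explicitly, at
#' their own risk, for the unassigned -2/-1 positions.
#'
#' @param entries Named integer vector: names are target positions
#'   (`"-4"`, `"-3"`, ...), values LE guide positions.
#' @return Validated named integer vector.
#' @export
gl_ct_map <- function(entries = c(`-4` = 17L, `-3` = 16L)) {
  entries <- as.integer(entries) |> stats::setNames(names(entries))
  if (anyDuplicated(entries)) abort("guide positions must be distinct",
                                    class = "peelpaste_parameter_error")
  entries
}

new_design <- function(le, junction, site, target_source, ext_len, linker_len,
                       extension, register, validation = list()) {
  structure(
    list(le = le, junction = junction, site = site,
         target_source = target_source,
         ext_len = as.integer(ext_len), linker_len = as.integer(linker_len),
         extension = extension, recognized_len = 4L + as.integer(ext_len),
         register = register, validation = validation),
    class = "retarget_design"
  )
}

#' @export
print.retarget_design <- function(x, ...) {
  cat(sprintf("<retarget_design> %d-nt extension, %d-nt linker; recognizes a %d-nt site\n",
              x$ext_len, x$linker_len, x$recognized_len))
  cat(sprintf("  C_T %s | extension +44..+%d: %s\n", x$site$ct_seq,
              43L + x$ext_len, x$extension))
  if (length(x$validation)) {
    ck <- x$validation$checks
    if (!is.null(ck)) {
      cat(sprintf("  validation: %s\n",
                  paste(sprintf("%s=%s", ck$check, ifelse(ck$pass, "pass", "FAIL")),
                        collapse = " ")))
    }
  }
  invisible(x)
}

build_register <- function(ext_len, linker_len) {
  gl <- tibble(le_pos = c(16L, 17L), target_pos = c(-3L, -4L), kind = "WC")
  triplet <- tibble(le_pos = c(42L, 43L), target_pos = c(-4L, -3L),
                    kind = "triplet")
  ext <- tibble(le_pos = 43L + seq_len(ext_len),
                target_pos = -(linker_len + 4L + seq_len(ext_len)),
                kind = "WC")
  bind_rows(gl, triplet, ext)
}

#' Design an extension that retargets integration to a chosen site
#'
#' Implements the retargeting strategy: the LE bases at +44 onward are
#' replaced by the reverse complement of the target window sitting
#' `linker_len` nt upstream of C_T (for the defaults, target positions
#' -15...-8), so the transposon recognizes a `4 + ext_len` nt site — the
#' native 4-nt guide/C_T interaction plus the engineered duplex. LE +44 pairs
#' target -(linker_len + 5) and the register proceeds antiparallel. The 3-nt
#' linker leaves the duplex room to reach the cleavage site: in the capture
#' complex the target 5' end (-5) sits 10.5 A from the +44 phosphate.
#'
#' @param locus DNA string (or named length-1 vector) containing the site.
#' @param site One-row site tibble from [scan_sites()], or a list with
#'   `ct_seq`, `plus1` and `upstream` fields.
#' @param ext_len Extension length; 8-13 are supported (5-7 are accepted with
#'   a warning: 5 bp of complementarity gives no efficient selection).
#' @param linker_len Unpaired linker between the window and C_T; default 3
#'   (2-5 accepted, with a warning away from 3).
#' @param end Optional LE template (`transposon_end`); by default a
#'   wild-type-like synthetic LE carrying the occluding second hairpin.
#' @param template_seed Seed for the default template.
#' @return A `retarget_design` (not yet unlocked or validated; see
#'   [apply_structural_unlocking()] and [validate_design()]).
#' @export
design_extension <- function(locus, site, ext_len = 8L, linker_len = 3L,
                             end = NULL, template_seed = 608L) {
  ext_len <- as.integer(ext_len)
  linker_len <- as.integer(linker_len)
  if (ext_len > 13L) {
    abort("ext_len > 13 is unsupported (no demonstrated selection beyond 13)",
          class = "peelpaste_parameter_error")
  }
  if (ext_len < 5L) {
    abort("ext_len < 5 cannot select targets", class = "peelpaste_parameter_error")
  }
  if (ext_len < 8L) {
    warn(sprintf("ext_len = %d: 5 bp of complementarity did not enable efficient target selection in vitro; 8-13 recommended", ext_len))
  }
  if (linker_len < 2L || linker_len > 5L) {
    abort("linker_len must be between 2 and 5", class = "peelpaste_parameter_error")
  }
  if (linker_len != 3L) {
    warn("linker_len != 3: a 3-nt linker best supported cleavage in vitro")
  }
  upstream <- site$upstream
  U <- nchar(upstream)
  if (U < linker_len + ext_len) {
    abort("site too close to the locus 5' end for the requested register",
          class = "peelpaste_bounds_error")
  }
  window <- substr(upstream, U - linker_len - ext_len + 1L, U - linker_len)
  extension <- revcomp(window)

  le <- end %||% make_synthetic_le(template_seed, ext_len = 0L,
                                   with_second_hairpin = TRUE)
  le <- set_le_seq(le, 44L, 43L + ext_len, extension)
  le$features$EXT <- c(44L, 43L + ext_len)
  validate_transposon_end(le)

  site_row <- as_tibble(site[c("source_id", "ct_start", "strand", "ct_seq",
                               "plus1", "upstream")[
                                 c("source_id", "ct_start", "strand", "ct_seq",
                                   "plus1", "upstream") %in% names(site)]])
  src <- if ("source_id" %in% names(site_row)) site_row$source_id else "locus"
  new_design(
    le = le, junction = junction_from_le(le), site = site_row,
    target_source = src, ext_len = ext_len, linker_len = linker_len,
    extension = extension,
    register = build_register(ext_len, linker_len)
  )
}

transversions <- function(base) {
  switch(base, A = c("C", "T"), G = c("C", "T"), C = c("A", "G"),
         T = c("A", "G"))
}
transition <- function(base) {
  switch(base, A = "G", G = "A", C = "T", T = "C")
}

ext_window_on_junction <- function(design) {
  c(le_pos(design$junction, 44L),
    le_pos(design$junction, 43L + design$ext_len))
}

ext_accessibility <- function(design, params = fold_params()) {
  f <- fold(design$junction$seq, params)
  accessibility(f, ext_window_on_junction(design))
}

#' Open the secondary structure that occludes the extension
#'
#' The wild-type element keeps its extension window buried: a second hairpin
#' at +46...+60 spans the retargeting bases, and the bulky triplet-forming A
#' at +42 adds steric constraint. This operation mutates +42 to T (a T-AT
#' triplet is more stable and less constrained than A-AT) and, while the
#' extension window folds to less than `threshold` accessibility, greedily
#' introduces single-base substitutions confined to +55...+60 — transversions
#' tried first, positions scanned 5' to 3', refolding after each edit — until
#' the window is free. G_L, IP_L, +43 and the extension itself are never
#' edited.
#'
#' @param design A `retarget_design`.
#' @param max_mut Maximum number of +55...+60 substitutions (default 6).
#' @param threshold Required unpaired fraction of the extension window.
#' @param params Fold parameters.
#' @return The design with edits recorded in `validation$unlocking`; if the
#'   threshold is unreachable within `max_mut` edits, the design is returned
#'   with `unlocking$pass = FALSE` and the best structure found (a
#'   design-failure result, not an error).
#' @export
apply_structural_unlocking <- function(design, max_mut = 6L, threshold = 0.9,
                                       params = fold_params()) {
  edits <- list()
  le <- design$le
  if (get_le_seq(le, 42L, 42L) != "T") {
    edits[[length(edits) + 1L]] <- list(pos = 42L,
                                        from = get_le_seq(le, 42L, 42L), to = "T")
    le <- set_le_seq(le, 42L, 42L, "T")
  }
  design$le <- le
  design$junction <- junction_from_le(le)

  mutable <- setdiff(55:60, seq(44L, 43L + design$ext_len))
  acc <- ext_accessibility(design, params)
  n_mut <- 0L
  while (acc < threshold && n_mut < max_mut && length(mutable)) {
    best <- NULL
    for (p in sort(mutable)) {
      cur <- get_le_seq(design$le, p, p)
      for (b in c(transversions(cur), transition(cur))) {
        cand_le <- set_le_seq(design$le, p, p, b)
        cand <- design
        cand$le <- cand_le
        cand$junction <- junction_from_le(cand_le)
        a <- ext_accessibility(cand, params)
        if (is.null(best) || a > best$acc + 1e-12) {
          best <- list(acc = a, pos = p, from = cur, to = b, design = cand)
        }
      }
    }
    if (is.null(best) || best$acc <= acc + 1e-12) break  # no progress
    design <- best$design
    edits[[length(edits) + 1L]] <- list(pos = best$pos, from = best$from,
                                        to = best$to)
    acc <- best$acc
    n_mut <- n_mut + 1L
  }
  design$validation$unlocking <- list(
    edits = edits, accessibility = acc, threshold = threshold,
    pass = acc >= threshold
  )
  design
}

#' Retarget the core C_T tetranucleotide
#'
#' Redirects integration to an alternative 4-nt target sequence by mutating
#' the LE guide bases that read the changed positions. Only positions with a
#' guide assignment in `map` (-4 and -3 by default) can be reset; requesting
#' a change at an unmapped position is an error listing the offending
#' positions. Extended-complementarity designs combine freely with C_T
#' resetting.
#'
#' @param design A `retarget_design`.
#' @param new_ct The new 4-mer C_T (positions -4...-1).
#' @param map A [gl_ct_map()].
#' @return The design with guide edits applied, `site$ct_seq` updated and
#'   register kinds at reset positions set to `"WC"`.
#' @export
reset_ct <- function(design, new_ct, map = gl_ct_map()) {
  new_ct <- check_dna(new_ct, allow_n = FALSE)
  if (nchar(new_ct) != 4L) abort("`new_ct` must be a 4-mer",
                                 class = "peelpaste_parameter_error")
  old_ct <- design$site$ct_seq
  oldc <- seq_chars(old_ct); newc <- seq_chars(new_ct)
  changed <- which(oldc != newc)
  target_pos <- changed - 5L                       # index 1 -> -4, ..., 4 -> -1
  unmapped <- target_pos[!(as.character(target_pos) %in% names(map))]
  if (length(unmapped)) {
    abort(sprintf("no guide assignment for target position(s) %s; extend gl_ct_map() explicitly",
                  paste(unmapped, collapse = ", ")),
          class = "peelpaste_unsupported_position_error")
  }
  edits <- list()
  for (i in seq_along(changed)) {
    p <- target_pos[i]
    lp <- map[[as.character(p)]]
    newbase <- complement(newc[changed[i]])
    oldbase <- get_le_seq(design$le, lp, lp)
    design$le <- set_le_seq(design$le, lp, lp, newbase)
    edits[[length(edits) + 1L]] <- list(le_pos = lp, target_pos = p,
                                        from = oldbase, to = newbase)
    design$register$kind[design$register$le_pos == lp &
                           design$register$target_pos == p] <- "WC"
  }
  design$junction <- junction_from_le(design$le)
  design$site$ct_seq <- new_ct
  design$validation$ct_reset <- list(new_ct = new_ct, edits = edits)
  design
}

#' Validate a retargeting design
#'
#' Runs the design checks the retargeting strategy depends on and records a
#' pass/fail report: extension-window accessibility in the folded junction;
#' a self-complementarity guard (no >= 6 nt reverse-complement match between
#' the extension and any other LE window, which would fold the extension
#' away); an unintended-C_T guard (the engineered junction must not gain an
#' extra cleavage motif); the +42 unlocking mutation; and, when a genome is
#' supplied, an off-target survey (no high-risk site beyond the intended
#' one). The overall design passes iff all checks pass.
#'
#' @param design A `retarget_design`.
#' @param genome Optional genome (named character vector or FASTA path) for
#'   the off-target check.
#' @param threshold Accessibility threshold (default 0.9).
#' @param params Fold parameters.
#' @return The design with `validation$checks` (tibble) and
#'   `validation$overall` filled in.
#' @export
validate_design <- function(design, genome = NULL, threshold = 0.9,
                            params = fold_params()) {
  checks <- list()
  add <- function(check, pass, details) {
    checks[[length(checks) + 1L]] <<- tibble(check = check, pass = pass,
                                             details = details)
  }

  acc <- ext_accessibility(design, params)
  add("extension_accessibility", acc >= threshold,
      sprintf("unpaired fraction %.3f (threshold %.2f)", acc, threshold))

  ext <- design$extension
  jseq <- design$junction$seq
  ext_iv <- ext_window_on_junction(design)
  le_region_start <- design$junction$le_start
  selfhit <- FALSE
  if (nchar(ext) >= 6L) {
    for (s in 1:(nchar(ext) - 5L)) {
      pat <- revcomp(substr(ext, s, s + 5L))
      for (h in find_all(jseq, pat)) {
        if (h + 5L < ext_iv[1] || h > ext_iv[2]) {
          if (h >= le_region_start || h + 5L >= le_region_start) selfhit <- TRUE
        }
      }
    }
  }
  add("self_complementarity", !selfhit,
      if (selfhit) "extension has a >= 6 nt reverse-complement match elsewhere in the LE"
      else "no >= 6 nt reverse-complement match between extension and other LE windows")

  ct <- design$site$ct_seq
  hits <- find_all(jseq, ct)
  allowed <- lapply(c("CT", "CR", "CL"), function(nm) design$junction$features[[nm]])
  allowed <- allowed[!vapply(allowed, is.null, logical(1))]
  stray <- vapply(hits, function(h) {
    !any(vapply(allowed, function(iv) h == iv[1] && h + 3L == iv[2], logical(1)))
  }, logical(1))
  add("unintended_ct", !any(stray),
      sprintf("%d unregistered occurrence(s) of %s in the junction",
              sum(stray), ct))

  add("plus42_is_T", get_le_seq(design$le, 42L, 42L) == "T",
      sprintf("+42 is %s (T minimizes steric constraint while keeping the triplet)",
              get_le_seq(design$le, 42L, 42L)))

  if (!is.null(genome)) {
    ot <- offtarget_report(genome, design)
    intended <- ot$source_id == (design$site$source_id %||% "") &
      ot$ct_start == (design$site$ct_start %||% -1L) &
      ot$strand == (design$site$strand %||% "+")
    n_risk <- sum(ot$high_risk & !intended, na.rm = TRUE)
    add("offtarget", n_risk == 0L,
        sprintf("%d high-risk off-target site(s) (match >= 8 with +1 = C); %d site(s) scanned",
                n_risk, nrow(ot)))
    design$validation$offtarget <- ot
  }

  checks <- bind_rows(checks)
  design$validation$checks <- checks
  design$validation$overall <- all(checks$pass)
  design
}

#' @method tidy retarget_design
#' @export
tidy.retarget_design <- function(x, ...) {
  x$validation$checks %||%
    tibble(check = character(), pass = logical(), details = character())
}

#' @method glance retarget_design
#' @export
glance.retarget_design <- function(x, ...) {
  tibble(
    ext_len = x$ext_len, linker_len = x$linker_len,
    recognized_len = x$recognized_len, ct = x$site$ct_seq,
    n_unlock_edits = length(x$validation$unlocking$edits %||% list()),
    accessibility = x$validation$unlocking$accessibility %||% NA_real_,
    overall_pass = x$validation$overall %||% NA
  )
}

#' Serialize a design report
#'
#' Writes a JSON report carrying the sequences, feature maps, pairing
#' register, edits and validation outcomes of a design. Feature intervals
#' survive the round trip unchanged.
#'
#' @param design A `retarget_design`.
#' @param path Optional output path.
#' @return The report as a list (invisibly when `path` is given).
#' @export
design_report <- function(design, path = NULL) {
  rep <- list(
    target_source = design$target_source,
    site = as.list(design$site),
    ext_len = design$ext_len, linker_len = design$linker_len,
    extension = design$extension, recognized_len = design$recognized_len,
    junction = list(seq = design$junction$seq,
                    features = lapply(design$junction$features, as.integer),
                    le_start = design$junction$le_start),
    le = list(seq = design$le$seq,
              features = lapply(design$le$features, as.integer)),
    register = as.list(design$register),
    unlocking = design$validation$unlocking,
    ct_reset = design$validation$ct_reset,
    checks = if (!is.null(design$validation$checks)) as.list(design$validation$checks),
    overall = design$validation$overall
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
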