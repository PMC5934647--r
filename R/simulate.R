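#' Cleave a target oligo 3' of its C_T motif
#'
#' Locates the single C_T occurrence by sequence search and places the cut
#' immediately 3' of it. The downstream segment leaves the reaction
#' covalently attached to the transposase through a 5' phosphotyrosine; the
#' upstream segment ends in a free 3'-OH, ready for strand transfer.
#'
#' @param target DNA string (optionally named; the name becomes the
#'   substrate id).
#' @param ct The 4-nt cleavage motif.
#' @param labeled Is the substrate 5'-radiolabeled?
#' @param id Substrate identifier (defaults to the name of `target`).
#' @return A `cleavage_event`: `substrate_id`, `cut_after` (0-based index of
#'   the last base 5' of the cut), `upstream_len`, `downstream_len`,
#'   `covalent_attachment`, plus the two segment sequences.
#' @export
cleave_target <- function(target, ct = "TTAC", labeled = FALSE, id = NULL) {
  id <- id %||% names(target) %||% "target"
  seq <- check_dna(unname(target[[1]]))
  hits <- find_all(seq, check_dna(ct, allow_n = FALSE))
  if (length(hits) != 1L) {
    abort(sprintf("substrate %s contains %d occurrence(s) of %s; cleavage requires exactly one",
                  id, length(hits), ct),
          class = "peelpaste_ambiguity_error")
  }
  cut <- hits + 3L                               # 1-based last upstream base
  new_cleavage_event(id, seq, cut, labeled)
}

new_cleavage_event <- function(id, seq, cut, labeled) {
  n <- nchar(seq)
  down <- n - cut
  structure(
    list(
      substrate_id = id,
      cut_after = cut - 1L,                      # 0-based
      upstream_len = cut,
      downstream_len = down,
      covalent_attachment = if (down > 0L) "enzyme_5prime_phosphotyrosine" else "none",
      upstream_seq = substr(seq, 1L, cut),
      downstream_seq = if (down > 0L) substr(seq, cut + 1L, n) else "",
      labeled_5prime = isTRUE(labeled)
    ),
    class = "cleavage_event"
  )
}

#' @export
print.cleavage_event <- function(x, ...) {
  cat(sprintf("<cleavage_event> %s: cut after base %d (%d | %d nt); %s\n",
              x$substrate_id, x$upstream_len, x$upstream_len,
              x$downstream_len, x$covalent_attachment))
  invisible(x)
}

#' Cleave a transposon end / junction at its registered motif
#'
#' The cleavage position is recovered from the feature map at run time (the
#' 3' boundary of the CT, CR or CL feature, in that priority), never from a
#' stored segment length.
#'
#' @param end A `transposon_end` whose features register a cleavage motif.
#' @return A `cleavage_event`.
#' @export
cleave_end <- function(end) {
  for (nm in c("CT", "CR", "CL")) {
    iv <- end$features[[nm]]
    if (!is.null(iv)) {
      return(new_cleavage_event(paste0("junction:", nm), end$seq, iv[2],
                                end$label_5prime))
    }
  }
  abort("no cleavage motif feature (CT/CR/CL) registered on this end",
        class = "peelpaste_feature_error")
}

#' Excise a transposon from a single-stranded donor
#'
#' Models the peel-and-paste excision step: the element between `le_start`
#' and `re_end` is peeled out as a circular RE-LE junction (represented
#' linearly, opened at the joint) and the donor backbone is sealed, retaining
#' the C_L motif (TTAC) in the left flank. No bases are created or
#' destroyed.
#'
#' @param donor DNA string, or a list from [make_donor()].
#' @param le_start 1-based first base of the element.
#' @param re_end 1-based last base of the element.
#' @return List with `sealed_donor` (string) and `junction`
#'   (`transposon_end`, `circular = TRUE`).
#' @export
excise <- function(donor, le_start = NULL, re_end = NULL) {
  if (is.list(donor)) {
    le_start <- le_start %||% donor$le_start
    re_end <- re_end %||% donor$re_end
    donor <- donor$seq
  }
  donor <- check_dna(donor)
  if (le_start < 5L || re_end > nchar(donor) || le_start >= re_end) {
    abort("element bounds outside the donor", class = "peelpaste_bounds_error")
  }
  if (subseq_str(donor, le_start - 4L, le_start - 1L) != "TTAC") {
    abort("C_L (TTAC) must lie immediately 5' of the element",
          class = "peelpaste_precondition_error")
  }
  jseq <- subseq_str(donor, le_start, re_end)
  feats <- list()
  if (substr(jseq, nchar(jseq) - 3L, nchar(jseq)) == "TCAA") {
    feats$CR <- c(nchar(jseq) - 3L, nchar(jseq))
  }
  junction <- transposon_end(jseq, role = "junction", features = feats,
                             circular = TRUE)
  sealed <- paste0(subseq_str(donor, 1L, le_start - 1L),
                   subseq_str(donor, re_end + 1L, nchar(donor)))
  list(sealed_donor = sealed, junction = junction)
}

#' Integrate a junction into a target
#'
#' Cleaves the target 3' of its C_T and joins junction and target segments.
#' For a circular (excised) junction the whole element is inserted between
#' the target segments — excision followed by integration into the sealed
#' donor's retained C_L reconstitutes the original donor exactly. For a
#' linear assay junction the strand-transfer product is the junction's 5'
#' cleavage segment joined to the target's 3' segment, the species followed
#' on sequencing gels; it is labeled iff the junction carries the 5' label.
#'
#' @param junction A `transposon_end` with role `"junction"`.
#' @param target Target DNA string (optionally named).
#' @param ct Target cleavage motif.
#' @param id Product identifier.
#' @return A `transfer_product`: `id`, `seq`, `length`, `composition`
#'   (tibble of source segments) and `labeled`.
#' @export
integrate <- function(junction, target, ct = "TTAC", id = NULL) {
  tid <- names(target) %||% "target"
  ev <- cleave_target(target, ct, id = tid)
  if (junction$circular) {
    seq <- paste0(ev$upstream_seq, junction$seq, ev$downstream_seq)
    comp <- tibble(
      source_id = c(tid, "junction", tid),
      start = c(1L, 1L, ev$upstream_len + 1L),
      end = c(ev$upstream_len, nchar(junction$seq),
              ev$upstream_len + ev$downstream_len)
    )
    comp <- comp[comp$start <= comp$end, ]
    labeled <- FALSE                       # 5'-most segment is target-derived
    pid <- id %||% sprintf("insertion:%s", tid)
  } else {
    jev <- cleave_end(junction)
    seq <- paste0(jev$upstream_seq, ev$downstream_seq)
    comp <- tibble(
      source_id = c("junction", tid),
      start = c(1L, ev$upstream_len + 1L),
      end = c(jev$upstream_len, ev$upstream_len + ev$downstream_len)
    )
    comp <- comp[comp$start <= comp$end, ]
    labeled <- junction$label_5prime
    pid <- id %||% sprintf("transfer:%s", tid)
  }
  structure(
    list(id = pid, seq = seq, length = nchar(seq), composition = comp,
         labeled = labeled),
    class = "transfer_product"
  )
}

#' @export
print.transfer_product <- function(x, ...) {
  cat(sprintf("<transfer_product> %s: %d nt%s\n", x$id, x$length,
              if (x$labeled) " (labeled)" else ""))
  invisible(x)
}

#' Render labeled species as a virtual gel
#'
#' Emulates the denaturing-PAGE readout of strand-transfer assays: only
#' 5'-labeled species appear, sorted by descending length. When competition
#' fractions are supplied, integration-product band intensities are the
#' predicted fractions.
#'
#' @param products List of `transfer_product` and/or `cleavage_event`
#'   objects.
#' @param substrates Optional list of `transposon_end` substrates to show as
#'   unreacted bands.
#' @param fractions Optional named numeric vector (by product id or by the
#'   target id after the colon) of predicted integration fractions.
#' @return A tibble (class `virtual_gel`) with `id`, `species`, `length`,
#'   `composition` and `intensity`, longest band first.
#' @export
virtual_gel <- function(products, substrates = list(), fractions = NULL) {
  rows <- list()
  for (s in substrates) {
    if (!isTRUE(s$label_5prime)) next
    rows[[length(rows) + 1L]] <- tibble(
      id = paste0("substrate:", s$role), species = "substrate",
      length = nchar(s$seq), composition = s$role
    )
  }
  for (p in products) {
    if (inherits(p, "cleavage_event")) {
      if (!isTRUE(p$labeled_5prime) || p$upstream_len == 0L) next
      rows[[length(rows) + 1L]] <- tibble(
        id = paste0("cleaved:", p$substrate_id), species = "cleavage_product",
        length = p$upstream_len,
        composition = sprintf("%s[1..%d]", p$substrate_id, p$upstream_len)
      )
    } else if (inherits(p, "transfer_product")) {
      if (!isTRUE(p$labeled)) next
      rows[[length(rows) + 1L]] <- tibble(
        id = p$id, species = "integration_product", length = p$length,
        composition = paste(sprintf("%s[%d..%d]", p$composition$source_id,
                                    p$composition$start, p$composition$end),
                            collapse = "+")
      )
    }
  }
  if (!length(rows)) {
    out <- tibble(id = character(), species = character(), length = integer(),
                  composition = character(), intensity = numeric())
    class(out) <- c("virtual_gel", class(out))
    return(out)
  }
  out <- arrange(bind_rows(rows), dplyr::desc(.data$length))
  out$intensity <- NA_real_
  if (!is.null(fractions)) {
    for (r in which(out$species == "integration_product")) {
      key <- sub("^[^:]*:", "", out$id[r])
      if (key %in% names(fractions)) out$intensity[r] <- fractions[[key]]
      else if (out$id[r] %in% names(fractions)) out$intensity[r] <- fractions[[out$id[r]]]
    }
  }
  class(out) <- c("virtual_gel", class(out))
  out
}
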