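#' Run configuration
#'
#' Bundles every tunable of the toolkit with validated defaults. The
#' competition calibration constraints are re-checked on load, so an invalid
#' user configuration fails at startup naming the offending field.
#'
#' @param ct Target motif (4-mer, default TTAC).
#' @param ext_len Default extension length.
#' @param linker_len Default linker length.
#' @param plus1_weights Named weights for the +1 base, see [plus1_weight()].
#' @param coop [coop_params()] competition calibration.
#' @param fold [fold_params()] folding model.
#' @param seed Integer seed used by every generator.
#' @param accessibility_threshold Required unpaired fraction of the extension
#'   window (default 0.9).
#' @return A validated `run_config` list.
#' @export
run_config <- function(ct = "TTAC", ext_len = 8L, linker_len = 3L,
                       plus1_weights = plus1_defaults(),
                       coop = coop_params(), fold = fold_params(),
                       seed = 1L, accessibility_threshold = 0.9) {
  fail <- function(field, msg) {
    abort(sprintf("invalid config field `%s`: %s", field, msg),
          class = "peelpaste_config_error")
  }
  ct <- tryCatch(check_dna(ct, allow_n = FALSE), error = function(e) fail("ct", conditionMessage(e)))
  if (nchar(ct) != 4L) fail("ct", "must be a 4-mer")
  ext_len <- as.integer(ext_len)
  if (is.na(ext_len) || ext_len < 5L || ext_len > 13L) fail("ext_len", "must be 5-13")
  linker_len <- as.integer(linker_len)
  if (is.na(linker_len) || linker_len < 2L || linker_len > 5L) fail("linker_len", "must be 2-5")
  if (!all(DNA_BASES %in% names(plus1_weights))) fail("plus1_weights", "must name A, C, G, T")
  if (any(plus1_weights <= 0) || any(plus1_weights > 1)) fail("plus1_weights", "must lie in (0, 1]")
  if (!inherits(coop, "coop_params")) {
    coop <- tryCatch(do.call(coop_params, as.list(coop)),
                     error = function(e) fail("coop", conditionMessage(e)))
  } else {
    tryCatch(validate_coop_params(coop), error = function(e) fail("coop", conditionMessage(e)))
  }
  if (!inherits(fold, "fold_params")) {
    fold <- tryCatch(do.call(fold_params, as.list(fold)),
                     error = function(e) fail("fold", conditionMessage(e)))
  }
  seed <- as.integer(seed)
  if (is.na(seed)) fail("seed", "must be an integer")
  if (!is.numeric(accessibility_threshold) || accessibility_threshold <= 0 ||
      accessibility_threshold > 1) {
    fail("accessibility_threshold", "must lie in (0, 1]")
  }
  structure(
    list(ct = ct, ext_len = ext_len, linker_len = linker_len,
         plus1_weights = plus1_weights, coop = coop, fold = fold,
         seed = seed, accessibility_threshold = accessibility_threshold),
    class = "run_config"
  )
}

#' Read a run configuration from a key/value file
#'
#' Accepts a minimal YAML-like `key: value` contract (scalars only, `#`
#' comments; nested coop/fold fields as `coop.K: 7` etc.) and validates the
#' result through [run_config()].
#'
#' @param path Path to the configuration file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, ":", fixed = TRUE)
  args <- list()
  coop_args <- list(); fold_args <- list()
  for (p in kv) {
    if (length(p) < 2L) next
    key <- trimws(p[1]); val <- trimws(paste(p[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    val <- if (!is.na(num)) num else val
    if (startsWith(key, "coop.")) coop_args[[sub("^coop\\.", "", key)]] <- val
    else if (startsWith(key, "fold.")) fold_args[[sub("^fold\\.", "", key)]] <- val
    else args[[key]] <- val
  }
  if (length(coop_args)) {
    args$coop <- do.call(coop_params, utils::modifyList(
      list(floor = 1, amp = 60, K = 6.8, h = 12), coop_args))
  }
  if (length(fold_args)) {
    base <- fold_params()
    if (!is.null(fold_args$min_loop)) base$min_loop <- as.integer(fold_args$min_loop)
    if (!is.null(fold_args$min_helix)) base$min_helix <- as.integer(fold_args$min_helix)
    if (!is.null(fold_args$allow_GT)) base$allow_GT <- as.logical(fold_args$allow_GT)
    args$fold <- do.call(fold_params, base[c("pair_weights", "min_loop",
                                             "allow_GT", "min_helix")])
  }
  do.call(run_config, args)
}
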