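#' Construct a pore model
#'
#' A pore model maps every k-mer over \{A,C,G,T\} to the expected current
#' level observed while that k-mer dwells in the pore.  It is the dictionary
#' used to synthesize a signal-space reference from a base sequence.
#'
#' @param levels Named numeric vector: names are k-mers, values are expected
#'   levels (model units).
#' @param stdvs Optional named numeric vector of per-k-mer level spreads.
#' @return An object of class `pore_model` with fields `k`, `levels`,
#'   `stdvs` and `complete` (TRUE when all 4^k k-mers are present).
#' @export
pore_model <- function(levels, stdvs = NULL) {
  kmers <- names(levels)
  if (is.null(kmers) || any(!nzchar(kmers))) {
    sqm_stop("`levels` must be a named vector of k-mer levels",
             "sqm_format_error")
  }
  k <- nchar(kmers[1])
  if (any(nchar(kmers) != k)) {
    sqm_stop("inconsistent k-mer lengths in pore model", "sqm_format_error")
  }
  if (any(grepl("[^ACGT]", kmers))) {
    sqm_stop("pore model k-mers must be over {A,C,G,T}", "sqm_format_error")
  }
  if (anyDuplicated(kmers)) {
    sqm_stop("duplicate k-mers in pore model", "sqm_format_error")
  }
  if (!all(is.finite(levels))) {
    sqm_stop("pore model levels must be finite", "sqm_format_error")
  }
  if (!is.null(stdvs)) {
    stdvs <- stdvs[kmers]
  }
  structure(list(k = as.integer(k),
                 levels = levels,
                 stdvs = stdvs,
                 complete = length(levels) == 4L^k),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("<pore_model> k = %d, %d k-mers (%s), level range [%.2f, %.2f]\n",
              x$k, length(x$levels), if (x$complete) "complete" else "partial",
              min(x$levels), max(x$levels)))
  invisible(x)
}

#' Load a k-mer pore model from a TSV table
#'
#' The expected format follows community k-mer model tables: tab-separated
#' rows `kmer<TAB>level_mean[<TAB>level_stdv ...]`, with an optional header
#' line whose first field is `kmer`.  Columns beyond `level_stdv` are
#' ignored.
#'
#' @param path Path to the TSV file.
#' @return A [pore_model()].
#' @export
load_pore_model <- function(path) {
  if (!file.exists(path)) {
    sqm_stop(paste0("pore model file not found: ", path), "sqm_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    sqm_stop(paste0("empty pore model file: ", path), "sqm_format_error")
  }
  if (grepl("^#?kmer\\b", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) {
    sqm_stop(paste0("pore model file has no data rows: ", path),
             "sqm_format_error")
  }
  fields <- strsplit(lines, "[\t ]+")
  ncol_min <- min(lengths(fields))
  if (ncol_min < 2) {
    sqm_stop("pore model rows need at least `kmer` and `level_mean` columns",
             "sqm_format_error")
  }
  kmers <- toupper(vapply(fields, `[[`, "", 1L))
  means <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (any(is.na(means))) {
    sqm_stop("non-numeric level_mean in pore model", "sqm_format_error")
  }
  stdvs <- NULL
  if (ncol_min >= 3) {
    sv <- suppressWarnings(as.numeric(vapply(fields, function(f)
      if (length(f) >= 3) f[[3]] else NA_character_, "")))
    if (!any(is.na(sv))) stdvs <- stats::setNames(sv, kmers)
  }
  pore_model(stats::setNames(means, kmers), stdvs = stdvs)
}

#' Write a pore model as a TSV table
#'
#' @param model A [pore_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pore_model <- function(model, path) {
  header <- if (is.null(model$stdvs)) "kmer\tlevel_mean"
            else "kmer\tlevel_mean\tlevel_stdv"
  rows <- if (is.null(model$stdvs)) {
    sprintf("%s\t%.17g", names(model$levels), model$levels)
  } else {
    sprintf("%s\t%.17g\t%.17g", names(model$levels), model$levels,
            model$stdvs)
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Reverse-complement a DNA sequence
#'
#' Needed because DNA is double-stranded: a read may come from either
#' strand, so the reference is indexed in both orientations.
#'
#' @param seq A single character string over \{A,C,G,T,N\}
#'   (case-insensitive).
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("AACG")  # "CGTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) {
    sqm_stop("sequence contains characters outside {A,C,G,T,N}",
             "sqm_alphabet_error")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Convert a base sequence to its expected signal
#'
#' Slides a window of k bases over the sequence; each window is looked up in
#' the pore model, producing the synthetic squiggle a perfect pore would
#' emit.  Output length is `nchar(seq) - k + 1`.
#'
#' @param seq A single base string over \{A,C,G,T\}.
#' @param model A [pore_model()].
#' @return Numeric vector of expected levels, one per k-mer window.
#' @export
sequence_to_signal <- function(seq, model) {
  stopifnot(inherits(model, "pore_model"))
  s <- toupper(seq)
  k <- model$k
  n <- nchar(s)
  if (n < k) {
    sqm_stop("sequence shorter than the model k-mer length", "sqm_size_error")
  }
  if (grepl("[^ACGT]", s)) {
    sqm_stop("sequence contains non-ACGT characters; ambiguity codes are not indexed",
             "sqm_alphabet_error")
  }
  kmers <- substring(s, 1:(n - k + 1), k:n)
  idx <- match(kmers, names(model$levels))
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    sqm_stop(sprintf("k-mer '%s' at position %d not present in the pore model",
                     kmers[miss], miss), "sqm_lookup_error")
  }
  unname(model$levels[idx])
}

#' Z-score normalize a signal
#'
#' Centers to mean zero and scales to unit *population* standard deviation
#' (divide by n).  Both reference and query signals go through the same
#' normalization so they live on a comparable scale.
#'
#' @param x Numeric vector of length >= 2 with positive variance.
#' @return Normalized numeric vector, with attributes `mean` and `sd`
#'   recording the statistics that were removed.
#' @export
znormalize <- function(x) {
  if (length(x) < 2) {
    sqm_stop("need at least 2 samples to z-normalize", "sqm_size_error")
  }
  if (!all(is.finite(x))) {
    sqm_stop("signal must be finite", "sqm_domain_error")
  }
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) {
    sqm_stop("degenerate signal: zero variance, cannot z-normalize",
             "sqm_degenerate_error")
  }
  structure((x - m) / s, mean = m, sd = s)
}

#' Build a two-strand signal-space reference index
#'
#' Forms the synthetic reference signal for the forward and
#' reverse-complement representation of the base reference via the pore
#' model, z-normalizes each strand independently, and quantizes it with the
#' fixed-point configuration.  This is the initialization step performed
#' once per target before any read is mapped.
#'
#' @param seq Base sequence (single string over \{A,C,G,T\}).
#' @param model A [pore_model()].
#' @param fp A [fp_config()].
#' @param name Reference identifier carried into mapping output.
#' @return An object of class `reference_index` with fields `name`,
#'   `base_length`, `k`, `fp` and `strands`, the latter a list with entries
#'   `"+"` and `"-"`, each holding `float_signal`, `quant_signal`,
#'   `norm_mean`, `norm_sd` and `n_clamped`.
#' @export
build_reference_index <- function(seq, model, fp = fp_config(),
                                  name = "ref") {
  stopifnot(inherits(model, "pore_model"), inherits(fp, "fp_config"))
  seq <- toupper(seq)
  strand_signal <- function(s) {
    raw <- sequence_to_signal(s, model)
    z <- znormalize(raw)
    q <- quantize(as.numeric(z), fp)
    list(float_signal = as.numeric(z),
         quant_signal = as.integer(q),
         norm_mean = attr(z, "mean"),
         norm_sd = attr(z, "sd"),
         n_clamped = attr(q, "n_clamped"))
  }
  fwd <- strand_signal(seq)
  rev <- strand_signal(reverse_complement(seq))
  structure(list(name = name,
                 base_length = nchar(seq),
                 k = model$k,
                 fp = fp,
                 strands = list("+" = fwd, "-" = rev)),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("<reference_index> '%s': %d bases, k = %d, %d signal positions/strand\n",
              x$name, x$base_length, x$k,
              length(x$strands[["+"]]$float_signal)))
  cat(sprintf("  fixed point: %d-bit, scale %d, overflow '%s'\n",
              x$fp$bits, x$fp$scale, x$fp$overflow))
  invisible(x)
}

#' Read reference sequences from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    sqm_stop(paste0("FASTA file not found: ", path), "sqm_io_error")
  }
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

# --- index serialization -----------------------------------------------------
# Single binary container, little-endian, versioned.  Layout:
#   magic "SQGIDX" (6 bytes) | version int32 | name (int32 length + UTF-8)
#   | base_length int32 | k int32 | bits int32 | scale int32
#   | overflow int32 (0 = wraparound, 1 = saturate)
#   then per strand (+ then -):
#   norm_mean double | norm_sd double | n_clamped int32
#   | n int32 | float_signal double[n] | quant_signal int32[n]

#' Serialize a reference index to disk
#'
#' Writes a versioned little-endian binary container that round-trips
#' bit-exactly through [read_reference_index()].
#'
#' @param idx A [build_reference_index()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_index <- function(idx, path) {
  stopifnot(inherits(idx, "reference_index"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SQGIDX"), con)
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wd <- function(v) writeBin(as.numeric(v), con, size = 8, endian = "little")
  wi(1L)  # format version
  nm <- charToRaw(enc2utf8(idx$name))
  wi(length(nm)); writeBin(nm, con)
  wi(idx$base_length); wi(idx$k)
  wi(idx$fp$bits); wi(idx$fp$scale)
  wi(if (idx$fp$overflow == "wraparound") 0L else 1L)
  for (st in c("+", "-")) {
    s <- idx$strands[[st]]
    wd(s$norm_mean); wd(s$norm_sd); wi(s$n_clamped)
    wi(length(s$float_signal))
    wd(s$float_signal); wi(s$quant_signal)
  }
  invisible(path)
}

#' Read a serialized reference index
#'
#' @param path Path written by [write_reference_index()].
#' @return A `reference_index`.
#' @export
read_reference_index <- function(path) {
  if (!file.exists(path)) {
    sqm_stop(paste0("index file not found: ", path), "sqm_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n = 1) readBin(con, "integer", n, size = 4, endian = "little")
  rd <- function(n = 1) readBin(con, "numeric", n, size = 8, endian = "little")
  magic <- rawToChar(readBin(con, "raw", 6))
  if (!identical(magic, "SQGIDX")) {
    sqm_stop("not a squigglemap index file (bad magic)", "sqm_format_error")
  }
  version <- ri()
  if (version != 1L) {
    sqm_stop(sprintf("unsupported index version %d", version),
             "sqm_format_error")
  }
  name <- rawToChar(readBin(con, "raw", ri()))
  base_length <- ri(); k <- ri()
  bits <- ri(); scale <- ri()
  overflow <- if (ri() == 0L) "wraparound" else "saturate"
  strands <- list()
  for (st in c("+", "-")) {
    norm_mean <- rd(); norm_sd <- rd(); n_clamped <- ri()
    n <- ri()
    strands[[st]] <- list(float_signal = rd(n),
                          quant_signal = ri(n),
                          norm_mean = norm_mean,
                          norm_sd = norm_sd,
                          n_clamped = n_clamped)
  }
  structure(list(name = name, base_length = base_length, k = k,
                 fp = fp_config(bits = bits, scale = scale,
                                overflow = overflow),
                 strands = strands),
            class = "reference_index")
}
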