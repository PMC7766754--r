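#' Pore models: expected current level per 6-mer
#'
#' A pore model maps each 6-base window occupying the nanopore to the
#' expected ionic current level (pA) measured while that 6-mer sits in
#' the pore. A complete model over the DNA alphabet has 4^6 = 4096
#' entries. [read_pore_model()] parses ONT-style tab-separated k-mer
#' tables; [expected_signal()] converts a nucleotide sequence into the
#' ordered levels of its overlapping 6-mer windows.
#'
#' @param levels named numeric vector, names are 6-mers over A/C/G/T and
#'   values are expected current levels in pA.
#' @return `pore_model()` returns an object of class `"pore_model"`: a
#'   named numeric vector with the k-mer length in attribute `k`.
#' @examples
#' pm <- pore_model(c(AAAAAA = 80.5, AAAAAC = 83.1))
#' expected_signal("AAAAAAC", pm)
#' @export
pore_model <- function(levels) {
  if (length(levels) && (is.null(names(levels)) || any(names(levels) == "")))
    stop_input("pore model levels must be named by their 6-mers")
  nm <- names(levels)
  bad_len <- nchar(nm) != 6L
  if (any(bad_len))
    stop_input("invalid k-mer length (expected 6): ", nm[bad_len][1L])
  bad_alpha <- grepl("[^ACGT]", nm)
  if (any(bad_alpha))
    stop_input("invalid k-mer alphabet (expected A/C/G/T): ", nm[bad_alpha][1L])
  if (anyDuplicated(nm))
    stop_input("duplicate k-mer in pore model: ", nm[duplicated(nm)][1L])
  if (length(levels) && any(!is.finite(levels)))
    stop_input("pore model levels must be finite")
  structure(as.numeric(stats::setNames(as.numeric(levels), nm)),
            names = nm, k = 6L, class = "pore_model")
}

#' @rdname pore_model
#' @param path path to a tab-separated k-mer table. Each non-comment line
#'   is `KMER<TAB>level` with optional further columns (e.g. a level
#'   standard deviation) that are ignored. A header line whose first
#'   field is not a valid 6-mer (e.g. `kmer<TAB>level_mean`) is skipped.
#' @export
read_pore_model <- function(path) {
  if (!file.exists(path)) stop_input("pore model file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(pore_model(stats::setNames(numeric(0), character(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate a single header line ("kmer<TAB>level_mean" and variants)
  if (grepl("^(kmer|k-mer|KMER)$", fields[[1L]][1L])) {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
  }
  if (!length(fields)) return(pore_model(stats::setNames(numeric(0), character(0))))
  nfield <- lengths(fields)
  if (any(nfield < 2L))
    stop_input("malformed pore model line ", lineno[which(nfield < 2L)[1L]],
               ": expected at least two tab-separated fields")
  kmers <- vapply(fields, `[`, character(1L), 1L)
  vals <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1L), 2L)))
  if (any(is.na(vals)))
    stop_input("malformed pore model line ", lineno[which(is.na(vals))[1L]],
               ": level is not numeric")
  pore_model(stats::setNames(vals, kmers))
}

#' @rdname pore_model
#' @param model a `"pore_model"` object.
#' @export
write_pore_model <- function(model, path) {
  stopifnot(inherits(model, "pore_model"))
  writeLines(c("# 6-mer pore model: kmer<TAB>level_mean_pA",
               sprintf("%s\t%.6g", names(model), as.numeric(model))), path)
  invisible(path)
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("6-mer pore model: %d entries", length(x)))
  if (length(x))
    cat(sprintf(", levels %.1f-%.1f pA", min(x), max(x)))
  cat("\n")
  invisible(x)
}

#' @rdname pore_model
#' @param sequence a nucleotide string over A/C/G/T of length >= 6.
#' @return `expected_signal()` returns an object of class
#'   `"expected_signal"`: the numeric vector of per-window levels (length
#'   `nchar(sequence) - 5`) with the source length in attribute
#'   `source_length`.
#' @export
expected_signal <- function(sequence, model) {
  stopifnot(inherits(model, "pore_model"))
  if (!is.character(sequence) || length(sequence) != 1L)
    stop_input("sequence must be a single character string")
  n <- nchar(sequence)
  if (n < 6L) stop_input("sequence shorter than 6 bases")
  if (grepl("[^ACGT]", sequence)) {
    bad <- regmatches(sequence, regexpr("[^ACGT]", sequence))
    stop_input("invalid character '", bad, "' in sequence ",
               "(only A/C/G/T are supported; ambiguity codes are rejected)")
  }
  windows <- substring(sequence, 1:(n - 5L), 6:n)
  idx <- match(windows, names(model))
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1L]
    stop_input("6-mer '", windows[p], "' at position ", p,
               " is absent from the pore model")
  }
  structure(as.numeric(model[idx]), source_length = n,
            class = "expected_signal")
}

#' @export
print.expected_signal <- function(x, ...) {
  cat(sprintf("expected signal: %d levels from a %d-base sequence\n",
              length(x), attr(x, "source_length")))
  invisible(x)
}
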