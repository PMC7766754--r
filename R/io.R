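#' Read and write the pipeline's file formats
#'
#' FASTA for sequences (via Biostrings when available, with a base-R
#' fallback parser for minimal installs), one-value-per-line TSV for
#' signals, and two-column TSV for training pairs.
#'
#' @param path file path.
#' @return `read_fasta()` returns a list of `list(id, sequence)` in file
#'   order, sequences uppercased.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  if (!startsWith(lines[[1L]], ">"))
    stop_input("malformed FASTA: sequence line before the first header")
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    return(unname(Map(function(id, s) list(id = id, sequence = toupper(s)),
                      ids, as.character(ss))))
  }
  starts <- which(startsWith(lines, ">"))
  ends <- c(starts[-1L] - 1L, length(lines))
  unname(Map(function(s, e) {
    body <- if (e > s) lines[(s + 1L):e] else character(0)
    list(id = sub("\\s.*$", "", sub("^>", "", lines[s])),
         sequence = toupper(paste(body, collapse = "")))
  }, starts, ends))
}

#' @rdname read_fasta
#' @param records named character vector of sequences, or a list as
#'   returned by `read_fasta()`.
#' @export
write_fasta <- function(records, path) {
  if (is.list(records) && length(records) && is.list(records[[1L]]))
    records <- setNames(vapply(records, `[[`, character(1L), "sequence"),
                        vapply(records, `[[`, character(1L), "id"))
  writeLines(as.vector(rbind(paste0(">", names(records)),
                             unname(records))), path)
  invisible(path)
}

#' @rdname read_fasta
#' @param read_id identifier stored in the file header.
#' @param signal numeric signal to store.
#' @param metadata named list written as `# key=value` header comments.
#' @param format only `"tsv"` is supported: one float per line with
#'   comment headers. (fast5-style HDF5 output is not provided.)
#' @export
write_signal <- function(path, read_id, signal, metadata = list(),
                         format = "tsv") {
  if (!identical(format, "tsv"))
    stop_input("unsupported signal format '", format, "' (only \"tsv\")")
  signal <- as.numeric(signal)
  check_numeric_vector(signal, "signal")
  hdr <- c(sprintf("# read_id=%s", read_id),
           vapply(names(metadata), function(k)
             sprintf("# %s=%s", k, format(metadata[[k]])), character(1L)))
  writeLines(c(hdr, sprintf("%.8g", signal)), path)
  invisible(path)
}

#' @rdname read_fasta
#' @return `read_signal()` returns the numeric signal with attributes
#'   `read_id` and `metadata`.
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stop_input("signal file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
  }
  vals <- as.numeric(lines[!hdr & nzchar(lines)])
  if (any(is.na(vals))) stop_input("non-numeric signal value in ", path)
  structure(vals, read_id = meta[["read_id"]],
            metadata = meta[setdiff(names(meta), "read_id")])
}

#' @rdname read_fasta
#' @param pair a [training_pair()].
#' @export
write_pair <- function(pair, path) {
  stopifnot(inherits(pair, "training_pair"))
  writeLines(c("# squigglesim training pair: input<TAB>target",
               sprintf("# tag=%s", pair$tag),
               sprintf("%.8g\t%.8g", pair$I, pair$R)), path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_pair <- function(path) {
  if (!file.exists(path)) stop_input("pair file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  tagline <- grep("^# tag=", lines, value = TRUE)
  tag <- if (length(tagline)) sub("^# tag=", "", tagline[[1L]]) else ""
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  I <- as.numeric(vapply(parts, `[`, character(1L), 1L))
  R <- as.numeric(vapply(parts, `[`, character(1L), 2L))
  training_pair(I, R, tag = tag)
}

#' Simulation configuration
#'
#' Bundles the knobs of a simulation run; [read_sim_config()] loads the
#' same structure from a YAML file (flags given on the command line
#' override it).
#'
#' @param pore_model_path path to the pore-model TSV (`NULL` to use the
#'   synthetic model).
#' @param filter_mode `"bigru"`, `"lowpass"`, or `"none"`.
#' @param model_checkpoint_path BiGRU checkpoint (required for
#'   `filter_mode = "bigru"`).
#' @param cutoff_hz low-pass cutoff in Hz (default 950).
#' @param noise_std Gaussian noise standard deviation in pA (default 2).
#' @param sample_rate_hz sampling rate in Hz (default 4000).
#' @param seed integer seed.
#' @param output_format `"tsv"`.
#' @return an object of class `"sim_config"`.
#' @export
simulation_config <- function(pore_model_path = NULL,
                              filter_mode = c("bigru", "lowpass", "none"),
                              model_checkpoint_path = NULL,
                              cutoff_hz = 950, noise_std = 2.0,
                              sample_rate_hz = 4000, seed = 1L,
                              output_format = "tsv") {
  filter_mode <- match.arg(filter_mode)
  if (filter_mode == "bigru" && is.null(model_checkpoint_path))
    stop_input("filter_mode \"bigru\" requires model_checkpoint_path")
  if (noise_std < 0) stop_input("noise_std must be >= 0")
  if (!identical(output_format, "tsv"))
    stop_input("unsupported output format '", output_format, "'")
  structure(list(pore_model_path = pore_model_path,
                 filter_mode = filter_mode,
                 model_checkpoint_path = model_checkpoint_path,
                 cutoff_hz = cutoff_hz, noise_std = noise_std,
                 sample_rate_hz = sample_rate_hz, seed = as.integer(seed),
                 output_format = output_format),
            class = "sim_config")
}

#' @rdname simulation_config
#' @param path YAML file with any subset of the `simulation_config()`
#'   fields.
#' @param ... overrides applied on top of the file.
#' @export
read_sim_config <- function(path, ...) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  over <- list(...)
  y[names(over)] <- over
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop_input("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(simulation_config, y)
}

#' Write a self-contained synthetic fixture directory
#'
#' Materializes a [make_dataset()] run on disk: the FASTA of sequences,
#' the synthetic pore-model TSV, one training-pair TSV per read, and a
#' JSON manifest sufficient to regenerate the dataset bit-identically.
#'
#' @param dir output directory (created if needed).
#' @param ... passed to [make_dataset()].
#' @return the dataset, invisibly.
#' @export
make_fixtures <- function(dir, ...) {
  ds <- make_dataset(...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pairs"), showWarnings = FALSE)
  seqs <- setNames(vapply(ds$reads, `[[`, character(1L), "sequence"),
                   vapply(seq_along(ds$reads), function(i)
                     sprintf("synthetic_read_%03d", i), character(1L)))
  write_fasta(seqs, file.path(dir, "reads.fasta"))
  write_pore_model(synthetic_pore_model(ds$manifest$pore_model_seed),
                   file.path(dir, "pore_model.tsv"))
  for (i in seq_along(ds$pairs))
    write_pair(ds$pairs[[i]],
               file.path(dir, "pairs", sprintf("pair_%03d.tsv", i)))
  jsonlite::write_json(ds$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ds)
}
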