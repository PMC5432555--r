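# polynomial rolling hash (mod 2^31 - 1) of a deparsed object; cheap
# provenance fingerprint
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write / read recordings as delimited text with a metadata sidecar
#'
#' The data file holds the channels x samples matrix, tab-delimited, one
#' channel per row.  The sidecar (`<path>.meta`) holds `key=value` lines:
#' sampling rate, channel labels, reference tag, seed and a config hash.
#'
#' @param recording an [eeg_recording()].
#' @param path data file path; the sidecar is written next to it.
#' @param layout an [electrode_layout()] to attach on read (labels must
#'   match the sidecar).
#' @return `read_recording` returns an [eeg_recording()]; `write_recording`
#'   returns `path` invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  utils::write.table(recording$data, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  seed <- recording$provenance$seed
  meta <- c(sprintf("fs=%.10g", recording$fs),
            sprintf("labels=%s", paste(recording$layout$names, collapse = ",")),
            sprintf("reference=%s", recording$reference),
            sprintf("seed=%s", if (is.null(seed)) "NA" else seed),
            sprintf("config_hash=%s", config_hash(recording$provenance$config)))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, layout) {
  data <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                      colClasses = "numeric"))
  dimnames(data) <- NULL
  meta_lines <- readLines(paste0(path, ".meta"))
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  labels <- strsplit(meta[["labels"]], ",", fixed = TRUE)[[1]]
  if (!identical(labels, layout$names))
    stop("sidecar labels do not match the supplied layout")
  eeg_recording(data, fs = as.numeric(meta[["fs"]]), layout = layout,
                reference = meta[["reference"]],
                provenance = list(seed = meta[["seed"]],
                                  config_hash = meta[["config_hash"]]))
}

#' Write / read reference transforms as delimited matrices
#'
#' Header lines (prefixed `#`) carry the scheme and provenance hashes;
#' the matrix follows, tab-delimited.
#'
#' @param transform a [ref_transform()].
#' @param path file path.
#' @return `read_transform` returns a [ref_transform()]; `write_transform`
#'   returns `path` invisibly.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "ref_transform"))
  hdr <- c(sprintf("# scheme=%s", transform$scheme),
           sprintf("# provenance_hash=%s", config_hash(transform$provenance)))
  writeLines(hdr, path)
  utils::write.table(transform$matrix, path, sep = "\t", append = TRUE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s=", key), "", grep(key, hdr, value = TRUE)[1])
  m <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t"))
  dimnames(m) <- NULL
  ref_transform(m, scheme = get("scheme"),
                provenance = list(provenance_hash = get("provenance_hash")))
}
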