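#' Read a multichannel epoched dataset from text files
#'
#' Two plain-text layouts are supported:
#' \describe{
#'   \item{`"matrix"`}{`<path>.tsv`, a numeric matrix with one row per
#'     channel-epoch (channel-major order), plus a JSON header
#'     `<path>.json` with fields `fs`, `n_channels`, `n_epochs`,
#'     `n_samples` and optional `channel_labels`.}
#'   \item{`"long"`}{a single TSV with columns `channel`, `epoch`, `sample`,
#'     `value` and a comment header line `# fs=<Hz>`.}
#' }
#'
#' @param path file path; for `"matrix"` the `.tsv`/`.json` pair shares this
#'   stem (with or without the `.tsv` extension).
#' @param format `"matrix"` or `"long"`.
#' @return an object of class `dataset`: list with `data` (3-D array
#'   channel x epoch x sample), `fs`, `channels` (labels).
#' @export
read_dataset <- function(path, format = c("matrix", "long")) {
  format <- match.arg(format)
  if (format == "matrix") {
    stem <- sub("\\.tsv$", "", path)
    tsv <- paste0(stem, ".tsv"); hdr <- paste0(stem, ".json")
    if (!file.exists(hdr)) stop("missing JSON header: ", hdr)
    h <- jsonlite::read_json(hdr, simplifyVector = TRUE)
    for (fld in c("fs", "n_channels", "n_epochs", "n_samples"))
      if (is.null(h[[fld]])) stop("header field missing: ", fld)
    m <- as.matrix(utils::read.table(tsv, sep = "\t", header = FALSE,
                                     colClasses = "numeric"))
    if (nrow(m) != h$n_channels * h$n_epochs || ncol(m) != h$n_samples)
      stop(sprintf("matrix shape %dx%d does not match header (%d channels x %d epochs, %d samples)",
                   nrow(m), ncol(m), h$n_channels, h$n_epochs, h$n_samples))
    arr <- array(NA_real_, c(h$n_channels, h$n_epochs, h$n_samples))
    for (ch in seq_len(h$n_channels))
      arr[ch, , ] <- m[(ch - 1) * h$n_epochs + seq_len(h$n_epochs), ,
                       drop = FALSE]
    labels <- h$channel_labels %||% paste0("ch", seq_len(h$n_channels))
  } else {
    first <- readLines(path, n = 1L)
    fs_match <- regmatches(first, regexec("^#\\s*fs=([0-9.eE+-]+)", first))[[1]]
    if (length(fs_match) < 2L) stop("long TSV must start with a '# fs=<Hz>' line")
    fs <- as.numeric(fs_match[2])
    d <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
    need <- c("channel", "epoch", "sample", "value")
    if (!all(need %in% names(d)))
      stop("long TSV needs columns: ", paste(need, collapse = ", "))
    chs <- sort(unique(d$channel)); eps <- sort(unique(d$epoch))
    smp <- sort(unique(d$sample))
    arr <- array(NA_real_, c(length(chs), length(eps), length(smp)))
    arr[cbind(match(d$channel, chs), match(d$epoch, eps),
              match(d$sample, smp))] <- d$value
    if (any(is.na(arr))) stop("long TSV is not a complete channel x epoch x sample grid")
    labels <- as.character(chs)
    h <- list(fs = fs)
  }
  structure(list(data = arr, fs = h$fs, channels = labels), class = "dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset in the matrix-plus-JSON-header layout
#'
#' @param dataset a `dataset` (see [read_dataset()]), or a [segment_set()]
#'   (written as one channel).
#' @param path output stem; writes `<path>.tsv` and `<path>.json`.
#' @return invisibly, the `.tsv` path.
#' @export
write_dataset <- function(dataset, path) {
  if (inherits(dataset, "segment_set")) {
    arr <- array(NA_real_,
                 c(1L, length(dataset$segments), length(dataset$segments[[1]])))
    for (i in seq_along(dataset$segments)) arr[1, i, ] <- dataset$segments[[i]]
    dataset <- structure(list(data = arr, fs = dataset$fs, channels = "ch1"),
                         class = "dataset")
  }
  stopifnot(inherits(dataset, "dataset"))
  stem <- sub("\\.tsv$", "", path)
  d <- dim(dataset$data)
  m <- matrix(aperm(dataset$data, c(3, 2, 1)), ncol = d[3], byrow = TRUE)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     paste0(stem, ".tsv"), sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = dataset$fs, n_channels = d[1],
                            n_epochs = d[2], n_samples = d[3],
                            channel_labels = dataset$channels),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(stem, ".tsv"))
}

#' Extract one channel of a dataset as a segment set
#'
#' @param dataset a `dataset`.
#' @param channel channel index or label.
#' @return a [segment_set()] of the channel's epochs.
#' @export
dataset_channel <- function(dataset, channel = 1L) {
  stopifnot(inherits(dataset, "dataset"))
  if (is.character(channel)) channel <- match(channel, dataset$channels)
  if (is.na(channel) || channel < 1L || channel > dim(dataset$data)[1])
    stop("unknown channel")
  segment_set(dataset$data[channel, , , drop = TRUE], dataset$fs)
}
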