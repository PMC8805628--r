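# Plain-text (TSV) serialization for the package's containers. Each file
# starts with '#key=value' header lines followed by a tab-separated numeric
# matrix, so the files are diffable and language-agnostic.

write_header_matrix <- function(mat, headers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(headers)) {
    writeLines(sprintf("#%s=%s", k, headers[[k]]), con)
  }
  utils::write.table(mat, con, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_header_matrix <- function(path) {
  lines <- readLines(path, n = 64L)
  hdr_n <- sum(startsWith(lines, "#"))
  hdr <- lines[seq_len(hdr_n)]
  kv <- regmatches(hdr, regexec("^#([^=]+)=(.*)$", hdr))
  headers <- stats::setNames(
    lapply(kv, function(m) m[3]),
    vapply(kv, function(m) m[2], character(1))
  )
  mat <- as.matrix(utils::read.table(path, skip = hdr_n, sep = "\t"))
  dimnames(mat) <- NULL
  list(headers = headers, mat = mat)
}

#' Read and write feature sets as TSV
#'
#' A feature set is stored as `#key=value` header lines (`fs`, `tag`,
#' `names`) followed by the predictors x samples matrix, tab-separated.
#'
#' @param x a [feature_set()].
#' @param path file path.
#' @return `read_feature_set()` returns a [feature_set()];
#'   `write_feature_set()` returns `path` invisibly.
#' @export
write_feature_set <- function(x, path) {
  stopifnot(inherits(x, "feature_set"))
  write_header_matrix(x$data, list(
    fs = x$fs, tag = x$tag, names = paste(x$names, collapse = ",")
  ), path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  p <- read_header_matrix(path)
  feature_set(p$mat, fs = as.numeric(p$headers$fs), tag = p$headers$tag,
    names = strsplit(p$headers$names, ",")[[1]])
}

#' Read and write EEG recordings as TSV
#'
#' Channels x samples matrix preceded by `#key=value` headers (`fs`,
#' `labels`, optional `positions` as `x;y;z` triples and `mastoids`).
#'
#' @param x an [eeg_recording()].
#' @param path file path.
#' @return `read_eeg()` returns an [eeg_recording()].
#' @export
write_eeg <- function(x, path) {
  stopifnot(inherits(x, "eeg_recording"))
  hdr <- list(fs = x$fs, labels = paste(x$labels, collapse = ","))
  if (!is.null(x$positions)) {
    hdr$positions <- paste(apply(x$positions, 1L, paste, collapse = ";"),
      collapse = ",")
  }
  if (!is.null(x$mastoids)) hdr$mastoids <- paste(x$mastoids, collapse = ",")
  write_header_matrix(x$data, hdr, path)
}

#' @rdname write_eeg
#' @export
read_eeg <- function(path) {
  p <- read_header_matrix(path)
  pos <- NULL
  if (!is.null(p$headers$positions)) {
    pos <- do.call(rbind, lapply(
      strsplit(p$headers$positions, ",")[[1]],
      function(s) as.numeric(strsplit(s, ";")[[1]])
    ))
  }
  mast <- if (is.null(p$headers$mastoids)) NULL else
    as.integer(strsplit(p$headers$mastoids, ",")[[1]])
  eeg_recording(p$mat, fs = as.numeric(p$headers$fs),
    labels = strsplit(p$headers$labels, ",")[[1]],
    positions = pos, mastoids = mast)
}

#' Write a synthetic study to disk
#'
#' Serializes every trial of a study tibble in the same formats the
#' real-data readers consume: per-stream alignments as TSV, feature
#' matrices and EEG as headered TSV, one directory per subject.
#'
#' @param study a study tibble from [make_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(study))) {
    sd <- file.path(dir, sprintf("subject%02d", study$subject[i]))
    dir.create(sd, showWarnings = FALSE)
    base <- sprintf("trial%02d", study$trial[i])
    write_eeg(study$eeg[[i]], file.path(sd, paste0(base, "_eeg.tsv")))
    for (cond in c("att", "unatt")) {
      feats <- study[[paste0("features_", cond)]][[i]]
      for (tag in names(feats)) {
        write_feature_set(feats[[tag]],
          file.path(sd, sprintf("%s_%s_%s.tsv", base, cond, tag)))
      }
    }
  }
  meta <- study[c("subject", "trial", "attended")]
  utils::write.table(meta, file.path(dir, "trials.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Serialize a fitted TRF model
#'
#' Weights are flattened lag-fastest within predictor; the header records
#' lambda, the lag range, sampling rate, tags and dimensions.
#'
#' @param model a `trf_model`.
#' @param path file path.
#' @return `read_trf()` returns a `trf_model`.
#' @export
write_trf <- function(model, path) {
  stopifnot(inherits(model, "trf_model"))
  d <- dim(model$weights)
  write_header_matrix(
    matrix(as.vector(model$weights), nrow = d[1] * d[2]),
    list(
      lambda = model$lambda,
      lag_ms = paste(model$lag_ms, collapse = ","),
      fs = model$fs,
      tags = paste(model$tags, collapse = ","),
      dims = paste(d, collapse = ","),
      predictors = paste(model$predictors, collapse = ","),
      channels = paste(model$channels, collapse = ",")
    ), path)
}

#' @rdname write_trf
#' @export
read_trf <- function(path) {
  p <- read_header_matrix(path)
  d <- as.integer(strsplit(p$headers$dims, ",")[[1]])
  new_trf_model(
    weights = array(as.vector(p$mat), dim = d),
    lambda = as.numeric(p$headers$lambda),
    lag_ms = as.numeric(strsplit(p$headers$lag_ms, ",")[[1]]),
    fs = as.numeric(p$headers$fs),
    tags = strsplit(p$headers$tags, ",")[[1]],
    predictors = strsplit(p$headers$predictors, ",")[[1]],
    channels = strsplit(p$headers$channels, ",")[[1]]
  )
}
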