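#' Phoneme inventory with binary articulatory features
#'
#' Loads a phoneme-to-feature table mapping each phoneme (ARPAbet labels by
#' default) to a binary vector of articulatory/acoustic features (manner,
#' place, voicing and vowel position classes) and to a vowel/consonant class.
#' The shipped default table has 19 features; the table is plain TSV so a
#' different mapping can be substituted.
#'
#' @param path path to a TSV with columns `phoneme`, `class`
#'   (`vowel`/`consonant`) and one 0/1 column per feature. Defaults to the
#'   table shipped with the package.
#'
#' @return A `phoneme_inventory`: a tibble with one row per phoneme, plus a
#'   `features` attribute holding the phonemes x features 0/1 matrix.
#' @examples
#' inv <- phoneme_inventory()
#' n_features(inv)
#' @export
phoneme_inventory <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "phoneme_features.tsv", package = "speechtrf")
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("phoneme", "class") %in% names(tab))) {
    abort_bad_arg("inventory table needs `phoneme` and `class` columns.")
  }
  if (nrow(tab) == 0L) {
    abort_bad_arg("phoneme inventory is empty.",
      class = "speechtrf_error_config")
  }
  if (anyDuplicated(tab$phoneme)) {
    abort_bad_arg("duplicated phoneme labels in inventory.")
  }
  if (!all(tab$class %in% c("vowel", "consonant"))) {
    abort_bad_arg("`class` must be 'vowel' or 'consonant' for every phoneme.")
  }
  featcols <- setdiff(names(tab), c("phoneme", "class"))
  fmat <- as.matrix(tab[, featcols, drop = FALSE])
  storage.mode(fmat) <- "double"
  if (anyNA(fmat) || !all(fmat %in% c(0, 1))) {
    abort_bad_arg("feature columns must be 0/1.")
  }
  if (any(rowSums(fmat) < 1)) {
    bad <- tab$phoneme[rowSums(fmat) < 1]
    abort_bad_arg(sprintf(
      "every phoneme must carry at least one feature (violated by: %s).",
      paste(bad, collapse = ", ")
    ))
  }
  rownames(fmat) <- tab$phoneme
  out <- tibble::as_tibble(tab)
  attr(out, "features") <- fmat
  class(out) <- c("phoneme_inventory", class(out))
  out
}

#' @rdname phoneme_inventory
#' @param inventory a `phoneme_inventory`.
#' @export
n_features <- function(inventory) ncol(attr(inventory, "features"))

#' @rdname phoneme_inventory
#' @export
feature_matrix <- function(inventory) attr(inventory, "features")

#' @export
print.phoneme_inventory <- function(x, ...) {
  cat(sprintf(
    "<phoneme_inventory>  %d phonemes (%d vowels, %d consonants), %d features\n",
    nrow(x), sum(x$class == "vowel"), sum(x$class == "consonant"),
    n_features(x)
  ))
  invisible(x)
}
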