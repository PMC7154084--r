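#' Bundled spoken-phrase confusion counts
#'
#' The published test confusion matrix for five-phrase spoken decoding,
#' accumulated across subjects during the articulation stage (rows = true
#' phrase, columns = predicted phrase). Shipped as a worked example for
#' [confusion_and_accuracy()].
#'
#' @return 5 x 5 integer matrix with phrase dimnames.
#' @export
phrase_confusion_counts <- function() {
  path <- system.file("extdata", "spoken_phrase_confusion.tsv",
                      package = "megdecode", mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
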