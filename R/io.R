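#' Read and write word-object matrices as TSV
#'
#' The shared on-disk dialect for learned matrices: a header row of word
#' tokens, then one row per object with the object label in the first
#' column. Values round-trip at full precision.
#'
#' @param qw An `xsit_fit` or objects x words matrix.
#' @param path File path.
#' @return `read_qw_tsv()` returns a named numeric matrix;
#'   `write_qw_tsv()` invisibly returns `path`.
#' @export
write_qw_tsv <- function(qw, path) {
  values <- qw_matrix(qw)
  df <- tibble::as_tibble(values, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(object = rownames(values)), df)
  readr::write_tsv(df, path, col_names = TRUE)
  invisible(path)
}

#' @rdname write_qw_tsv
#' @export
read_qw_tsv <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      object = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  values <- as.matrix(df[, setdiff(names(df), "object"), drop = FALSE])
  rownames(values) <- df$object
  values
}

#' Serialize a Q-network to a flat text file
#'
#' A single JSON document holding the layer shapes, activations and all
#' parameters at full precision, so trained networks survive as plain text.
#'
#' @param net An `xsit_qnetwork`.
#' @param path File path.
#' @return `read_qnetwork()` returns an `xsit_qnetwork`;
#'   `write_qnetwork()` invisibly returns `path`.
#' @export
write_qnetwork <- function(net, path) {
  doc <- list(
    format = "xsit_qnetwork",
    N = net$N, H = net$H,
    activations = c("sigmoid", "sigmoid", "softmax"),
    W1 = net$W1, b1 = net$b1,
    W2 = net$W2, b2 = net$b2,
    W3 = net$W3, b3 = net$b3
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_qnetwork
#' @export
read_qnetwork <- function(path) {
  doc <- jsonlite::fromJSON(path)
  stopifnot(identical(doc$format, "xsit_qnetwork"))
  net <- structure(
    list(
      W1 = as.matrix(doc$W1), b1 = as.numeric(doc$b1),
      W2 = as.matrix(doc$W2), b2 = as.numeric(doc$b2),
      W3 = as.matrix(doc$W3), b3 = as.numeric(doc$b3),
      N = as.integer(doc$N), H = as.integer(doc$H)
    ),
    class = "xsit_qnetwork"
  )
  stopifnot(
    identical(dim(net$W1), c(net$N, net$H)),
    identical(dim(net$W2), c(net$H, net$H)),
    identical(dim(net$W3), c(net$H, net$N))
  )
  net
}
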