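#' Feature matrix with block tags
#'
#' Samples x features matrix in which every feature is tagged with the data
#' block it came from (`CNA`, `ASCN` or `SNV`) and the matrix as a whole is
#' either `raw` (non-negative counts/scores, ready for the ln(x+1) z-score
#' transform) or `normalised`.
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature names, unique).
#' @param blocks Character vector, one of `"CNA"`, `"ASCN"`, `"SNV"` per
#'   feature; either named by feature or in column order.
#' @param state `"raw"` or `"normalised"`.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, blocks, state = c("raw", "normalised")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  if (is.null(colnames(values)) || is.null(rownames(values)))
    stop("feature matrix needs sample rownames and feature colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature name(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!is.null(names(blocks))) blocks <- blocks[colnames(values)]
  if (length(blocks) != ncol(values))
    stop("blocks must give one block per feature")
  blocks <- as.character(blocks)
  bad <- !blocks %in% c("CNA", "ASCN", "SNV")
  if (any(bad)) stop("unknown block tag: ", paste(unique(blocks[bad]), collapse = ", "))
  if (state == "raw" && any(values < 0, na.rm = TRUE))
    stop("raw feature values must be non-negative")
  structure(values,
            blocks = stats::setNames(blocks, colnames(values)),
            state = state,
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features (%s)\n",
              nrow(x), ncol(x), attr(x, "state")))
  cat("blocks:", paste(sprintf("%s=%d", names(table(attr(x, "blocks"))),
                               table(attr(x, "blocks"))), collapse = " "), "\n")
  invisible(x)
}

fm_blocks <- function(x) attr(x, "blocks")
fm_state <- function(x) attr(x, "state")

#' Column-bind feature matrices over identical samples
#' @param ... `feature_matrix` objects with identical sample rows and state.
#' @return A combined `feature_matrix`.
#' @export
cbind_features <- function(...) {
  ms <- list(...)
  ids <- rownames(ms[[1]])
  st <- fm_state(ms[[1]])
  for (m in ms[-1]) {
    if (!identical(rownames(m), ids)) stop("sample ids differ between matrices")
    if (!identical(fm_state(m), st)) stop("cannot mix raw and normalised matrices")
  }
  vals <- do.call(cbind, lapply(ms, unclass))
  blocks <- do.call(c, lapply(ms, fm_blocks))
  feature_matrix(vals, blocks, state = st)
}

#' Write / read a feature matrix as TSV
#'
#' Samples are rows; a comment header line `#blocks: feat=BLOCK ...` and
#' `#state: raw|normalised` carry the metadata so that a write/read round
#' trip is lossless (values at 12 significant digits).
#'
#' @param x A `feature_matrix`.
#' @param path File path.
#' @return `path` (write) or a `feature_matrix` (read).
#' @export
write_feature_matrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#state: ", fm_state(x)), con)
  writeLines(paste0("#blocks: ",
                    paste(names(fm_blocks(x)), fm_blocks(x), sep = "=",
                          collapse = "\t")), con)
  df <- data.frame(sample_id = rownames(x),
                   signif(unclass(x), 12), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path, n = 2)
  if (!startsWith(lines[1], "#state: ") || !startsWith(lines[2], "#blocks: "))
    stop("feature matrix file lacks #state/#blocks header lines")
  state <- sub("^#state: ", "", lines[1])
  pairs <- strsplit(sub("^#blocks: ", "", lines[2]), "\t")[[1]]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  blocks <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- utils::read.delim(path, skip = 2, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  feature_matrix(m, blocks, state = state)
}
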